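test_that("the comb maximum has its closed form", {
  expect_identical(max_variance(1), 0)
  expect_identical(max_variance(2), 0)
  expect_equal(max_variance(3), 2 / 9)
  expect_identical(max_variance(8), 4.484375)
  expect_identical(as.character(max_variance(3, exact = TRUE)), "2/9")
  for (n in c(5, 17, 100, 4096)) {
    expect_equal(max_variance(n), depth_statistics(tree_comb(n))$V, tolerance = 1e-14)
  }
})

test_that("type profiles implement the four feasibility cases", {
  p <- type_profile(184, 6)
  expect_identical(p$case, 2L)
  expect_identical(p$p1, 9)
  expect_identical(p$delta, 8)
  p6 <- type_profile(6)
  expect_identical(p6$p1, 2)
  expect_identical(p6$delta, 3)
  expect_false(type_profile(64, c(5, 6))$feasible)      # between the guards
  expect_identical(type_profile(8)$case, 1L)            # fully symmetric
  expect_identical(type_profile(8)$delta, 3)
  p3 <- type_profile(482, 6)                            # deep case: delta = m + 2
  expect_identical(p3$case, 3L)
  expect_identical(p3$p1, 479)
  expect_identical(p3$delta, 10)
  expect_error(type_profile(30, c(6, 5)), "strictly increasing")
  expect_error(type_profile(30, 1), "strictly increasing")
})

test_that("type variance matches materialized representatives", {
  expect_identical(type_variance(184, 6, exact = TRUE), rq(8055, 33856))
  expect_identical(type_variance(184, integer(0), exact = TRUE), rq(8064, 33856))
  expect_identical(type_variance(256, integer(0)), 0)
  expect_error(type_variance(64, c(5, 6)), "infeasible")
  # feasible profiles are Kraft-realizable and reproduce their V exactly,
  # across a seeded sample of (n, ls) pairs up to n = 4096
  set.seed(5)
  checked <- 0
  while (checked < 60) {
    n <- sample(4:4096, 1)
    m <- floor(log2(n))
    if (m < 5) next
    pool <- 5:m
    j <- sample(0:min(3, length(pool)), 1)
    ls <- sort(sample(pool, j))
    p <- type_profile(n, ls)
    if (!p$feasible) next
    d <- depthvar:::type_depth_multiset(p)
    expect_true(kraft_realizable(d))
    sh <- tree_from_depths(d)
    st <- depth_statistics(sh)
    expect_equal(st$V_num / st$V_den, type_variance(n, ls), tolerance = 1e-15)
    expect_identical(st$n, as.integer(n))
    checked <- checked + 1
  }
})

test_that("minimum-V search handles small and boundary leaf counts", {
  m8 <- min_variance(8)
  expect_identical(m8$min_value, 0)
  expect_identical(m8$argmin, list(integer(0)))
  m184 <- min_variance(184)
  expect_identical(min_variance_exact(m184), rq(8055, 33856))
  expect_identical(m184$argmin, list(6L))
  m100 <- min_variance(100)
  expect_identical(m100$min_value, 0.2016)  # 2*36*28/10000, the F_100 value
  expect_identical(m100$argmin, list(integer(0)))
  expect_identical(min_variance(1)$min_value, 0)
  expect_identical(min_variance(3)$min_num, 2)
  # min over candidate types never exceeds the maximally balanced value
  for (n in c(7, 50, 183, 184, 482, 1000)) {
    mv <- min_variance(n)
    expect_true(mv$min_value <= type_variance(n, integer(0)) + 1e-15)
    balanced_opt <- any(lengths(mv$argmin) == 0L)
    expect_identical(balanced_opt,
                     mv$min_num == n^2 * type_variance(n, integer(0)))
  }
})

test_that("for all n <= 183 the minimum is the maximally balanced class", {
  for (n in 2:183) {
    mv <- min_variance(n)
    expect_identical(mv$argmin, list(integer(0)))
  }
})

test_that("the search minimum equals the exhaustive minimum for n <= 20", {
  for (n in 2:20) {
    tbl <- enumerate_shapes(n, materialize = FALSE)
    key <- n * tbl$S2 - tbl$S ^ 2        # integer n^2 V per shape
    mv <- min_variance(n)
    expect_identical(min(key), mv$min_num)
    # every exhaustive argmin shape classifies into an argmin type
    argmin_strings <- vapply(mv$argmin, paste, "", collapse = ",")
    hits <- which(key == min(key))
    for (i in hits) {
      d <- depth_multiset(rep(seq_along(tbl$depths[[i]]) - 1L, tbl$depths[[i]]))
      ct <- classify_type(d)
      expect_false(is.null(ct))
      expect_true(paste(ct$ls, collapse = ",") %in% argmin_strings)
    }
  }
})

test_that("scan summaries expose the dyadic-interval structure", {
  sc <- scan_min_variance(180, 200)
  expect_s3_class(sc, "depthvar_scan")
  expect_identical(first_unbalanced(sc), 184)
  expect_identical(sc$argmin_ls[sc$n == 184], "6")
  expect_identical(round(sc$min_V[sc$n == 184], 4), 0.2379)
  expect_true(all(sc$is_max_balanced[sc$n <= 183]))
  expect_identical(balanced_fraction(sc), mean(sc$is_max_balanced))
  # run-length encoding descends within each dyadic block
  sc2 <- scan_min_variance(256, 511)
  runs <- argmin_runs(sc2)
  expect_true(all(runs$from_n >= runs$to_n))
  expect_identical(sum(runs$length), nrow(sc2))
  # n = 482 = 2^9 - 30 sits alone in a type-(6) run
  expect_identical(sc2$argmin_ls[sc2$n == 482], "6")
})

test_that("tidy and glance methods summarize the search result", {
  mv <- min_variance(184)
  td <- tidy(mv)
  expect_identical(td$ls, "6")
  expect_identical(td$V_num, 8055)
  gl <- glance(mv)
  expect_false(gl$is_max_balanced)
  expect_identical(gl$n_argmin, 1L)
  gl8 <- glance(min_variance(8))
  expect_true(gl8$is_max_balanced)
})

test_that("scan plots build without error", {
  sc <- scan_min_variance(100, 140)
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
})
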