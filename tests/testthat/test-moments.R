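test_that("special numbers evaluate to their defining values", {
  s3 <- special_numbers(3, exact = TRUE)
  expect_identical(as.character(s3$H), "11/6")
  expect_identical(as.character(s3$r), "8/3")
  expect_identical(vapply(s3$C_row, as.character, ""), c("1/2", "1/2"))
  s5 <- special_numbers(5)
  expect_identical(s5$dfact_odd, 105)
  expect_equal(sum(s5$C_row), 1)
  s2 <- special_numbers(2, exact = TRUE)
  expect_identical(length(s2$C_row), 1L)
  expect_identical(as.character(s2$C_row[[1]]), "1")
})

test_that("splitting weights are symmetric and sum to one, n <= 100", {
  # exact for a ladder of n, double route for the rest
  for (n in c(2, 3, 10, 30, 100)) {
    cr <- special_numbers(n, exact = TRUE)$C_row
    expect_identical(as.character(Reduce(`+`, cr, rq(0))), "1")
    for (k in seq_len((n - 1) %/% 2)) {
      expect_identical(cr[[k]], cr[[n - k]])
    }
  }
  for (n in 2:100) {
    expect_equal(sum(special_numbers(n)$C_row), 1, tolerance = 1e-12)
  }
})

test_that("recurrence closed forms match known uniform-model solutions", {
  # forcing -3n + 2n r_n, X1 = 0 resolves to (4n-1)n - 3n r_n
  spec2 <- recurrence_spec(a = -3, b = 2, X1 = 0)
  sol2 <- solve_recurrence(spec2)
  expect_identical(vapply(sol2$a_hat, as.character, ""), c("3", "8"))
  expect_identical(vapply(sol2$b_hat, as.character, ""), "-3")
  for (n in c(1, 2, 5, 12, 20)) {
    expect_identical(eval_solution(sol2, n), uniform_moments_exact(n)$E_S2)
  }
  # forcing -n(5n-2) + (5/2)n^2 r_n resolves to n(10n^2-1)/3 - n(5n+1)/2 r_n
  spec3 <- recurrence_spec(a = c(-3, -10), b = list(rq(5, 2), rq(5)), X1 = 0)
  sol3 <- solve_recurrence(spec3)
  for (n in c(1, 2, 4, 9, 17)) {
    expect_identical(eval_solution(sol3, n), uniform_moments_exact(n)$E_Ssq)
  }
  # the homogeneous equation with zero start stays at zero
  sol0 <- solve_recurrence(recurrence_spec(a = 0, b = 0, X1 = 0))
  expect_identical(as.numeric(eval_solution(sol0, 13)), 0)
})

test_that("direct iteration and the closed form agree termwise, n <= 30", {
  spec2 <- recurrence_spec(a = -3, b = 2, X1 = 0)
  spec3 <- recurrence_spec(a = c(-3, -10), b = list(rq(5, 2), rq(5)), X1 = 0)
  for (spec in list(spec2, spec3)) {
    sol <- solve_recurrence(spec)
    it <- iterate_recurrence(spec, 30)
    for (n in 1:30) expect_identical(eval_solution(sol, n), it[[n]])
  }
  expect_identical(iterate_recurrence(spec3, 4)[[4]], rq(388, 5))
  expect_identical(iterate_recurrence(spec2, 2)[[2]], eval_solution(solve_recurrence(spec2), 2))
  # random specs, seeded
  set.seed(31)
  for (rep in 1:12) {
    a <- sample(-6:6, sample(1:3, 1), replace = TRUE)
    b <- lapply(sample(-6:6, sample(1:2, 1), replace = TRUE),
                function(x) rq(x, sample(1:3, 1)))
    spec <- recurrence_spec(a = a, b = b, X1 = sample(-3:3, 1))
    sol <- solve_recurrence(spec)
    it <- iterate_recurrence(spec, 18)
    for (n in 1:18) expect_identical(eval_solution(sol, n), it[[n]])
  }
})

test_that("power-basis polynomials convert to the binomial basis", {
  # n^2 = C(n,1) + 2 C(n,2); 5n^2/2 = (5/2) C(n,1) + 5 C(n,2)
  conv <- power_to_binomial(list(rq(0), rq(5, 2)))
  expect_identical(vapply(conv, as.character, ""), c("5/2", "5"))
  conv2 <- power_to_binomial(c(2, -5))
  expect_identical(vapply(conv2, as.character, ""), c("-3", "-10"))
  # reconstruction: sum a_l C(n,l) == polynomial for a random cubic
  coefs <- c(3, -2, 7)
  a <- power_to_binomial(coefs)
  for (n in 1:9) {
    expect_equal(sum(vapply(seq_along(a), function(l) as.numeric(a[[l]]) * choose(n, l), 0)),
                 sum(coefs * n ^ (1:3)))
  }
})

test_that("Yule moments: closed forms, identities, and known rows", {
  expect_identical(as.numeric(yule_moments_exact(1)$E_V), 0)
  y3 <- yule_moments_exact(3)
  expect_identical(as.character(y3$E_S), "5")
  expect_identical(y3$E_V, rq(2, 9))
  expect_identical(round(yule_moments(8)$E_V, 4), 1.2402)
  # E_V = E_S2/n - E_Ssq/n^2 exactly
  for (n in c(2, 5, 11, 23)) {
    y <- yule_moments_exact(n)
    expect_identical(y$E_V, y$E_S2 / rq(n) - y$E_Ssq / rq(n ^ 2))
  }
})

test_that("uniform moments: closed forms, identities, and known rows", {
  expect_identical(as.numeric(uniform_moments_exact(1)$E_V), 0)
  u3 <- uniform_moments_exact(3)
  expect_identical(u3$E_V, rq(2, 9))  # 10/9 - 8/9
  expect_identical(round(uniform_moments(8)$E_V, 4), 2.2864)
  for (n in c(2, 5, 11, 23)) {
    u <- uniform_moments_exact(n)
    expect_identical(u$E_V, u$E_S2 / rq(n) - u$E_Ssq / rq(n ^ 2))
  }
})

test_that("uniform variances and covariance: known rows and positivity", {
  v3 <- uniform_covariances_exact(3)
  expect_identical(as.numeric(v3$var_S), 0)
  expect_identical(uniform_covariances_exact(4)$cov_SPhi, rq(8, 25))  # 0.32
  v <- uniform_covariances(1:10000)
  expect_true(all(v$var_S >= -1e-9))
  expect_true(all(v$var_Phi >= -1e-9))
  expect_true(all(v$cov_SPhi ^ 2 <= v$var_S * v$var_Phi * (1 + 1e-9) + 1e-12))
})

test_that("closed-form moments equal the enumeration oracle exactly, n <= 8", {
  for (n in 2:8) {
    y <- yule_moments_exact(n)
    expect_identical(expected_by_enumeration(n, "V", "yule", exact = TRUE), y$E_V)
    expect_identical(expected_by_enumeration(n, "S", "yule", exact = TRUE), y$E_S)
    expect_identical(expected_by_enumeration(n, "S2", "yule", exact = TRUE), y$E_S2)
    expect_identical(expected_by_enumeration(n, "Ssq", "yule", exact = TRUE), y$E_Ssq)
    u <- uniform_moments_exact(n)
    ES <- expected_by_enumeration(n, "S", "uniform", exact = TRUE)
    EPhi <- expected_by_enumeration(n, "Phi", "uniform", exact = TRUE)
    expect_identical(expected_by_enumeration(n, "V", "uniform", exact = TRUE), u$E_V)
    expect_identical(ES, u$E_S)
    expect_identical(expected_by_enumeration(n, "S2", "uniform", exact = TRUE), u$E_S2)
    cv <- uniform_covariances_exact(n)
    expect_identical(expected_by_enumeration(n, "Ssq", "uniform", exact = TRUE) - ES ^ 2,
                     cv$var_S)
    expect_identical(expected_by_enumeration(n, "PhiSq", "uniform", exact = TRUE) - EPhi ^ 2,
                     cv$var_Phi)
    expect_identical(expected_by_enumeration(n, "SPhi", "uniform", exact = TRUE) - ES * EPhi,
                     cv$cov_SPhi)
  }
})

test_that("asymptotic regimes emerge at large n", {
  # r_n / sqrt(pi n) -> 1
  expect_true(abs(dfact_ratio(1e4) / sqrt(pi * 1e4) - 1) < 0.01)
  expect_true(abs(dfact_ratio(1e6) / sqrt(pi * 1e6) - 1) < 0.001)
  # E_U(V_n) ~ 2n/3: within 1% by n = 1e6, approaching monotonically
  ns <- 10 ^ (2:6)
  ratio_u <- uniform_moments(ns)$E_V / (2 * ns / 3)
  expect_true(all(diff(ratio_u) > 0))
  expect_lt(abs(ratio_u[5] - 1), 0.01)
  # E_Y(V_n) ~ 2 log n: slow (1/log n) convergence, so check monotone
  # approach and the asymptotic deficit 2*gamma - 5 over 2 log n
  ratio_y <- yule_moments(ns)$E_V / (2 * log(ns))
  expect_true(all(diff(ratio_y) > 0))
  expect_equal(ratio_y[5], 1 + (2 * (-digamma(1)) - 5) / (2 * log(1e6)),
               tolerance = 1e-3)
  # limiting Pearson correlation of S and Phi
  expect_identical(round(uniform_asymptotics()$rho_limit, 3), 0.965)
  cv <- uniform_covariances(1e6)
  expect_equal(cv$var_S / 1e18, uniform_asymptotics()$c_var_S, tolerance = 0.01)
})

test_that("the combined moment table lines up with its parts", {
  mt <- moment_table(3:8)
  expect_identical(mt$EY_V, yule_moments(3:8)$E_V)
  expect_identical(mt$covU_SPhi, uniform_covariances(3:8)$cov_SPhi)
  expect_named(mt, c("n", "EY_V", "EU_V", "varU_S", "varU_Phi", "covU_SPhi"))
})
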