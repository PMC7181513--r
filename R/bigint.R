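# Arbitrary-precision signed integers, used as the backbone of the exact
# rational class `rq`.  Magnitudes are little-endian limb vectors in base 1e7
# stored as doubles; every intermediate quantity stays below 2^53, so all limb
# arithmetic is exact.  Only what the package needs is implemented: add, sub,
# mul, compare, divmod (binary shift-subtract), gcd, and decimal printing.

.BI_BASE <- 1e7

bi <- function(sign, mag) list(s = sign, m = mag)

bi_zero <- function() bi(0L, numeric(0))
bi_one <- function() bi(1L, 1)

bi_is_zero <- function(x) x$s == 0L

# strip leading (high-order) zero limbs
bi_trim <- function(m) {
  n <- length(m)
  while (n > 0L && m[n] == 0) n <- n - 1L
  m[seq_len(n)]
}

# full carry propagation, extending length as needed
bi_carry_full <- function(m) {
  repeat {
    carry <- floor(m / .BI_BASE)
    if (all(carry == 0)) break
    m <- m - carry * .BI_BASE
    carry <- c(0, carry)
    if (carry[length(carry)] == 0) carry <- carry[-length(carry)] else m <- c(m, 0)
    m <- m + carry
  }
  bi_trim(m)
}

# convert a double holding an exact integer |x| < 2^53
bi_from_num <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x))
    stop_data("cannot convert %s to an exact integer", format(x))
  if (abs(x) > 2^53)
    stop_data("|%s| exceeds 2^53; construct it with big-integer arithmetic instead", format(x))
  s <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  m <- numeric(0)
  while (x > 0) {
    m <- c(m, x %% .BI_BASE)
    x <- x %/% .BI_BASE
  }
  bi(s, m)
}

as_bi <- function(x) {
  if (is.list(x) && !is.null(x$s)) x else bi_from_num(x)
}

# magnitude comparison: -1, 0, 1
bi_cmp_mag <- function(a, b) {
  la <- length(a$m); lb <- length(b$m)
  if (la != lb) return(if (la < lb) -1L else 1L)
  if (la == 0L) return(0L)
  for (i in rev(seq_len(la))) {
    if (a$m[i] != b$m[i]) return(if (a$m[i] < b$m[i]) -1L else 1L)
  }
  0L
}

bi_cmp <- function(a, b) {
  if (a$s != b$s) return(if (a$s < b$s) -1L else 1L)
  if (a$s == 0L) return(0L)
  a$s * bi_cmp_mag(a, b)
}

bi_add_mag <- function(ma, mb) {
  la <- length(ma); lb <- length(mb)
  n <- max(la, lb)
  m <- numeric(n)
  m[seq_len(la)] <- ma
  m[seq_len(lb)] <- m[seq_len(lb)] + mb
  bi_carry_full(m)
}

# requires magnitude(ma) >= magnitude(mb)
bi_sub_mag <- function(ma, mb) {
  la <- length(ma); lb <- length(mb)
  m <- ma
  m[seq_len(lb)] <- m[seq_len(lb)] - mb
  # borrow propagation
  while (any(m < 0)) {
    i <- which(m < 0)
    m[i] <- m[i] + .BI_BASE
    m[i + 1L] <- m[i + 1L] - 1
  }
  bi_trim(m)
}

bi_neg <- function(a) bi(-a$s, a$m)

bi_add <- function(a, b) {
  if (a$s == 0L) return(b)
  if (b$s == 0L) return(a)
  if (a$s == b$s) return(bi(a$s, bi_add_mag(a$m, b$m)))
  cmp <- bi_cmp_mag(a, b)
  if (cmp == 0L) return(bi_zero())
  if (cmp > 0L) bi(a$s, bi_sub_mag(a$m, b$m)) else bi(b$s, bi_sub_mag(b$m, a$m))
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (a$s == 0L || b$s == 0L) return(bi_zero())
  ma <- a$m; mb <- b$m
  lr <- length(ma) + length(mb)
  res <- numeric(lr)
  for (i in seq_along(ma)) {
    idx <- i:(i + length(mb) - 1L)
    res[idx] <- res[idx] + ma[i] * mb
    # keep partial column sums well below 2^53
    if (i %% 40L == 0L) {
      res <- bi_carry_full(res)
      if (length(res) < lr) res <- c(res, numeric(lr - length(res)))
    }
  }
  m <- bi_carry_full(res)
  bi(a$s * b$s, m)
}

bi_mul_small <- function(a, k) bi_mul(a, bi_from_num(k))

# divmod on nonnegative values: a = q*b + r, 0 <= r < b
bi_divmod <- function(a, b) {
  if (bi_is_zero(b)) stop_data("big-integer division by zero")
  if (a$s < 0L || b$s < 0L) stop_data("bi_divmod expects nonnegative operands")
  if (bi_cmp_mag(a, b) < 0) return(list(q = bi_zero(), r = a))
  # doublings of b (and matching powers of two) up to |a|
  ds <- list(b)
  ps <- list(bi_one())
  while (bi_cmp_mag(ds[[length(ds)]], a) <= 0) {
    last <- ds[[length(ds)]]
    ds[[length(ds) + 1L]] <- bi(1L, bi_add_mag(last$m, last$m))
    lp <- ps[[length(ps)]]
    ps[[length(ps) + 1L]] <- bi(1L, bi_add_mag(lp$m, lp$m))
  }
  q <- bi_zero()
  r <- a
  for (i in rev(seq_along(ds))) {
    if (bi_cmp_mag(r, ds[[i]]) >= 0) {
      m <- bi_sub_mag(r$m, ds[[i]]$m)
      r <- bi(if (length(m) > 0L) 1L else 0L, m)
      q <- bi_add(q, ps[[i]])
    }
  }
  list(q = q, r = r)
}

bi_gcd <- function(a, b) {
  a <- bi(abs(a$s), a$m); b <- bi(abs(b$s), b$m)
  while (!bi_is_zero(b)) {
    r <- bi_divmod(a, b)$r
    a <- b
    b <- r
  }
  a
}

bi_pow_small <- function(base, k) {
  out <- bi_one()
  b <- as_bi(base)
  k <- as.integer(k)
  while (k > 0L) {
    if (k %% 2L == 1L) out <- bi_mul(out, b)
    b <- bi_mul(b, b)
    k <- k %/% 2L
  }
  out
}

bi_fact <- function(n) {
  out <- bi_one()
  if (n >= 2) for (i in 2:n) out <- bi_mul_small(out, i)
  out
}

# odd double factorial (2n-3)!!, with the convention (-1)!! = 1
bi_dfact_odd <- function(n) {
  out <- bi_one()
  k <- 2 * n - 3
  if (k >= 3) for (i in seq(3, k, by = 2)) out <- bi_mul_small(out, i)
  out
}

# even double factorial (2n-2)!! = 2^(n-1) (n-1)!
bi_dfact_even <- function(n) bi_mul(bi_pow_small(2, n - 1), bi_fact(n - 1))

bi_to_num <- function(x) {
  if (x$s == 0L) return(0)
  v <- 0
  for (i in rev(seq_along(x$m))) v <- v * .BI_BASE + x$m[i]
  x$s * v
}

bi_to_string <- function(x) {
  if (x$s == 0L) return("0")
  digs <- vapply(rev(x$m[-length(x$m)]), function(d) sprintf("%07.0f", d), "")
  paste0(if (x$s < 0L) "-" else "", sprintf("%.0f", x$m[length(x$m)]),
         paste(digs, collapse = ""))
}

# exact sum of nonnegative integer-valued doubles (each < 2^53), chunked so
# partial double sums never lose precision
bi_sum_terms <- function(terms) {
  if (any(terms >= 2^53)) stop_data("summand exceeds 2^53; cannot accumulate exactly")
  acc <- bi_zero()
  run <- 0
  for (t in terms) {
    if (run + t >= 2^53) {
      acc <- bi_add(acc, bi_from_num(run))
      run <- 0
    }
    run <- run + t
  }
  bi_add(acc, bi_from_num(run))
}

# Pascal-row binomial coefficients C(n, 0..n) as big integers
bi_binom_row <- function(n) {
  row <- list(bi_one())
  if (n >= 1) {
    for (i in seq_len(n)) {
      new <- vector("list", i + 1L)
      new[[1L]] <- bi_one()
      new[[i + 1L]] <- bi_one()
      if (i >= 2) for (j in 2:i) new[[j]] <- bi_add(row[[j - 1L]], row[[j]])
      row <- new
    }
  }
  row
}
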