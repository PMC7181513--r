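#' Harmonic numbers and double-factorial ratios
#'
#' Helpers underlying the closed-form moments: the harmonic numbers
#' `H_n = sum(1/i)` and `H2_n = sum(1/i^2)`, the odd double factorial
#' `(2n-3)!!`, and the ratio `r_n = (2n-2)!!/(2n-3)!!`, which grows like
#' `sqrt(pi * n)`.  Double versions are vectorized (via `digamma`/`trigamma`
#' and log-gamma, accurate to double precision for any `n`); exact versions
#' return [rq()] rationals.
#'
#' @param n leaf count(s).
#' @param exact return exact [rq()] values (scalar `n` only).
#' @return Doubles (vectorized) or `rq` objects.
#' @examples
#' harmonic_number(8)       # 761/280
#' dfact_ratio(4)           # 3.2
#' @export
harmonic_number <- function(n, exact = FALSE) {
  if (exact) {
    n <- check_count(n)
    return(q_sum(lapply(seq_len(n), function(i) rq(1, i))))
  }
  digamma(n + 1) - digamma(1)
}

#' @rdname harmonic_number
#' @export
harmonic_number2 <- function(n, exact = FALSE) {
  if (exact) {
    n <- check_count(n)
    return(q_sum(lapply(seq_len(n), function(i) rq(1, i ^ 2))))
  }
  pi ^ 2 / 6 - trigamma(n + 1)
}

#' @rdname harmonic_number
#' @export
dfact_ratio <- function(n, exact = FALSE) {
  if (exact) {
    n <- check_count(n)
    return(new_rq(bi_dfact_even(n), bi_dfact_odd(n)))
  }
  exp((2 * n - 2) * log(2) + 2 * lgamma(n) - lgamma(2 * n - 1))
}

# log of (2n-3)!!
ldfact_odd <- function(n) {
  ifelse(n < 2, 0, lgamma(2 * n - 1) - (n - 1) * log(2) - lgamma(n))
}

#' Special numbers for the uniform-model recurrences
#'
#' Bundles, for a given `n`: the harmonic numbers `H` and `H2`, the labeled
#' tree count `dfact_odd = (2n-3)!!`, the ratio `r = (2n-2)!!/(2n-3)!!`, and
#' the splitting weights
#'
#'   `C_{k,n-k} = 1/2 * choose(n,k) * (2k-3)!!(2(n-k)-3)!! / (2n-3)!!`
#'
#' for `k = 1..n-1`: the probability weight with which a uniform-model tree
#' splits into root subtrees of sizes `k` and `n-k`.  The row is symmetric
#' and sums to 1 for every `n >= 2`.
#'
#' @param n leaf count.
#' @param exact return `rq` values throughout.
#' @return A list with `H`, `H2`, `dfact_odd`, `r`, `C_row` (length `n-1`;
#'   `C_row` is a plain numeric vector, or a list of `rq` when exact).
#' @examples
#' special_numbers(3)$C_row   # 1/2, 1/2
#' @export
special_numbers <- function(n, exact = FALSE) {
  n <- check_count(n)
  if (exact) {
    dfo <- bi_dfact_odd(n)
    row <- bi_binom_row(n)
    C_row <- if (n >= 2) {
      lapply(seq_len(n - 1), function(k) {
        num <- bi_mul(row[[k + 1L]], bi_mul(bi_dfact_odd(k), bi_dfact_odd(n - k)))
        new_rq(num, bi_mul_small(dfo, 2))
      })
    } else {
      list()
    }
    return(list(
      H = harmonic_number(n, exact = TRUE),
      H2 = harmonic_number2(n, exact = TRUE),
      dfact_odd = structure(list(num = dfo, den = bi_one()), class = "rq"),
      r = dfact_ratio(n, exact = TRUE),
      C_row = C_row
    ))
  }
  ks <- seq_len(max(n - 1, 0))
  C_row <- if (n >= 2) {
    exp(lchoose(n, ks) + ldfact_odd(ks) + ldfact_odd(n - ks) - ldfact_odd(n)) / 2
  } else {
    numeric(0)
  }
  list(
    H = harmonic_number(n),
    H2 = harmonic_number2(n),
    dfact_odd = n_labeled_trees(n),
    r = dfact_ratio(n),
    C_row = C_row
  )
}

# --- recurrences in the binomial / double-factorial basis -----------------

#' Recurrences of the uniform-model type and their closed-form solution
#'
#' The uniform-model expectations in this package satisfy recurrences
#'
#'   `X_n = 2 * sum_k C_{k,n-k} X_k + sum_l a_l * choose(n,l)
#'          + r_n * sum_l b_l * choose(n,l)`
#'
#' with `r_n = (2n-2)!!/(2n-3)!!` and polynomial forcing terms written in
#' the binomial basis with no independent term.  `recurrence_spec()` bundles
#' the coefficients and the initial condition `X_1`; `solve_recurrence()`
#' returns the closed form
#'
#'   `X_n = sum_{l=1}^{s+1} ahat_l * choose(n,l)
#'          + r_n * sum_{l=1}^{r} bhat_l * choose(n,l)`
#'
#' with `ahat_1 = X_1 - a_1`,
#' `ahat_l = l*(2l-2)!!/(2l-3)!! * (b_l/l + b_{l-1}/(l-1))` for `l = 2..s`,
#' `ahat_{s+1} = (s+1)*(2s)!!/(s*(2s-1)!!) * b_s`, and
#' `bhat_l = (2l-3)!!/(2l-2)!! * a_l`; `iterate_recurrence()` instead runs
#' the recurrence directly (quadratic cost) in exact arithmetic, serving as
#' an independent check of the closed form.  When the `b` part is absent it
#' is padded with a single zero coefficient.
#'
#' @param a numeric or list of [rq()]: coefficients `a_1..a_r`.
#' @param b numeric or list of [rq()]: coefficients `b_1..b_s`.
#' @param X1 initial condition (numeric or `rq`).
#' @return `recurrence_spec()`: a `recurrence_spec` object;
#'   `solve_recurrence()`: a `recurrence_solution` with `rq` coefficient
#'   lists `a_hat`, `b_hat`; `iterate_recurrence()`: list of `rq`
#'   `X_1..X_{n_max}`; `eval_solution()`: `rq` (or double) value at `n`.
#' @examples
#' spec <- recurrence_spec(a = -3, b = 2, X1 = 0)
#' sol <- solve_recurrence(spec)
#' as.numeric(eval_solution(sol, 4))   # 21.6, the expected S^(2) at n = 4
#' @export
recurrence_spec <- function(a, b, X1 = 0) {
  to_rq_list <- function(v) {
    if (is_rq(v)) return(list(v))
    if (is.list(v)) {
      if (!all(vapply(v, is_rq, TRUE))) {
        stop_data("coefficient lists must contain rq values; use list(rq(...), ...)")
      }
      return(v)
    }
    lapply(as.numeric(v), as_rq)
  }
  a <- to_rq_list(a)
  b <- to_rq_list(b)
  if (length(a) == 0L) a <- list(as_rq(0))
  if (length(b) == 0L) b <- list(as_rq(0))
  structure(list(a = a, b = b, X1 = as_rq(X1)), class = "recurrence_spec")
}

#' @rdname recurrence_spec
#' @param spec a `recurrence_spec`.
#' @export
solve_recurrence <- function(spec) {
  stopifnot(inherits(spec, "recurrence_spec"))
  a <- spec$a
  b <- spec$b
  r <- length(a)
  s <- length(b)
  dfe <- function(k) new_rq(bi_dfact_even(k), bi_one())    # (2k-2)!!
  dfo <- function(k) new_rq(bi_dfact_odd(k), bi_one())     # (2k-3)!!
  a_hat <- vector("list", s + 1L)
  a_hat[[1L]] <- spec$X1 - a[[1L]]
  if (s >= 2) {
    for (l in 2:s) {
      # l * (2l-2)!! / (2l-3)!!
      coef <- rq(l) * dfe(l) / dfo(l)
      a_hat[[l]] <- coef * (b[[l]] / rq(l) + b[[l - 1L]] / rq(l - 1))
    }
  }
  # (s+1) * (2s)!! / (s * (2s-1)!!): (2s)!! = (2(s+1)-2)!!, (2s-1)!! = (2(s+1)-3)!!
  a_hat[[s + 1L]] <- rq(s + 1) * dfe(s + 1) / (rq(s) * dfo(s + 1)) * b[[s]]
  b_hat <- lapply(seq_len(r), function(l) dfo(l) / dfe(l) * a[[l]])
  structure(list(a_hat = a_hat, b_hat = b_hat, spec = spec),
            class = "recurrence_solution")
}

#' @rdname recurrence_spec
#' @param sol a `recurrence_solution`.
#' @param n evaluation point.
#' @param exact return an `rq` (default) or a double.
#' @export
eval_solution <- function(sol, n, exact = TRUE) {
  stopifnot(inherits(sol, "recurrence_solution"))
  n <- check_count(n)
  row <- bi_binom_row(n)
  binom <- function(l) {
    if (l > n) as_rq(0) else structure(list(num = row[[l + 1L]], den = bi_one()),
                                       class = "rq")
  }
  poly <- function(coefs) {
    q_sum(lapply(seq_along(coefs), function(l) coefs[[l]] * binom(l)))
  }
  val <- poly(sol$a_hat) + dfact_ratio(n, exact = TRUE) * poly(sol$b_hat)
  if (exact) val else as.numeric(val)
}

#' @rdname recurrence_spec
#' @param n_max iterate up to this `n`.
#' @export
iterate_recurrence <- function(spec, n_max) {
  stopifnot(inherits(spec, "recurrence_spec"))
  n_max <- check_count(n_max, "n_max")
  # common denominator M of all coefficients, so W_n = X_n * M * (2n-3)!! is
  # an integer and the iteration stays in big-integer arithmetic
  dens <- c(lapply(spec$a, function(x) x$den), lapply(spec$b, function(x) x$den),
            list(spec$X1$den))
  M <- Reduce(function(acc, d) {
    g <- bi_gcd(acc, d)
    bi_mul(bi_divmod(acc, g)$q, d)
  }, dens, bi_one())
  int_coef <- function(x) bi_mul(x$num, bi_divmod(M, x$den)$q)
  aM <- lapply(spec$a, int_coef)
  bM <- lapply(spec$b, int_coef)
  W <- vector("list", n_max)
  W[[1L]] <- int_coef(spec$X1)
  dfo <- lapply(seq_len(n_max), bi_dfact_odd)
  dfe <- lapply(seq_len(n_max), bi_dfact_even)
  if (n_max >= 2) {
    for (n in 2:n_max) {
      row <- bi_binom_row(n)
      acc <- bi_zero()
      for (k in seq_len(n - 1L)) {
        acc <- bi_add(acc, bi_mul(row[[k + 1L]], bi_mul(dfo[[n - k]], W[[k]])))
      }
      forcing <- function(coefs, scale) {
        tot <- bi_zero()
        for (l in seq_along(coefs)) {
          if (l <= n) tot <- bi_add(tot, bi_mul(coefs[[l]], row[[l + 1L]]))
        }
        bi_mul(scale, tot)
      }
      acc <- bi_add(acc, forcing(aM, dfo[[n]]))
      acc <- bi_add(acc, forcing(bM, dfe[[n]]))
      W[[n]] <- acc
    }
  }
  lapply(seq_len(n_max), function(n) new_rq(W[[n]], bi_mul(M, dfo[[n]])))
}

#' Power-basis to binomial-basis polynomial conversion
#'
#' Rewrites `sum_i c_i n^i` (no constant term) as `sum_l a_l choose(n, l)`
#' using Stirling numbers of the second kind: `a_l = sum_i c_i S(i,l) l!`.
#'
#' @param coefs numeric or list of [rq()]: coefficients of `n^1, n^2, ...`.
#' @return A list of `rq` coefficients on `choose(n, 1), choose(n, 2), ...`.
#' @examples
#' # n^2 = choose(n,1) + 2*choose(n,2)
#' sapply(power_to_binomial(c(0, 1)), as.numeric)
#' @export
power_to_binomial <- function(coefs) {
  if (!is.list(coefs)) coefs <- lapply(as.numeric(coefs), as_rq)
  r <- length(coefs)
  # Stirling numbers of the second kind S(i, l), 1 <= l <= i <= r
  S <- matrix(0, r, r)
  S[1, 1] <- 1
  if (r >= 2) {
    for (i in 2:r) {
      for (l in seq_len(i)) {
        S[i, l] <- (if (l > 1) S[i - 1, l - 1] else 0) + l * S[i - 1, l]
      }
    }
  }
  lapply(seq_len(r), function(l) {
    q_sum(lapply(l:r, function(i) coefs[[i]] * rq(S[i, l] * factorial(l))))
  })
}

# --- closed-form moments ---------------------------------------------------

#' Closed-form moments of the depth indices under the Yule model
#'
#' Exact expectations under the Yule (Equal-Rate Markov) model, as functions
#' of the harmonic numbers `H_n` and `H2_n = sum(1/i^2)`:
#'
#' * `E_S`: expected Sackin index, `2n(H_n - 1)`;
#' * `E_S2`: expected sum of squared depths,
#'   `2n(2H_n^2 - 3H_n - 2H2_n + 3)`;
#' * `E_Ssq`: expected squared Sackin index,
#'   `4n^2(H_n^2 - H2_n - 2H_n) - 2nH_n + 11n^2 - n`;
#' * `E_V`: expected depth variance, `2(n+1)/n * H_n + 1/n - 5`, which grows
#'   like `2 log n`.
#'
#' The identity `E_V = E_S2/n - E_Ssq/n^2` holds exactly.
#'
#' @param n leaf counts (vectorized).
#' @return A tibble with columns `n`, `E_S`, `E_S2`, `E_Ssq`, `E_V`.
#' @examples
#' yule_moments(3:8)
#' @export
yule_moments <- function(n) {
  H <- harmonic_number(n)
  H2 <- harmonic_number2(n)
  tibble(
    n = n,
    E_S = 2 * n * (H - 1),
    E_S2 = 2 * n * (2 * H ^ 2 - 3 * H - 2 * H2 + 3),
    E_Ssq = 4 * n ^ 2 * (H ^ 2 - H2 - 2 * H) - 2 * n * H + 11 * n ^ 2 - n,
    E_V = 2 * (n + 1) / n * H + 1 / n - 5
  )
}

#' @rdname yule_moments
#' @export
yule_moments_exact <- function(n) {
  n <- check_count(n)
  H <- harmonic_number(n, exact = TRUE)
  H2 <- harmonic_number2(n, exact = TRUE)
  list(
    E_S = rq(2 * n) * (H - 1),
    E_S2 = rq(2 * n) * (rq(2) * H ^ 2 - rq(3) * H - rq(2) * H2 + 3),
    E_Ssq = rq(4 * n ^ 2) * (H ^ 2 - H2 - rq(2) * H) - rq(2 * n) * H +
      rq(11 * n ^ 2 - n),
    E_V = rq(2 * (n + 1), n) * H + rq(1, n) - 5
  )
}

#' Closed-form moments of the depth indices under the uniform model
#'
#' Exact expectations under the uniform (PDA) model, in terms of
#' `r_n = (2n-2)!!/(2n-3)!! ~ sqrt(pi n)`:
#'
#' * `E_S = n(r_n - 1)`;
#' * `E_S2 = (4n-1)n - 3n r_n`;
#' * `E_Ssq = n(10n^2 - 1)/3 - n(5n+1)/2 * r_n`;
#' * `E_V = (2n-1)(n-1)/(3n) - (n-1)/(2n) * r_n`, which grows like `2n/3`.
#'
#' The identity `E_V = E_S2/n - E_Ssq/n^2` holds exactly.
#'
#' @param n leaf counts (vectorized).
#' @return A tibble with columns `n`, `E_S`, `E_S2`, `E_Ssq`, `E_V`.
#' @examples
#' uniform_moments(3:8)
#' @export
uniform_moments <- function(n) {
  r <- dfact_ratio(n)
  tibble(
    n = n,
    E_S = n * (r - 1),
    E_S2 = (4 * n - 1) * n - 3 * n * r,
    E_Ssq = n * (10 * n ^ 2 - 1) / 3 - n * (5 * n + 1) / 2 * r,
    E_V = (2 * n - 1) * (n - 1) / (3 * n) - (n - 1) / (2 * n) * r
  )
}

#' @rdname uniform_moments
#' @export
uniform_moments_exact <- function(n) {
  n <- check_count(n)
  r <- dfact_ratio(n, exact = TRUE)
  list(
    E_S = rq(n) * (r - 1),
    E_S2 = rq((4 * n - 1) * n) - rq(3 * n) * r,
    E_Ssq = rq(n * (10 * n ^ 2 - 1), 3) - rq(n * (5 * n + 1), 2) * r,
    E_V = rq((2 * n - 1) * (n - 1), 3 * n) - rq(n - 1, 2 * n) * r
  )
}

#' Variances and covariance of S and Phi under the uniform model
#'
#' Exact closed forms for the variance of the Sackin index `S_n`, the
#' variance of the total cophenetic index `Phi_n`, and their covariance
#' under the uniform model, with `r_n = (2n-2)!!/(2n-3)!!`:
#'
#' * `var_S = n(10n^2 - 3n - 1)/3 - choose(n+1,2) r_n - n^2 r_n^2`
#' * `var_Phi = choose(n,2)(2n-1)(7n^2-3n-2)/30
#'    - choose(n,2)(5n^2-n-2)/32 * r_n - choose(n,2)^2/4 * r_n^2`
#' * `cov_SPhi = choose(n,2)(26n^2-5n-4)/15
#'    - (3n+2)/8 choose(n,2) r_n - n/2 choose(n,2) r_n^2`
#'
#' Asymptotically `var_S ~ (10-3pi)/3 n^3`, `var_Phi ~ (56-15pi)/240 n^5`,
#' `cov_SPhi ~ (52-15pi)/60 n^4`, so the Pearson correlation of `S_n` and
#' `Phi_n` tends to a constant, approximately 0.965; see
#' [uniform_asymptotics()].
#'
#' @param n leaf counts (vectorized).
#' @return A tibble with columns `n`, `var_S`, `var_Phi`, `cov_SPhi`.
#' @examples
#' uniform_covariances(3:8)
#' @export
uniform_covariances <- function(n) {
  r <- dfact_ratio(n)
  c2 <- n * (n - 1) / 2
  out <- tibble(
    n = n,
    var_S = n * (10 * n ^ 2 - 3 * n - 1) / 3 - (n + 1) * n / 2 * r - n ^ 2 * r ^ 2,
    var_Phi = c2 * (2 * n - 1) * (7 * n ^ 2 - 3 * n - 2) / 30 -
      c2 * (5 * n ^ 2 - n - 2) / 32 * r - c2 ^ 2 / 4 * r ^ 2,
    cov_SPhi = c2 * (26 * n ^ 2 - 5 * n - 4) / 15 - (3 * n + 2) / 8 * c2 * r -
      n / 2 * c2 * r ^ 2
  )
  # small n: the three-term differences cancel catastrophically in doubles
  # (e.g. an exact 0 at n = 3); take the exact route there
  for (i in which(n <= 32)) {
    ex <- uniform_covariances_exact(n[i])
    out$var_S[i] <- as.numeric(ex$var_S)
    out$var_Phi[i] <- as.numeric(ex$var_Phi)
    out$cov_SPhi[i] <- as.numeric(ex$cov_SPhi)
  }
  out
}

#' @rdname uniform_covariances
#' @export
uniform_covariances_exact <- function(n) {
  n <- check_count(n)
  r <- dfact_ratio(n, exact = TRUE)
  c2 <- rq(n * (n - 1), 2)
  list(
    var_S = rq(n * (10 * n ^ 2 - 3 * n - 1), 3) - rq((n + 1) * n, 2) * r -
      rq(n ^ 2) * r ^ 2,
    var_Phi = c2 * rq((2 * n - 1) * (7 * n ^ 2 - 3 * n - 2), 30) -
      c2 * rq(5 * n ^ 2 - n - 2, 32) * r - rq(1, 4) * c2 ^ 2 * r ^ 2,
    cov_SPhi = c2 * rq(26 * n ^ 2 - 5 * n - 4, 15) - rq(3 * n + 2, 8) * c2 * r -
      rq(n, 2) * c2 * r ^ 2
  )
}

#' @rdname uniform_covariances
#' @return `uniform_asymptotics()`: a list with the three leading constants
#'   and the limiting Pearson correlation `rho_limit` of `S_n` and `Phi_n`.
#' @export
uniform_asymptotics <- function() {
  c_var_S <- (10 - 3 * pi) / 3
  c_var_Phi <- (56 - 15 * pi) / 240
  c_cov <- (52 - 15 * pi) / 60
  list(
    c_var_S = c_var_S,
    c_var_Phi = c_var_Phi,
    c_cov = c_cov,
    rho_limit = c_cov / sqrt(c_var_S * c_var_Phi)
  )
}

#' Combined moment table
#'
#' One row per `n` with the Yule and uniform expectations of `V`, and the
#' uniform-model variances and covariance of `S` and `Phi` -- the quantities
#' a model test standardizes against.
#'
#' @param n leaf counts (vectorized).
#' @return A tibble with columns `n`, `EY_V`, `EU_V`, `varU_S`, `varU_Phi`,
#'   `covU_SPhi`.
#' @examples
#' moment_table(3:8)
#' @export
moment_table <- function(n) {
  y <- yule_moments(n)
  u <- uniform_moments(n)
  v <- uniform_covariances(n)
  tibble(
    n = n,
    EY_V = y$E_V,
    EU_V = u$E_V,
    varU_S = v$var_S,
    varU_Phi = v$var_Phi,
    covU_SPhi = v$cov_SPhi
  )
}
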