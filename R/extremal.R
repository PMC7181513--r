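#' Maximum of the depth variance: the comb
#'
#' Over all rooted trees with `n` leaves (multifurcating included) the
#' variance of the leaves' depths is maximized exactly at the comb `K_n`,
#' whose depth multiset is `{1, 2, ..., n-2, n-1, n-1}`, giving the closed
#' form
#'
#'   `V(K_n) = (n-1)(n-2)(n^2 + 3n - 6) / (12 n^2)`.
#'
#' @param n leaf count.
#' @param exact return an exact [rq()] rational.
#' @return A double or an `rq`.
#' @examples
#' max_variance(3)  # 2/9
#' max_variance(8)  # 4.484375
#' @export
max_variance <- function(n, exact = FALSE) {
  n <- check_count(n)
  if (exact) {
    return(rq(n - 1) * rq(n - 2) * rq(n^2 + 3 * n - 6) / (rq(12) * rq(n)^2))
  }
  (n - 1) * (n - 2) * (n ^ 2 + 3 * n - 6) / (12 * n ^ 2)
}

floor_log2 <- function(n) {
  m <- floor(log2(n))
  if (2 ^ (m + 1) <= n) m <- m + 1
  if (2 ^ m > n) m <- m - 1
  m
}

#' Depth profile of a candidate type
#'
#' Resolves the depth multiset of the type `T_{n; l1..lj}`: writing
#' `n = 2^m + k` with `m = floor(log2 n)`, the counts `p1` (leaves at depth
#' `delta - 1`) and `p0` (at depth `delta`) and the tree depth `delta` fall
#' into one of four cases:
#'
#' 1. `k + sum(2^l - 1) == 0`: the fully symmetric tree (`p1 = 0`,
#'    `delta = m`);
#' 2. `0 < k + sum(2^l - 1) <= 2^m`: `p1 = 2^m - k - sum(2^l - 1)`,
#'    `delta = m + 1`;
#' 3. `k + sum(2^(l-1) - 1) > 2^m`: `p1 = 3*2^m - k - sum(2^l - 1)`,
#'    `delta = m + 2`;
#' 4. otherwise no bifurcating tree of that type exists (`feasible = FALSE`).
#'
#' @param n leaf count.
#' @param ls strictly increasing integer sequence of l-values (each >= 2);
#'   may be empty (the `F_n` type).
#' @return An object of class `type_profile`: a list with `n`, `ls`, `m`,
#'   `k`, `case`, `feasible`, `p0`, `p1`, `delta`.
#' @examples
#' type_profile(184, 6)      # p1 = 9, delta = 8
#' type_profile(64, c(5, 6)) # infeasible
#' @export
type_profile <- function(n, ls = integer(0)) {
  n <- check_count(n)
  ls <- as.double(ls)
  if (length(ls) > 0L) {
    if (any(ls != floor(ls)) || any(ls < 2) || any(diff(ls) <= 0)) {
      stop_data("`ls` must be a strictly increasing sequence of integers >= 2")
    }
    if (max(ls) > 50) stop_data("l-values above 50 are not supported")
  }
  m <- floor_log2(n)
  k <- n - 2 ^ m
  j <- length(ls)
  sum_full <- k + sum(2 ^ ls - 1)
  sum_half <- k + sum(2 ^ (ls - 1) - 1)
  out <- list(n = n, ls = as.integer(ls), m = m, k = k)
  if (sum_full == 0) {
    out <- c(out, list(case = 1L, feasible = TRUE, p0 = n, p1 = 0, delta = m))
  } else if (sum_full <= 2 ^ m) {
    p1 <- 2 ^ m - sum_full
    out <- c(out, list(case = 2L, feasible = TRUE, p0 = n - j - p1, p1 = p1,
                       delta = m + 1))
  } else if (sum_half > 2 ^ m) {
    p1 <- 3 * 2 ^ m - sum_full
    p0 <- n - j - p1
    if (p1 >= 0 && p0 > 0) {
      out <- c(out, list(case = 3L, feasible = TRUE, p0 = p0, p1 = p1, delta = m + 2))
    } else {
      out <- c(out, list(case = 3L, feasible = FALSE, p0 = NA_real_, p1 = NA_real_,
                         delta = NA_real_))
    }
  } else {
    out <- c(out, list(case = 4L, feasible = FALSE, p0 = NA_real_, p1 = NA_real_,
                       delta = NA_real_))
  }
  structure(out, class = "type_profile")
}

#' @export
print.type_profile <- function(x, ...) {
  ls <- if (length(x$ls) == 0L) "-" else paste(x$ls, collapse = ",")
  if (x$feasible) {
    cat(sprintf("<type T_{%d; %s}: delta = %d, p0 = %d, p1 = %d (case %d)>\n",
                x$n, ls, x$delta, x$p0, x$p1, x$case))
  } else {
    cat(sprintf("<type T_{%d; %s}: infeasible (case %d)>\n", x$n, ls, x$case))
  }
  invisible(x)
}

# depth multiset of a feasible type profile
type_depth_multiset <- function(profile) {
  if (!profile$feasible) stop_data("type is infeasible; it has no depth multiset")
  depths <- c(profile$delta - profile$ls, profile$delta - 1, profile$delta)
  counts <- c(rep(1, length(profile$ls)), profile$p1, profile$p0)
  dm_from_counts(depths, counts)
}

#' Depth variance of a candidate type
#'
#' The variance of the leaves' depths shared by every tree of type
#' `T_{n; l1..lj}`:
#'
#'   `V = ( n * (p1 + sum(l^2)) - (p1 + sum(l))^2 ) / n^2`
#'
#' with `p1` from [type_profile()].  The empty sequence gives the
#' minimal-Sackin value `V(F_n) = 2k(2^m - k) / n^2`.
#'
#' @inheritParams type_profile
#' @param exact return an exact [rq()] rational.
#' @return A double or an `rq`.
#' @examples
#' type_variance(184, 6)           # 8055/33856 ~ 0.2379
#' type_variance(184, integer(0))  # 8064/33856 ~ 0.2382
#' @export
type_variance <- function(n, ls = integer(0), exact = FALSE) {
  profile <- type_profile(n, ls)
  if (!profile$feasible) {
    stop_data("type T_{%d; %s} is infeasible", profile$n, paste(ls, collapse = ","))
  }
  if (profile$case == 1L) {
    return(if (exact) as_rq(0) else 0)
  }
  ls <- profile$ls
  num <- profile$n * (profile$p1 + sum(ls ^ 2)) - (profile$p1 + sum(ls)) ^ 2
  if (exact) rq(num, profile$n ^ 2) else num / profile$n ^ 2
}

# Vectorized tables over all l-subsets of {5, ..., m}; cached per m.
# Columns: j, sumL, sumL2, pow (sum of 2^l - 1), half (sum of 2^(l-1) - 1),
# and the decoded l-sequences.
lseq_table <- function(m) {
  key <- as.character(m)
  tbl <- .depthvar_env$lseq[[key]]
  if (!is.null(tbl)) return(tbl)
  j <- 0; sumL <- 0; sumL2 <- 0; pow <- 0; half <- 0
  ls <- list(integer(0))
  if (m >= 5) {
    for (l in 5:m) {
      j <- c(j, j + 1)
      sumL <- c(sumL, sumL + l)
      sumL2 <- c(sumL2, sumL2 + l ^ 2)
      pow <- c(pow, pow + 2 ^ l - 1)
      half <- c(half, half + 2 ^ (l - 1) - 1)
      ls <- c(ls, lapply(ls, function(v) c(v, as.integer(l))))
    }
  }
  tbl <- list(j = j, sumL = sumL, sumL2 = sumL2, pow = pow, half = half, ls = ls)
  if (is.null(.depthvar_env$lseq)) .depthvar_env$lseq <- list()
  .depthvar_env$lseq[[key]] <- tbl
  tbl
}

# core of the minimum search: exact integer numerators n^2 * V over all
# candidate types of BT_n; returns min numerator and argmin subset indices
min_variance_core <- function(n) {
  m <- floor_log2(n)
  k <- n - 2 ^ m
  tbl <- lseq_table(m)
  sum_full <- k + tbl$pow
  sum_half <- k + tbl$half
  p1 <- rep(NA_real_, length(sum_full))
  case1 <- sum_full == 0
  case2 <- !case1 & sum_full <= 2 ^ m
  case3 <- sum_full > 2 ^ m & sum_half > 2 ^ m
  p1[case2] <- 2 ^ m - sum_full[case2]
  p1[case3] <- 3 * 2 ^ m - sum_full[case3]
  p0 <- n - tbl$j - p1
  feasible <- case1 | ((case2 | case3) & !is.na(p1) & p1 >= 0 & p0 > 0)
  num <- n * (p1 + tbl$sumL2) - (p1 + tbl$sumL) ^ 2
  num[case1] <- 0
  num[!feasible] <- Inf
  min_num <- min(num)
  list(m = m, k = k, min_num = min_num, argmin = which(num == min_num),
       num = num, feasible = feasible, tbl = tbl)
}

#' Minimum of the depth variance over bifurcating trees
#'
#' Finds the minimum value of the depth variance V over all bifurcating
#' rooted trees with `n` leaves, and all candidate types attaining it.  By
#' the characterization of minimum-V trees, any minimizer is of some type
#' `T_{n; l1..lj}` with `5 <= l1 < ... < lj <= floor(log2 n)`, so the search
#' enumerates all `2^(m-4)` l-subsets (including the empty one, the
#' maximally balanced class), skips infeasible ones, and compares exact
#' integer numerators `n^2 V` -- no floating point, so ties are exact and all
#' co-minimizers are reported.  Total work is `O(n log n)`.
#'
#' For every `n <= 183` the minimum is attained at the maximally balanced
#' class (empty l-sequence); `n = 184` is the first leaf count where it is
#' not.
#'
#' @param n leaf count.
#' @return An object of class `min_variance`: list with `n`, `m`, `k`,
#'   `min_num` (the integer `n^2 V`), `min_value` (double), `argmin` (list
#'   of integer l-sequences), `n_feasible`.  Methods: [tidy()], [glance()],
#'   `print()`, and `min_variance_exact()` for the `rq` value.
#' @examples
#' min_variance(8)     # 0, attained at the fully symmetric tree
#' min_variance(184)   # 8055/33856, attained at type (6)
#' @export
min_variance <- function(n) {
  n <- check_count(n)
  core <- min_variance_core(n)
  structure(
    list(n = n, m = core$m, k = core$k, min_num = core$min_num, den = n ^ 2,
         min_value = core$min_num / n ^ 2,
         argmin = core$tbl$ls[core$argmin],
         n_feasible = sum(core$feasible)),
    class = "min_variance"
  )
}

#' @rdname min_variance
#' @param x a `min_variance` object.
#' @export
min_variance_exact <- function(x) {
  stopifnot(inherits(x, "min_variance"))
  rq(x$min_num, x$den)
}

format_ls <- function(ls) {
  if (length(ls) == 0L) "-" else paste(ls, collapse = ";")
}

#' @export
print.min_variance <- function(x, ...) {
  cat(sprintf("Minimum depth variance on bifurcating trees with n = %d leaves\n", x$n))
  cat(sprintf("  min V = %s = %.6g\n", as.character(min_variance_exact(x)), x$min_value))
  cat(sprintf("  attained at type(s): %s\n",
              paste(vapply(x$argmin, format_ls, ""), collapse = " | ")))
  cat(sprintf("  (maximally balanced class %s optimal)\n",
              if (any(lengths(x$argmin) == 0L)) "is" else "is NOT"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.min_variance <- function(x, ...) {
  tibble(
    n = x$n,
    ls = vapply(x$argmin, format_ls, ""),
    j = lengths(x$argmin),
    V_num = x$min_num,
    V_den = x$den,
    V = x$min_value
  )
}

#' @exportS3Method generics::glance
glance.min_variance <- function(x, ...) {
  tibble(
    n = x$n, m = x$m, k = x$k, min_V = x$min_value,
    n_argmin = length(x$argmin),
    is_max_balanced = any(lengths(x$argmin) == 0L)
  )
}

#' Scan the minimum depth variance over a range of leaf counts
#'
#' Runs [min_variance()] for every `n` in `[n_lo, n_hi]` and returns a tidy
#' per-`n` table.  Companion summaries: [balanced_fraction()] (the share of
#' `n` whose minimum is attained at the maximally balanced class),
#' [first_unbalanced()] (the smallest such `n` that is not), and
#' [argmin_runs()] (run lengths of constant optimal l-sequence, scanning each
#' dyadic block `[2^m, 2^(m+1))` in descending `n`, the order in which the
#' runs show their regular pattern).
#'
#' @param n_lo,n_hi range of leaf counts, `2 <= n_lo <= n_hi`.
#' @return A tibble of class `depthvar_scan` with columns `n`, `m`, `k`,
#'   `min_V_num`, `min_V_den` (reduced exact fraction), `min_V`,
#'   `argmin_ls` (semicolon-joined; `-` for the empty sequence; ties joined
#'   with `|`), `n_argmin`, `is_max_balanced`.
#' @examples
#' scan_min_variance(180, 190)
#' @export
scan_min_variance <- function(n_lo, n_hi) {
  n_lo <- check_count(n_lo)
  n_hi <- check_count(n_hi)
  if (n_lo < 2 || n_lo > n_hi) stop_data("need 2 <= n_lo <= n_hi")
  ns <- as.integer(seq(n_lo, n_hi))
  len <- length(ns)
  m <- integer(len); k <- numeric(len)
  num <- numeric(len); den <- numeric(len)
  rnum <- numeric(len); rden <- numeric(len)
  argmin_chr <- character(len); n_argmin <- integer(len); balanced <- logical(len)
  for (i in seq_len(len)) {
    n <- ns[i]
    core <- min_variance_core(n)
    m[i] <- core$m; k[i] <- core$k
    num[i] <- core$min_num; den[i] <- n ^ 2
    g <- gcd_num(core$min_num, n ^ 2)
    rnum[i] <- core$min_num / g; rden[i] <- n ^ 2 / g
    amins <- core$tbl$ls[core$argmin]
    argmin_chr[i] <- paste(vapply(amins, format_ls, ""), collapse = "|")
    n_argmin[i] <- length(amins)
    balanced[i] <- any(lengths(amins) == 0L)
  }
  out <- tibble(
    n = ns, m = m, k = k, min_V_num = rnum, min_V_den = rden,
    min_V = num / den, argmin_ls = argmin_chr, n_argmin = n_argmin,
    is_max_balanced = balanced
  )
  class(out) <- c("depthvar_scan", class(out))
  out
}

#' @rdname scan_min_variance
#' @param scan a `depthvar_scan` tibble.
#' @export
balanced_fraction <- function(scan) {
  mean(scan$is_max_balanced)
}

#' @rdname scan_min_variance
#' @export
first_unbalanced <- function(scan) {
  hit <- scan$n[!scan$is_max_balanced]
  if (length(hit) == 0L) NA_real_ else as.numeric(min(hit))
}

#' @rdname scan_min_variance
#' @export
argmin_runs <- function(scan) {
  blocks <- split(seq_len(nrow(scan)), scan$m)
  rows <- lapply(blocks, function(idx) {
    idx <- rev(idx)  # descending n within the dyadic block
    r <- rle(scan$argmin_ls[idx])
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    tibble(
      m = scan$m[idx[1]],
      from_n = scan$n[idx[starts]],
      to_n = scan$n[idx[ends]],
      length = r$lengths,
      ls = r$values
    )
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method ggplot2::autoplot
autoplot.depthvar_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$min_V,
                                       colour = .data$is_max_balanced)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "#2c3e50"),
      name = "min at B_n"
    ) +
    ggplot2::labs(x = "number of leaves n", y = "minimum depth variance V") +
    ggplot2::theme_minimal()
}
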