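#' Exact rational numbers
#'
#' A minimal exact rational scalar built on the package's big-integer layer.
#' All index values and model moments in this package are rationals, and `rq`
#' keeps them exact regardless of magnitude; doubles appear only at output
#' boundaries.  `rq` objects support `+`, `-`, `*`, `/`, `^` (integer powers)
#' and comparisons, mixing freely with integer-valued numerics.
#'
#' @param num numerator: an integer-valued numeric, or another `rq`.
#' @param den denominator (nonzero integer-valued numeric).
#' @return An object of class `rq`.
#' @examples
#' rq(8055, 33856)
#' as.numeric(rq(1, 3) + rq(1, 6))
#' @export
rq <- function(num, den = 1) {
  if (inherits(num, "rq")) {
    if (!identical(den, 1)) num <- num / rq(den)
    return(num)
  }
  new_rq(as_bi(num), as_bi(den))
}

new_rq <- function(num, den) {
  if (bi_is_zero(den)) stop_data("rational with zero denominator")
  if (den$s < 0L) {
    num <- bi_neg(num)
    den <- bi_neg(den)
  }
  if (bi_is_zero(num)) return(structure(list(num = bi_zero(), den = bi_one()), class = "rq"))
  g <- bi_gcd(num, den)
  if (!(length(g$m) == 1L && g$m[1] == 1)) {
    num <- bi(num$s, bi_divmod(bi(1L, num$m), g)$q$m)
    den <- bi_divmod(den, g)$q
  }
  structure(list(num = num, den = den), class = "rq")
}

is_rq <- function(x) inherits(x, "rq")

as_rq <- function(x) if (is_rq(x)) x else rq(x)

q_add <- function(a, b) new_rq(bi_add(bi_mul(a$num, b$den), bi_mul(b$num, a$den)),
                               bi_mul(a$den, b$den))
q_mul <- function(a, b) new_rq(bi_mul(a$num, b$num), bi_mul(a$den, b$den))
q_div <- function(a, b) {
  if (bi_is_zero(b$num)) stop_data("rational division by zero")
  new_rq(bi_mul(a$num, b$den), bi_mul(a$den, b$num))
}
q_neg <- function(a) structure(list(num = bi_neg(a$num), den = a$den), class = "rq")

# exact comparison by cross-multiplication (no reduction needed)
q_cmp <- function(a, b) bi_cmp(bi_mul(a$num, b$den), bi_mul(b$num, a$den))

#' @export
Ops.rq <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(q_neg(as_rq(e1)))
    if (.Generic == "+") return(as_rq(e1))
    stop_usage("unary %s not defined for rq", .Generic)
  }
  if (.Generic == "^") {
    a <- as_rq(e1)
    k <- e2
    if (!is.numeric(k) || k != floor(k)) stop_usage("rq powers must be integers")
    if (k < 0) return(q_div(as_rq(1), a ^ (-k)))
    return(structure(list(num = bi_pow_small(a$num, k), den = bi_pow_small(a$den, k)),
                     class = "rq"))
  }
  a <- as_rq(e1)
  b <- as_rq(e2)
  switch(.Generic,
    "+" = q_add(a, b),
    "-" = q_add(a, q_neg(b)),
    "*" = q_mul(a, b),
    "/" = q_div(a, b),
    "==" = q_cmp(a, b) == 0L,
    "!=" = q_cmp(a, b) != 0L,
    "<"  = q_cmp(a, b) < 0L,
    "<=" = q_cmp(a, b) <= 0L,
    ">"  = q_cmp(a, b) > 0L,
    ">=" = q_cmp(a, b) >= 0L,
    stop_usage("operation %s not defined for rq", .Generic)
  )
}

#' @export
as.double.rq <- function(x, ...) {
  if (bi_is_zero(x$num)) return(0)
  # top-limb approximations with limb exponents, so huge values never overflow
  approx <- function(b) {
    k <- length(b$m)
    take <- min(3L, k)
    v <- 0
    for (i in seq(k, k - take + 1L)) v <- v * .BI_BASE + b$m[i]
    list(v = v, e = k - take)
  }
  an <- approx(x$num)
  ad <- approx(x$den)
  x$num$s * (an$v / ad$v) * .BI_BASE ^ (an$e - ad$e)
}

#' @export
as.character.rq <- function(x, ...) {
  if (length(x$den$m) == 1L && x$den$m[1] == 1) bi_to_string(x$num)
  else paste0(bi_to_string(x$num), "/", bi_to_string(x$den))
}

#' @export
format.rq <- function(x, ...) as.character(x)

#' @export
print.rq <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

# sum a list of rq
q_sum <- function(xs) Reduce(q_add, xs, as_rq(0))

# convenience: exact binomial coefficient as rq
q_binom <- function(n, k) {
  if (k < 0 || k > n) return(as_rq(0))
  row <- bi_binom_row(n)
  structure(list(num = row[[k + 1L]], den = bi_one()), class = "rq")
}
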