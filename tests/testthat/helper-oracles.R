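# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational routes.

# population variance of a vector of leaf depths, straight from the definition
variance_oracle <- function(depths) {
  mean(depths^2) - mean(depths)^2
}

# Wedderburn-Etherington counts of bifurcating shapes by leaf number,
# a(n) = sum_{i < n/2} a(i) a(n-i)  (+ choose(a(n/2)+1, 2) when n even)
wedderburn_counts <- function(n_max) {
  a <- numeric(n_max)
  a[1] <- 1
  for (n in 2:n_max) {
    tot <- 0
    for (i in seq_len((n - 1) %/% 2)) tot <- tot + a[i] * a[n - i]
    if (n %% 2 == 0) tot <- tot + a[n / 2] * (a[n / 2] + 1) / 2
    a[n] <- tot
  }
  a
}

# all leaf-depth multisets realizable by a bifurcating tree with n leaves,
# via bottom-up multiset merging (independent of the package's enumeration);
# each multiset is returned once as a sorted depth vector
realizable_multisets <- function(n) {
  memo <- list()
  gen <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 1) {
      list(0L)
    } else {
      seen <- new.env(parent = emptyenv())
      res <- list()
      for (k in seq_len(n %/% 2)) {
        for (da in gen(k)) {
          for (db in gen(n - k)) {
            d <- sort(c(da + 1L, db + 1L))
            id <- paste(d, collapse = ",")
            if (is.null(seen[[id]])) {
              seen[[id]] <- TRUE
              res[[length(res) + 1L]] <- d
            }
          }
        }
      }
      res
    }
    memo[[key]] <<- out
    out
  }
  gen(n)
}

# total cophenetic index through ape: with unit branch lengths, the
# phylogenetic covariance of two leaves is the depth of their LCA
phi_vcv_oracle <- function(phy) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  v <- ape::vcv(phy)
  sum(v[upper.tri(v)])
}

# double factorial (2n-3)!! as a plain double
dfact_odd_oracle <- function(n) {
  k <- 2 * n - 3
  if (k < 3) 1 else prod(seq(3, k, by = 2))
}

# depth multiset of a shape as a plain sorted vector
dm_vec <- function(x) {
  d <- depth_multiset(x)
  rep(d$depth, d$count)
}
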