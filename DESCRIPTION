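Package: depthvar
Title: Variance of Leaf Depths as a Phylogenetic Tree Balance Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the variance of the leaves' depths (V) of a
    rooted phylogenetic tree as a shape and balance index.  Computes V, the
    Sackin index S, the sum of squared depths, and the total cophenetic index
    in exact arithmetic; characterizes and searches for the bifurcating trees
    with n leaves that minimize V in O(n log n) via depth-equivalence classes;
    provides the closed-form maximum (the comb); exact closed-form expectations
    of V under the Yule and uniform (PDA) models, exact variances of S and the
    total cophenetic index and their covariance under the uniform model; exact
    samplers for both models; and exhaustive enumeration of bifurcating tree
    shapes as an independent verification oracle.  Includes a small exact
    big-integer and rational arithmetic layer so all index values and moments
    are computed without floating-point error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    optparse,
    readr,
    rlang,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
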