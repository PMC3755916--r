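# Closed-form approximations for segment counts and lengths on a single
# chromosome of map length l Morgans, and the Poisson-approximate
# likelihood built on the count formulas.
#
# Collateral (cousin-type) relationships follow the count formula
#   E(n_s) = a (d l + 1) (1/2)^(d-1)
# with a ancestors and d meioses; lineal chains use
#   E(n_s) = [(d-1) l + 1] (1/2)^(d-1)
# (recombination in the final meiosis to the parent does not break sharing
# with the grandparental genome).  The avuncular cases, where one endpoint
# is a diploid sib, follow neither: E(n_s) = (5l+2)/4 for uncle-nephew and
# (7l+2)/8 for great-uncle-great-nephew.

#' Expected number of shared segments (closed form)
#'
#' @param rel Relationship abbreviation or [relationship()] spec.
#' @param l Chromosome map length in Morgans.
#' @return Expected segment count, with attribute `"formula"` naming the
#'   dispatch used (`"collateral"`, `"lineal"`, `"UN"` or `"GUGN"`).
#' @examples
#' expected_num_segments("C", 1.632)    # 1.882
#' expected_num_segments("GPO", 1.632)  # 1.316
#' @export
expected_num_segments <- function(rel, l) {
  rel <- relationship(rel)
  stopifnot(is.finite(l), l > 0)
  d <- rel$d
  if (rel$abbrev == "UN") {
    out <- (5 * l + 2) / 4
    id <- "UN"
  } else if (rel$abbrev == "GUGN") {
    out <- (7 * l + 2) / 8
    id <- "GUGN"
  } else if (rel$base == "lineal") {
    out <- ((d - 1) * l + 1) * 0.5^(d - 1)
    id <- "lineal"
  } else {
    out <- rel$a * (d * l + 1) * 0.5^(d - 1)
    id <- "collateral"
  }
  structure(out, formula = id)
}

#' Expected length of an individual shared segment (closed form)
#'
#' Accounts for the finite chromosome: the mean total shared length `2R l`
#' partitioned over the expected number of segments gives `l/(dl+1)` -- not
#' the infinite-chromosome `1/d` -- for cousin-type and lineal
#' relationships.  For the avuncular cases the per-segment expectations are
#' `2l/(5l+2)` (UN) and `2l/(7l+2)` (GUGN).
#'
#' @inheritParams expected_num_segments
#' @return Expected individual segment length in Morgans.
#' @examples
#' expected_segment_length("HS", 1.632)  # 0.383 M
#' @export
expected_segment_length <- function(rel, l) {
  rel <- relationship(rel)
  stopifnot(is.finite(l), l > 0)
  if (rel$abbrev == "UN") return(2 * l / (5 * l + 2))
  if (rel$abbrev == "GUGN") return(2 * l / (7 * l + 2))
  l / (rel$d * l + 1)
}

#' Expected total shared length (closed form)
#'
#' The expected proportion of the (uniparental) genome shared is `2R`, so
#' the expected total shared length on a chromosome is `2 R l` Morgans.
#' For cousin-type relationships this equals
#' [expected_num_segments()] times [expected_segment_length()].
#'
#' @inheritParams expected_num_segments
#' @return Expected total shared length in Morgans.
#' @export
expected_total_shared <- function(rel, l) {
  rel <- relationship(rel)
  stopifnot(is.finite(l), l > 0)
  2 * rel$R * l
}

#' Poisson-approximate log-likelihood-ratio moments
#'
#' The simple route to likelihoods without simulation: assume the number of
#' shared segments is Poisson with mean given by the closed-form
#' [expected_num_segments()], and score lambda(true : hyp) from `n_s` only.
#' Moments are nonetheless taken over the *actual* (simulated) frequency
#' distribution of `n_s` under the true relationship, so the comparison
#' isolates the cost of the Poisson shape assumption.
#'
#' @inheritParams lr_moments
#' @return An `"lr_moments"` object with `method = "poisson"`.
#' @export
poisson_lr_moments <- function(fit, true, hyp) {
  stopifnot(inherits(fit, "ibd_fit"))
  specs <- fit$genome$specs
  K <- c(k1 = 0, k2 = 0, k3 = 0, k4 = 0)
  detail <- list()
  for (i in seq_len(nrow(specs))) {
    l <- specs$length_M[i]
    cnt <- specs$count[i]
    muA <- as.numeric(expected_num_segments(true, l))
    muB <- as.numeric(expected_num_segments(hyp, l))
    w <- dist_probs(get_dist(fit, true, l), "ns")
    ns <- w$code  # "ns" codes are the raw counts
    lam <- dpois(ns, muA, log = TRUE) - dpois(ns, muB, log = TRUE)
    p <- w$prob
    k1 <- sum(p * lam)
    m2 <- sum(p * (lam - k1)^2)
    m3 <- sum(p * (lam - k1)^3)
    m4 <- sum(p * (lam - k1)^4)
    K <- K + cnt * c(k1 = k1, k2 = m2, k3 = m3, k4 = m4 - 3 * m2^2)
    detail[[i]] <- data.frame(length_M = l, count = cnt, mean = k1, var = m2)
  }
  sd <- sqrt(K[["k2"]])
  structure(list(
    true = true, hyp = hyp, use = "ns",
    mean = K[["k1"]], sd = sd,
    skew = if (sd > 0) K[["k3"]] / K[["k2"]]^1.5 else NA_real_,
    ex_kurtosis = if (sd > 0) K[["k4"]] / K[["k2"]]^2 else NA_real_,
    ratio = if (sd > 0) K[["k1"]] / sd else NA_real_,
    n_zero_cell = 0L,
    per_length = do.call(rbind, detail),
    genome = fit$genome$name, N = fit$N, method = "poisson"),
    class = "lr_moments")
}
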