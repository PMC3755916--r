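# Log-likelihood ratios and their moments.
#
# For an outcome k on one chromosome the contribution to the log-likelihood
# ratio for relationships A vs B is ln P_A(k) - ln P_B(k), with the
# empirical probabilities taken as estimated.  Zero-cell rule: if one
# distribution's estimate is zero while the other's is positive, the zero is
# replaced by 1/(2N) of that distribution; if both are zero the outcome is
# uninformative and contributes 0 (with a warning when scoring observed
# data).  Natural logarithms throughout; values are in nats.

# per-chromosome cumulants of lambda(A:B) under the true distribution A
chrom_lr_cumulants <- function(distA, distB, use) {
  a <- dist_probs(distA, use)
  b <- dist_probs(distB, use)
  m <- merge(a[, c("code", "prob")], b[, c("code", "prob")],
             by = "code", all = TRUE, suffixes = c("_a", "_b"))
  pa <- m$prob_a; pa[is.na(pa)] <- 0
  pb <- m$prob_b; pb[is.na(pb)] <- 0
  w <- pa > 0
  nsub <- sum(pb[w] == 0)
  lam <- log(pa[w]) - log(ifelse(pb[w] == 0, 1 / (2 * distB$N), pb[w]))
  p <- pa[w]
  k1 <- sum(p * lam)
  m2 <- sum(p * (lam - k1)^2)
  m3 <- sum(p * (lam - k1)^3)
  m4 <- sum(p * (lam - k1)^4)
  c(k1 = k1, k2 = m2, k3 = m3, k4 = m4 - 3 * m2^2, nsub = nsub)
}

#' Moments of the genome-wide log-likelihood ratio
#'
#' Computes the mean (the directed Kullback-Leibler distance), SD, skew and
#' excess kurtosis of the log-likelihood ratio lambda(true : hyp) under the
#' true relationship's distribution, for a whole genome model.  Per-length
#' moments are evaluated over the empirical outcome distribution and
#' aggregated across (independent) chromosomes by summing cumulants; skew
#' and excess kurtosis follow from the summed cumulants.
#'
#' @param fit An [ibd_fit()] containing both relationships.
#' @param true,hyp Relationship abbreviations: the real relationship (whose
#'   distribution weights the expectation) and the hypothesized alternative.
#' @param use Information level: `"ns"` (segment numbers only), `"nsps"`
#'   (numbers and end positions) or `"nspsts"` (numbers, positions and
#'   length tenths; the default, with tenths used only for 1 <= n_s <= 4).
#' @return Object of class `"lr_moments"`: list with `mean`, `sd`, `skew`,
#'   `ex_kurtosis`, `ratio` (= mean/SD, `NA` when SD is 0), `n_zero_cell`
#'   (zero-cell substitutions used) and a `per_length` detail table.
#' @examples
#' \donttest{
#' fit <- ibd_fit("equal22", c("UN", "HS"), nrep = 20000, seed = 1)
#' lr_moments(fit, "UN", "HS")$mean  # KL distance, nats
#' }
#' @export
lr_moments <- function(fit, true, hyp, use = c("nspsts", "nsps", "ns")) {
  stopifnot(inherits(fit, "ibd_fit"))
  use <- match.arg(use)
  specs <- fit$genome$specs
  K <- c(k1 = 0, k2 = 0, k3 = 0, k4 = 0)
  nsub <- 0
  detail <- list()
  for (i in seq_len(nrow(specs))) {
    l <- specs$length_M[i]
    cnt <- specs$count[i]
    kk <- chrom_lr_cumulants(get_dist(fit, true, l), get_dist(fit, hyp, l), use)
    K <- K + cnt * kk[c("k1", "k2", "k3", "k4")]
    nsub <- nsub + cnt * kk[["nsub"]]
    detail[[i]] <- data.frame(length_M = l, count = cnt,
                              mean = kk[["k1"]], var = kk[["k2"]])
  }
  sd <- sqrt(K[["k2"]])
  structure(list(
    true = true, hyp = hyp, use = use,
    mean = K[["k1"]], sd = sd,
    skew = if (sd > 0) K[["k3"]] / K[["k2"]]^1.5 else NA_real_,
    ex_kurtosis = if (sd > 0) K[["k4"]] / K[["k2"]]^2 else NA_real_,
    ratio = if (sd > 0) K[["k1"]] / sd else NA_real_,
    n_zero_cell = nsub,
    per_length = do.call(rbind, detail),
    genome = fit$genome$name, N = fit$N, method = "empirical"),
    class = "lr_moments")
}

#' @export
print.lr_moments <- function(x, ...) {
  cat(sprintf("Log-likelihood ratio lambda(%s : %s), %s, genome %s [%s]\n",
              x$true, x$hyp, x$use, x$genome, x$method))
  cat(sprintf("  E = %.3f nats, SD = %.3f, E/SD = %s, skew = %.3f, ex.kurt = %.3f\n",
              x$mean, x$sd,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$skew, x$ex_kurtosis))
  if (x$n_zero_cell > 0)
    cat("  zero-cell substitutions used:", x$n_zero_cell, "\n")
  invisible(x)
}

#' Per-chromosome log-likelihood-ratio contribution of one outcome
#'
#' Scores a single observed outcome against two empirical distributions of
#' the same chromosome length: `ln P_A(k) - ln P_B(k)` with the zero-cell
#' substitution `1/(2N)` applied to whichever distribution estimates zero
#' while the other is positive.  An outcome never seen under either
#' distribution is uninformative: it contributes 0 with a warning.
#'
#' @param key Outcome: a [summarize_sharing()] result, or a list/vector with
#'   `n_s` and (as available) `p_s`, `t_s`.
#' @param distA,distB [empirical_distribution()] objects (same length).
#' @param use Information level; defaults to the coarsest level the two
#'   distributions support.
#' @return Log-likelihood ratio in nats.
#' @export
chrom_loglr <- function(key, distA, distB, use = NULL) {
  stopifnot(inherits(distA, "ibd_distribution"),
            inherits(distB, "ibd_distribution"))
  if (distA$l != distB$l)
    stop("distributions are for different chromosome lengths")
  lv <- c(ns = 1L, nsps = 2L, nspsts = 3L)
  if (is.null(use))
    use <- names(lv)[min(lv[[distA$use]], lv[[distB$use]])]
  code <- marginalize_code(key_code(key$n_s,
                                    if (!is.null(key$p_s)) key$p_s else NA,
                                    if (!is.null(key$t_s)) key$t_s else NA),
                           use)
  a <- dist_counts(distA, use)
  b <- dist_counts(distB, use)
  ca <- a$count[match(code, a$code)]
  cb <- b$count[match(code, b$code)]
  pa <- if (is.na(ca) || ca == 0L) 0 else ca / distA$N
  pb <- if (is.na(cb) || cb == 0L) 0 else cb / distB$N
  if (pa == 0 && pb == 0) {
    warning("outcome never observed under either distribution; ",
            "uninformative, contributes 0")
    return(0)
  }
  if (pa == 0) pa <- 1 / (2 * distA$N)
  if (pb == 0) pb <- 1 / (2 * distB$N)
  log(pa) - log(pb)
}

#' Genome-wide log-likelihood ratio of an outcome profile
#'
#' Sums per-chromosome contributions ([chrom_loglr()]) over a profile of
#' outcomes, using the distributions in a fitted bank.  Independent
#' segregation across chromosomes makes the genome-level log-likelihood
#' ratio additive.
#'
#' @param profile Data frame with one row per chromosome: `length_M` plus
#'   outcome columns `n_s`, `p_s`, `t_s`.  An empty profile scores 0.
#' @param fit An [ibd_fit()] holding distributions for every length in the
#'   profile.
#' @param true,hyp Relationship abbreviations (A and B).
#' @inheritParams lr_moments
#' @return Total log-likelihood ratio (nats), with attribute
#'   `"n_uninformative"` counting outcomes unseen under both distributions.
#' @export
genome_loglr <- function(profile, fit, true, hyp,
                         use = c("nspsts", "nsps", "ns")) {
  use <- match.arg(use)
  if (is.null(profile) || nrow(profile) == 0L)
    return(structure(0, n_uninformative = 0L))
  tot <- 0
  n_unin <- 0L
  for (i in seq_len(nrow(profile))) {
    l <- profile$length_M[i]
    key <- list(n_s = profile$n_s[i],
                p_s = if ("p_s" %in% names(profile)) profile$p_s[i] else NA,
                t_s = if ("t_s" %in% names(profile)) profile$t_s[i] else NA)
    lam <- withCallingHandlers(
      chrom_loglr(key, get_dist(fit, true, l), get_dist(fit, hyp, l), use),
      warning = function(w) {
        n_unin <<- n_unin + 1L
        invokeRestart("muffleWarning")
      })
    tot <- tot + lam
  }
  structure(tot, n_uninformative = n_unin)
}

#' Normal-approximation misclassification probabilities
#'
#' For discrimination by the sign of the log-likelihood ratio between
#' relationships A and B, assuming lambda is normal under each truth, the
#' probability of misassignment is `Phi(-m_A/s_A)` when A is true (we then
#' wrongly choose B) and `Phi(-m_B/s_B)` when B is true, where `m_A/s_A` is
#' the mean/SD ratio of lambda(A:B) under A and `m_B/s_B` that of
#' lambda(B:A) under B.
#'
#' @param momentsAB [lr_moments()] for lambda(A:B) under truth A.
#' @param momentsBA [lr_moments()] for lambda(B:A) under truth B.
#' @return Named numeric vector `c(truth_A = Phi(-m_A/s_A),
#'   truth_B = Phi(-m_B/s_B))`.
#' @examples
#' pnorm(-2.22)  # ~0.013, the scale of values returned
#' @export
misclassification_prob <- function(momentsAB, momentsBA) {
  stopifnot(inherits(momentsAB, "lr_moments"), inherits(momentsBA, "lr_moments"))
  if (momentsAB$sd <= 0 || momentsBA$sd <= 0)
    stop("misclassification probabilities need positive SD of lambda")
  c(truth_A = pnorm(-momentsAB$ratio), truth_B = pnorm(-momentsBA$ratio))
}

# lambda lookup tables per length class for a relationship pair: both
# probabilities floored at 1/(2N) so the table serves both directions
# (lambda(B:A) = -lambda(A:B) on the union support).
lambda_tables <- function(fit, relA, relB, use) {
  specs <- fit$genome$specs
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    l <- specs$length_M[i]
    dA <- get_dist(fit, relA, l)
    dB <- get_dist(fit, relB, l)
    a <- dist_probs(dA, use)
    b <- dist_probs(dB, use)
    m <- merge(a[, c("code", "prob")], b[, c("code", "prob")],
               by = "code", all = TRUE, suffixes = c("_a", "_b"))
    pa <- m$prob_a; pa[is.na(pa)] <- 1 / (2 * dA$N)
    pb <- m$prob_b; pb[is.na(pb)] <- 1 / (2 * dB$N)
    out[[i]] <- list(l = l, count = specs$count[i], code = m$code,
                     lam = log(pa) - log(pb))
  }
  out
}

# simulate M genome profiles under rel and return the per-genome summed
# lambda read off the lookup tables (sign = +1 scores lambda(A:B), -1
# scores lambda(B:A) from the same tables)
sim_genome_lambda <- function(fit, rel, tabs, M, sign = 1) {
  tot <- numeric(M)
  for (tb in tabs) {
    sim <- simulate_sharing(rel, tb$l, M * tb$count)
    code <- marginalize_code(key_code(sim$n_s, sim$p_s, sim$t_s),
                             attr(tabs, "use"))
    lam <- tb$lam[match(code, tb$code)]
    lam[is.na(lam)] <- 0  # unseen under both banks: uninformative
    tot <- tot + colSums(matrix(lam, nrow = tb$count, ncol = M))
  }
  sign * tot
}

#' Held-out assignment experiment between two relationships
#'
#' Simulates `M` fresh genome profiles under each of two relationships
#' (independently of the replicates that built the distribution bank) and
#' classifies each by the sign of the genome-wide log-likelihood ratio.
#' Ties (lambda exactly 0) count one half.
#'
#' @inheritParams lr_moments
#' @param relA,relB The two relationships to discriminate.
#' @param M Held-out genomes per truth.
#' @param seed Optional seed for the held-out stream (keep it different from
#'   the seed that built `fit` to avoid optimistic reuse of replicates).
#' @return Object of class `"assignment_experiment"`: list with
#'   `rate_true_A` (fraction of truth-A genomes with lambda(A:B) > 0),
#'   `rate_true_B`, and `mean_rate`.
#' @export
assignment_experiment <- function(fit, relA, relB, M = 1e4,
                                  use = c("nspsts", "nsps", "ns"),
                                  seed = NULL) {
  use <- match.arg(use)
  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tabs <- lambda_tables(fit, relA, relB, use)
  attr(tabs, "use") <- use
  lamA <- sim_genome_lambda(fit, relA, tabs, M, sign = 1)
  lamB <- sim_genome_lambda(fit, relB, tabs, M, sign = -1)
  rateA <- mean(lamA > 0) + 0.5 * mean(lamA == 0)
  rateB <- mean(lamB > 0) + 0.5 * mean(lamB == 0)
  structure(list(relA = relA, relB = relB, M = M, use = use,
                 rate_true_A = rateA, rate_true_B = rateB,
                 mean_rate = (rateA + rateB) / 2),
            class = "assignment_experiment")
}

#' @export
print.assignment_experiment <- function(x, ...) {
  cat(sprintf("Assignment by sign of lambda, %s vs %s (M = %d per truth, %s)\n",
              x$relA, x$relB, x$M, x$use))
  cat(sprintf("  correct | truth %s: %.3f\n", x$relA, x$rate_true_A))
  cat(sprintf("  correct | truth %s: %.3f\n", x$relB, x$rate_true_B))
  cat(sprintf("  mean correct-assignment rate: %.3f\n", x$mean_rate))
  invisible(x)
}

#' Sample the standardized genome-wide log-likelihood ratio
#'
#' Draws `M` fresh genome-level values of lambda(true : hyp) under the true
#' relationship and returns them divided by SD(lambda) from [lr_moments()],
#' for histogram or normality reporting.  When `true == hyp` all values are
#' exactly 0.
#'
#' @inheritParams assignment_experiment
#' @param true,hyp Relationship abbreviations.
#' @return Numeric vector of class `"lr_sample"` with the [lr_moments()]
#'   object attached as attribute `"moments"`.
#' @export
lr_sample <- function(fit, true, hyp, M = 1e4,
                      use = c("nspsts", "nsps", "ns"), seed = NULL) {
  use <- match.arg(use)
  M <- as.integer(M)
  if (!is.null(seed)) set.seed(seed)
  mom <- lr_moments(fit, true, hyp, use)
  tabs <- lambda_tables(fit, true, hyp, use)
  attr(tabs, "use") <- use
  lam <- sim_genome_lambda(fit, true, tabs, M, sign = 1)
  z <- if (mom$sd > 0) lam / mom$sd else lam
  structure(z, moments = mom, class = "lr_sample")
}

#' @export
print.lr_sample <- function(x, ...) {
  m <- attr(x, "moments")
  cat(sprintf("Standardized lambda(%s : %s) sample, M = %d\n",
              m$true, m$hyp, length(x)))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' @export
plot.lr_sample <- function(x, breaks = 50, ...) {
  m <- attr(x, "moments")
  graphics::hist(as.numeric(x), breaks = breaks, freq = FALSE,
                 main = sprintf("lambda(%s : %s) / SD", m$true, m$hyp),
                 xlab = "lambda / SD(lambda)", ...)
  if (m$sd > 0) {
    xs <- seq(min(x), max(x), length.out = 200)
    graphics::lines(xs, stats::dnorm(xs, mean = m$ratio, sd = 1), lty = 2)
  }
  invisible(x)
}
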