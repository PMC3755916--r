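# Shared fixtures: published single-chromosome count distributions (100,000
# replicates on 1.632 M) used as fixed references for likelihood-ratio
# examples, plus memoized mid-size fits reused across test files.

ref_counts_1632 <- list(
  UN   = c(921, 14948, 35379, 31041, 13556, 3501, 587, 65, 2, 0),
  GUGN = c(17696, 29825, 28580, 16286, 5940, 1408, 237, 26, 2, 0),
  C    = c(9976, 29729, 32644, 19168, 6719, 1515, 231, 17, 1, 0),
  HS   = c(1826, 24700, 41257, 24284, 6675, 1150, 101, 6, 1, 0),
  GPO  = c(9965, 54387, 30210, 5046, 386, 6, 0, 0, 0, 0)
)

# reference mean/variance of segment counts on 1.632 M (300,000 replicates)
ref_moments_1632 <- data.frame(
  rel = c("UN", "GUGN", "C", "C1R", "2C", "2C1R", "3C",
          "HS", "HUN", "HC", "HC1R", "H2C", "H2C1R",
          "GPO", "GGPO", "G3PO", "G4PO", "G5PO", "G6PO"),
  mean = c(2.539, 1.678, 1.885, 1.147, 0.674, 0.387, 0.219,
           2.135, 1.475, 0.941, 0.572, 0.336, 0.193,
           1.316, 1.066, 0.736, 0.471, 0.287, 0.169),
  var = c(1.170, 1.482, 1.311, 1.213, 0.845, 0.519, 0.299,
          0.942, 1.187, 1.020, 0.714, 0.445, 0.258,
          0.537, 0.767, 0.721, 0.543, 0.358, 0.217))

ns_distribution <- function(rel, N = 1e5, l = 1.632) {
  cnt <- ref_counts_1632[[rel]]
  empirical_distribution(data.frame(n_s = seq_along(cnt) - 1L, count = cnt),
                         l, rel)
}

# memoized fits so expensive simulation runs once per test session
.fixture_env <- new.env(parent = emptyenv())

fixture_fit <- function(name) {
  if (!is.null(.fixture_env[[name]])) return(.fixture_env[[name]])
  fit <- switch(name,
    # close relatives on the equal-length model, mid-size replication
    equal_small = ibd_fit("equal22", c("UN", "HS", "C", "HC"),
                          nrep = 30000, seed = 4001),
    # all 19 relationships on the equal-length model
    equal_all = ibd_fit("equal22", relationships()$abbrev,
                        nrep = 20000, seed = 4002),
    stop("unknown fixture fit ", name))
  .fixture_env[[name]] <- fit
  fit
}

# full-replication fixtures used by the acceptance suite (memoized so the
# expensive runs happen once even when several criteria draw on them)
accept_sim19 <- function() {
  if (is.null(.fixture_env$sim19)) {
    set.seed(9101)
    .fixture_env$sim19 <- simulate_sharing(relationships()$abbrev, 1.632, 1e5)
  }
  .fixture_env$sim19
}

accept_fit_h5 <- function() {
  if (is.null(.fixture_env$fit_h5)) {
    .fixture_env$fit_h5 <- ibd_fit("human5",
                                   c("UN", "HS", "C", "HC", "2C1R", "3C"),
                                   nrep = 1e5, seed = 9102)
  }
  .fixture_env$fit_h5
}

accept_fit_eq <- function() {
  if (is.null(.fixture_env$fit_eq)) {
    .fixture_env$fit_eq <- ibd_fit("equal22", c("UN", "HS"),
                                   nrep = 3e5, seed = 9103)
  }
  .fixture_env$fit_eq
}

# chi-square homogeneity test between two outcome count tables
# (code/count data frames); sparse cells pooled so expected counts are
# reasonable for the asymptotic test
compare_counts_chisq <- function(d1, d2, min_cell = 20L) {
  m <- merge(d1, d2, by = "code", all = TRUE, suffixes = c("_1", "_2"))
  m[is.na(m)] <- 0L
  big <- (m$count_1 + m$count_2) >= min_cell
  tab <- rbind(cbind(m$count_1[big], m$count_2[big]),
               c(sum(m$count_1[!big]), sum(m$count_2[!big])))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  suppressWarnings(stats::chisq.test(tab)$p.value)
}

# empirical (n_s, p_s, t_s) counts for an arbitrary relationship spec
sim_counts <- function(rel, l, n) {
  x <- simulate_sharing(list(rel), l, n)
  d <- empirical_distribution(x[, c("n_s", "p_s", "t_s")], l)
  d$counts
}
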