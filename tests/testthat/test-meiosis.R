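test_that("crossover sampling follows the Haldane model", {
  set.seed(101)
  expect_error(sample_crossovers(0), "> 0")
  expect_error(sample_crossovers(-1), "> 0")
  # vanishing map length: essentially never a crossover
  expect_equal(sample_crossovers(1e-9), numeric(0))

  n <- 1e5
  l <- 1.632
  counts <- integer(n)
  l2 <- 2.0
  for (i in seq_len(n)) counts[i] <- length(sample_crossovers(l))
  # Poisson mean equals the map length
  expect_lt(abs(mean(counts) - l), 3 * sqrt(l / n))
  # chi-square goodness of fit to Poisson(l), alpha = 0.001
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  p <- dpois(0:kmax, l); p[kmax + 1L] <- 1 - ppois(kmax - 1L, l)
  keep <- n * p >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(p[keep], sum(p[!keep]))
  pval <- suppressWarnings(chisq.test(obs2, p = p2 / sum(p2))$p.value)
  expect_gt(pval, 0.001)

  # uniform positions: mean l/2
  xs <- unlist(lapply(seq_len(2e4), function(i) sample_crossovers(l2)))
  expect_lt(abs(mean(xs) - l2 / 2), 3 * (l2 / sqrt(12)) / sqrt(length(xs)))
  expect_true(all(xs > 0 & xs < l2))
})

test_that("gamete formation copies, alternates and segregates correctly", {
  l <- 1.632
  A <- haplotype(l, labels = 1L)
  B <- haplotype(l, labels = 2L)

  # forced zero crossovers: output is one parent, each phase reachable
  set.seed(7)
  g <- replicate(400, form_gamete(A, B, crossovers = numeric(0))$labels)
  expect_true(all(g %in% 1:2))
  expect_lt(abs(mean(g == 1L) - 0.5), 3 * 0.5 / sqrt(400))

  # identical parents: output identical regardless of crossovers
  g <- form_gamete(A, A, crossovers = c(0.3, 0.9))
  expect_equal(g$labels, 1L)
  expect_equal(g$breakpoints, numeric(0))

  # single forced breakpoint with forced phase: direct construction
  g <- form_gamete(A, B, crossovers = 0.4, start = "A")
  expect_equal(g$labels, c(1L, 2L))
  expect_equal(g$breakpoints, 0.4)
  g <- form_gamete(A, B, crossovers = 0.4, start = "B")
  expect_equal(g$labels, c(2L, 1L))

  # mosaic parents: label proportions at a fixed position -> 1/2
  set.seed(8)
  hA <- haplotype(l, 0.8, c(1L, 2L))
  hB <- haplotype(l, 0.5, c(2L, 1L))
  lab <- replicate(2000, haplotype_label(form_gamete(hA, hB), 0.3))
  expect_lt(abs(mean(lab == 1L) - 0.5), 3 * 0.5 / sqrt(2000))

  expect_error(form_gamete(A, haplotype(2, labels = 1L)), "same chromosome length")
})

test_that("simplify merges equal neighbours, is idempotent and label-preserving", {
  h <- haplotype(1, c(0.2, 0.7), c(1L, 1L, 2L), simplify = FALSE)
  s <- simplify_haplotype(h)
  expect_equal(s$labels, c(1L, 2L))
  expect_equal(s$breakpoints, 0.7)
  expect_identical(simplify_haplotype(s), s)
  one <- haplotype(1, labels = 5L)
  expect_identical(simplify_haplotype(one), one)
  # label at any queried position is invariant
  pts <- c(0.05, 0.21, 0.69, 0.71, 0.99)
  expect_equal(haplotype_label(h, pts), haplotype_label(s, pts))
})

test_that("haplotype validation catches malformed mosaics", {
  expect_error(haplotype(1, c(0.5, 0.3), c(1L, 2L, 3L)), "strictly increasing")
  expect_error(haplotype(1, c(0.5), c(1L, 2L, 3L)), "one label per interval")
  expect_error(haplotype(1, c(1.2), c(1L, 2L)), "inside")
  expect_error(haplotype(-1, labels = 1L), "> 0")
})
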