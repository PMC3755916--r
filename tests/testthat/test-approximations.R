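test_that("closed-form expected segment counts match the printed values", {
  l <- 1.632
  expect_equal(round(as.numeric(expected_num_segments("C", l)), 3), 1.882)
  expect_equal(attr(expected_num_segments("C", l), "formula"), "collateral")
  expect_equal(round(as.numeric(expected_num_segments("GPO", l)), 3), 1.316)
  expect_equal(attr(expected_num_segments("GPO", l), "formula"), "lineal")
  expect_equal(as.numeric(expected_num_segments("UN", l)), (5 * l + 2) / 4)
  expect_equal(round(as.numeric(expected_num_segments("UN", l)), 2), 2.54)
  expect_equal(as.numeric(expected_num_segments("GUGN", l)), (7 * l + 2) / 8)
  expect_equal(as.numeric(expected_num_segments("HS", l)), (2 * l + 1) / 2)
})

test_that("expected segment lengths include the finite-chromosome correction", {
  l <- 1.632
  expect_equal(round(expected_segment_length("HS", l), 3), 0.383)
  expect_equal(round(expected_segment_length("HUN", l), 3), 0.277)
  expect_equal(round(expected_segment_length("HC", l), 3), 0.217)
  expect_equal(round(expected_segment_length("H2C", l), 3), 0.151)
  # strictly below the infinite-chromosome 1/d, approaching it as l grows
  for (rel in c("HS", "HC", "C", "2C", "GPO")) {
    d <- relationship(rel)$d
    lens <- vapply(c(1, 5, 50, 5000), function(ll)
      expected_segment_length(rel, ll), 0)
    expect_true(all(lens < 1 / d))
    expect_true(all(diff(lens) > 0))
    expect_equal(lens[4], 1 / d, tolerance = 1e-3)
  }
})

test_that("total shared length is 2Rl and factorizes for cousin-type pairs", {
  l <- 1.632
  expect_equal(expected_total_shared("HS", l), l / 2)
  expect_equal(expected_total_shared("3C", 2.4), 2.4 / 64)
  # count x individual length = total for the collateral (cousin-type) relationships
  for (rel in c("HS", "HUN", "HC", "HC1R", "H2C", "H2C1R",
                "C", "C1R", "2C", "2C1R", "3C")) {
    expect_equal(as.numeric(expected_num_segments(rel, l)) *
                   expected_segment_length(rel, l),
                 expected_total_shared(rel, l), tolerance = 1e-12)
  }
})

test_that("closed-form counts agree with simulation for all 19 relationships", {
  set.seed(81)
  n <- 60000
  l <- 1.632
  x <- simulate_sharing(relationships()$abbrev, l, n)
  for (rel in relationships()$abbrev) {
    d <- x[x$relationship == rel, ]
    pred <- as.numeric(expected_num_segments(rel, l))
    se <- sd(d$n_s) / sqrt(n)
    expect_lt(abs(mean(d$n_s) - pred), 0.003 + 3 * se)
  }
})

test_that("segment counts of close relatives are underdispersed vs Poisson", {
  set.seed(82)
  n <- 30000
  x <- simulate_sharing("UN", 1.632, n)
  m <- mean(x$n_s)
  v <- stats::var(x$n_s)
  # SE of (mean - variance) via the influence values of the difference
  infl <- x$n_s - (x$n_s - m)^2
  se <- stats::sd(infl) / sqrt(n)
  expect_gt(m - v, 3 * se)
})

test_that("Poisson-approximate moments are finite, zero on the diagonal", {
  fit <- fixture_fit("equal_all")
  rels <- relationships()$abbrev
  expect_identical(poisson_lr_moments(fit, "C", "C")$mean, 0)
  for (a in rels) for (b in rels) {
    m <- poisson_lr_moments(fit, a, b)
    expect_true(is.finite(m$mean))
    expect_true(is.finite(m$sd))
  }
})

test_that("the Poisson shape assumption shrinks the UN:HS distance", {
  fit <- fixture_fit("equal_small")
  sim <- lr_moments(fit, "UN", "HS", use = "ns")
  poi <- poisson_lr_moments(fit, "UN", "HS")
  expect_gt(sim$mean, poi$mean)  # ~1.82 vs ~0.81 at full replication
  expect_gt(poi$mean, 0)
})
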