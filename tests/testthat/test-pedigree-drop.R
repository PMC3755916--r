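test_that("the relationship catalog matches the published pedigree table", {
  cat <- relationships()
  expect_equal(nrow(cat), 19L)
  expect_equal(sum(cat$base == "full-sib"), 7L)
  expect_equal(sum(cat$base == "half-sib"), 6L)
  expect_equal(sum(cat$base == "lineal"), 6L)

  hs <- relationship("HS")
  expect_equal(hs$R, 1 / 4)
  expect_equal(hs$base, "half-sib")
  expect_equal(unname(c(hs$g1, hs$g2, hs$d)), c(1, 1, 2))

  c3 <- relationship("3C")
  expect_equal(c3$base, "full-sib")
  expect_equal(c3$R, 1 / 128)
  expect_equal(unname(c(c3$g1, c3$g2, c3$d)), c(4, 4, 8))

  g6 <- relationship("G6PO")
  expect_equal(g6$base, "lineal")
  expect_equal(g6$R, 1 / 128)
  expect_equal(g6$d, 7)

  expect_equal(relationship("C")$R, 1 / 8)
  expect_equal(relationship("UN")$d, 3)
  # Wright's numerator relationship from the meiosis path: R = a (1/2)^d
  expect_equal(cat$R, cat$a * 0.5^cat$d)
  expect_error(relationship("XX"), "unknown relationship")
  expect_error(drop_pair("HS", -1), "> 0")
})

test_that("shared segments reproduce the worked two-descendant example", {
  a <- haplotype(1, c(0.1256, 0.5701, 0.9012), c(1L, 2L, 1L, 3L))
  b <- haplotype(1, 0.3659, c(2L, 1L))
  seg <- shared_segments(a, b)
  expect_equal(unname(seg),
               rbind(c(0.1256, 0.3659), c(0.5701, 0.9012)))
  expect_equal(seg[, "end"] - seg[, "start"], c(0.2403, 0.3311))
  sm <- summarize_sharing(seg, 1)
  expect_equal(sm$total, 0.5714)
  expect_equal(sm$n_s, 2L)
  expect_equal(sm$p_s, 0L)
  expect_equal(sm$t_s, 6L)

  # disjoint label sets share nothing
  expect_equal(nrow(shared_segments(haplotype(1, labels = 1L),
                                    haplotype(1, labels = 9L))), 0L)
  # identical single-label haplotypes share everything
  seg <- shared_segments(haplotype(2, labels = 1L), haplotype(2, labels = 1L))
  expect_equal(unname(seg), rbind(c(0, 2)))
})

test_that("half-sibs on a vanishing chromosome share all or nothing, p = 1/2", {
  set.seed(21)
  x <- simulate_sharing("HS", 1e-6, 2000)
  expect_true(all(x$total %in% c(0, 1)))
  expect_true(all(x$p_s[x$n_s == 1L] == 2L))
  expect_lt(abs(mean(x$total) - 0.5), 3 * 0.5 / sqrt(2000))
})

test_that("drop_pair and the bulk simulator are the same process", {
  for (rel in c("HS", "UN", "GPO", "C", "3C", "H2C1R")) {
    set.seed(333)
    bulk <- simulate_sharing(rel, 1.3, 3)
    set.seed(333)
    for (i in 1:3) {
      pair <- drop_pair(rel, 1.3)
      sm <- summarize_sharing(shared_segments(pair$a, pair$b), 1.3)
      expect_equal(sm$n_s, bulk$n_s[i])
      expect_equal(sm$p_s, bulk$p_s[i])
      expect_equal(sm$total, bulk$total[i])
    }
  }
})

test_that("segment lists are disjoint, sorted, and inside the chromosome", {
  set.seed(31)
  for (i in 1:100) {
    rel <- sample(relationships()$abbrev, 1)
    pair <- drop_pair(rel, 1.632)
    seg <- shared_segments(pair$a, pair$b)
    if (nrow(seg) == 0) next
    expect_true(all(seg[, "start"] >= 0 & seg[, "end"] <= 1.632))
    expect_true(all(seg[, "end"] > seg[, "start"]))
    if (nrow(seg) > 1)
      expect_true(all(seg[-1, "start"] > seg[-nrow(seg), "end"]))
  }
})

test_that("mean segment counts and shared proportions track the references", {
  set.seed(41)
  n <- 40000
  x <- simulate_sharing(c("UN", "GPO", "HS"), 1.632, n)
  for (rel in c("UN", "GPO", "HS")) {
    d <- x[x$relationship == rel, ]
    ref <- ref_moments_1632[ref_moments_1632$rel == rel, ]
    expect_lt(abs(mean(d$n_s) - ref$mean), 3 * sd(d$n_s) / sqrt(n) + 0.003)
    # mean shared proportion recovers 2R
    tw <- relationship(rel)$R * 2
    expect_lt(abs(mean(d$total) - tw), 3 * sd(d$total) / sqrt(n))
  }
})

test_that("half-sib-base sharing depends only on R, full-sib base does not", {
  set.seed(51)
  n <- 40000
  l <- 1.632
  # HC (2,2) and half-great-uncle--great-nephew (1,3): same R = 1/16
  hc <- sim_counts(relationship("HC"), l, n)
  hgugn <- sim_counts(relationship(base = "half-sib", g1 = 1, g2 = 3), l, n)
  expect_gt(compare_counts_chisq(hc, hgugn), 0.001)

  # 2C (3,3) and cousins twice removed (2,4): same distribution
  c2 <- sim_counts(relationship("2C"), l, n)
  c2r <- sim_counts(relationship(base = "full-sib", g1 = 2, g2 = 4), l, n)
  expect_gt(compare_counts_chisq(c2, c2r), 0.001)

  # C (2,2) and GUGN (1,3) share R = 1/8 but have different distributions
  cc <- sim_counts(relationship("C"), l, n)
  gugn <- sim_counts(relationship("GUGN"), l, n)
  expect_lt(compare_counts_chisq(cc, gugn), 1e-6)
})
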