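# Bias statistics: KS uniformity, germline enrichment, adjacent losses,
# relative positions.

test_that("relative positions land at the expected fractions", {
  fx <- small_fixture()
  acc <- fx$fit$calls[fx$fit$calls$status == "accepted", , drop = FALSE]
  if (nrow(acc)) {
    pos <- suppressWarnings(relative_positions(fx$fit, acc))
    expect_true(all(pos > 0 & pos < 1))
  }
  # direct arithmetic on a known gene: offsets {30,150,270} of a 300 nt CDS
  expect_equal(c(30, 150, 270) / 300, c(0.1, 0.5, 0.9))
})

test_that("ks_uniform matches an independent oracle and handles extremes", {
  # point mass at 0.5: D converges to 0.5
  r <- ks_uniform(rep(0.5, 50))
  expect_equal(unname(r$statistic), 0.5)

  # near-uniform grid i/(n+1): tiny D, p near 1
  n <- 40
  r <- ks_uniform(seq_len(n) / (n + 1))
  expect_lt(unname(r$statistic), 2 / n)
  expect_gt(r$p_value, 0.99)

  # oracle agreement (conjugate theta-series representation) to 1e-10
  set.seed(17)
  for (i in 1:50) {
    x <- runif(sample(5:60, 1))
    r <- ks_uniform(x)
    o <- ks_oracle(x)
    expect_lt(abs(unname(r$statistic) - o[["D"]]) / o[["D"]], 1e-10)
    expect_lt(abs(r$p_value - o[["p"]]) / max(o[["p"]], 1e-12), 1e-10)
  }
  # cross-check against stats::ks.test at its own (1e-6) tolerance
  x <- runif(30)
  kt <- suppressWarnings(ks.test(x, "punif", exact = FALSE))
  r <- ks_uniform(x)
  expect_equal(unname(r$statistic), unname(kt$statistic))
  expect_lt(abs(r$p_value - kt$p.value), 1e-4)

  expect_error(ks_uniform(c(0.1, 0.2)), "at least 5")
})

test_that("germline enrichment reproduces the printed contingency statistics", {
  # counts as printed for loss genes against the genome background
  r <- germline_enrichment(187, 287, 7212, 13752)
  expect_equal(unname(r$statistic), 18.22946828, tolerance = 1e-8)
  expect_equal(r$p_value, 1.958254708e-05, tolerance = 1e-8)
  expect_lt(r$p_value, 0.05)

  # gain genes: significant below 0.01
  r <- germline_enrichment(135, 189, 7212, 13752)
  expect_equal(unname(r$statistic), 26.95858565, tolerance = 1e-8)
  expect_lt(r$p_value, 0.01)

  # equal proportions: statistic 0, p 1
  r <- germline_enrichment(50, 100, 500, 1000)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  expect_error(germline_enrichment(0, 0, 10, 20), "zero margin|degenerate")
})

test_that("chi-square agrees with the closed-form oracle on random tables", {
  set.seed(23)
  for (i in 1:100) {
    na_ <- sample(20:500, 1); nb <- sample(100:5000, 1)
    a <- sample(seq_len(na_ - 1), 1); b <- sample(seq_len(nb - 1), 1)
    r <- germline_enrichment(a, na_, b, nb)
    o <- chi22_oracle(a, na_, b, nb)
    expect_lt(abs(unname(r$statistic) - o[["stat"]]) / max(o[["stat"]], 1e-12),
              1e-10)
    expect_lt(abs(r$p_value - o[["p"]]) / max(o[["p"]], 1e-300), 1e-10)
  }
})

test_that("adjacent-loss excess reproduces the printed 9-vs-2.7 case", {
  r <- adjacent_loss_chisq(9, 2.7)
  expect_equal(unname(r$statistic), (9 - 2.7)^2 / 2.7)
  expect_equal(r$p_value, pchisq((9 - 2.7)^2 / 2.7, 1, lower.tail = FALSE))
  expect_lt(r$p_value, 0.05)
})

test_that("adjacent-loss permutation test counts consecutive same-branch losses", {
  # one loss per gene everywhere: zero adjacent pairs
  lc <- data.frame(gene = paste0("g", 1:6), branch = "b",
                   position = c(1, 2, 1, 3, 2, 1))
  counts <- setNames(rep(4L, 6), paste0("g", 1:6))
  r <- adjacent_loss_test(lc, counts, n_perm = 200, seed = 1)
  expect_equal(unname(r$counts[["observed"]]), 0)

  # two losses in a two-intron gene force adjacency; expectation is 1 too
  lc <- data.frame(gene = "g1", branch = "b", position = c(1, 2))
  r <- adjacent_loss_test(lc, setNames(2L, "g1"), n_perm = 100, seed = 1)
  expect_equal(unname(r$counts[["observed"]]), 1)
  expect_equal(unname(r$counts[["expected"]]), 1)

  # losses exceeding a gene's intron count is an upstream error
  lc <- data.frame(gene = "g1", branch = "b", position = c(1, 2, 3))
  expect_error(adjacent_loss_test(lc, setNames(2L, "g1"), n_perm = 10),
               "more losses than intron positions")
})
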