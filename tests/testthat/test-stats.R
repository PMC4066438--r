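test_that("viable spore yield is colonies per cell plated and may exceed 4", {
  expect_equal(viable_spore_yield(360, 100)$yield, 3.6)
  expect_equal(viable_spore_yield(0, 100)$yield, 0)
  expect_equal(viable_spore_yield(900, 100)$yield, 9)
  expect_error(viable_spore_yield(10, 0), "positive")
})

test_that("the transmission G-test matches its likelihood-ratio definition", {
  r0 <- transmission_test(50, 50)
  expect_equal(r0$t, 0.5)
  expect_equal(r0$G, 0)
  r1 <- transmission_test(72, 28)
  expect_equal(r1$t, 0.72)
  expect_equal(r1$G, 2 * (72 * log(72 / 50) + 28 * log(28 / 50)))
  expect_equal(round(r1$G, 2), 20.04)
  expect_equal(transmission_test(94, 6)$t, 0.94)
  expect_equal(transmission_test(100, 0)$G, 2 * 100 * log(2))  # empty cell

  # independent oracle: G as a multinomial log-likelihood ratio
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(20:500, 1)
      k <- rbinom(1, n, runif(1, 0.2, 0.8))
      if (k == 0 || k == n) next
      g_ref <- 2 * (dmultinom(c(k, n - k), prob = c(k, n - k) / n, log = TRUE) -
                    dmultinom(c(k, n - k), prob = c(0.5, 0.5), log = TRUE))
      got <- transmission_test(k, n - k)
      expect_equal(got$G, g_ref, tolerance = 1e-9)
      expect_equal(got$p, pchisq(g_ref, 1, lower.tail = FALSE), tolerance = 1e-9)
    }
  })
  expect_lt(transmission_test(72, 28, williams = TRUE)$G,
            transmission_test(72, 28)$G)
  expect_error(transmission_test(0, 0), "positive")
})

test_that("Haldane mapping round-trips and matches closed-form values", {
  expect_equal(haldane_cM(0), 0)
  expect_equal(round(haldane_cM(0.2), 2), 25.54)
  expect_equal(haldane_r(16), (1 - exp(-0.32)) / 2)
  expect_equal(round(haldane_r(16), 3), 0.137)   # 100 kb at 0.16 cM/kb
  grid <- seq(0, 0.49, by = 0.007)
  expect_true(all(abs(grid - haldane_r(haldane_cM(grid))) < 1e-12))
  expect_error(haldane_cM(0.5), "unlinked")
  expect_error(haldane_cM(-0.01), "non-negative")
})

test_that("genetic intervals from counts flag unlinked loci", {
  iv <- interval_from_counts(90, 10)
  expect_equal(iv$r, 0.1)
  expect_equal(round(iv$cM, 2), 11.16)
  expect_equal(interval_from_counts(100, 0)$cM, 0)
  un <- interval_from_counts(50, 50)
  expect_true(un$unlinked)
  expect_true(is.na(un$cM))
})

test_that("aneuploids per meiosis is the yield-by-fraction product", {
  expect_equal(aneuploids_per_meiosis(0.5, 0.4), 0.2)
  expect_equal(aneuploids_per_meiosis(3.6, 0.055), 0.198)
  expect_equal(aneuploids_per_meiosis(2.1, 0), 0)
  expect_error(aneuploids_per_meiosis(1, 1.4), "\\[0, 1\\]")
})

test_that("the transmission curve is monotone and anchored at its closed-form points", {
  expect_equal(transmission_curve(0, c(0, 0.2, 0.5)), rep(0.5, 3))
  expect_equal(transmission_curve(1, 0), 1)
  expect_equal(round(transmission_curve(0.8, 0.1), 4), 0.7667)
  d <- seq(0, 1, by = 0.1); r <- seq(0, 0.5, by = 0.05)
  for (dd in d) expect_true(all(diff(transmission_curve(dd, r)) <= 0))
  for (rr in r) expect_true(all(diff(transmission_curve(d, rr)) >= 0))
  # at r = 1/2 the algebra collapses: (1 - d/2)/(2 - d) = 1/2 for every d,
  # so the single-killer curve carries no signal from unlinked markers
  expect_equal(transmission_curve(d, 0.5), (1 - 0.5 * d) / (2 - d))
  expect_equal(transmission_curve(d, 0.5), rep(0.5, length(d)))
})

test_that("transmission summaries apply the assay's exclusion rules", {
  tab <- tibble::tibble(
    meiosis_id = 1:8, spore_id = 1L,
    lys1 = c("Sk", "Sk", "Sp", "Sp/Sk", "Sk", "Sk", "Sk", "Sk"),
    his5 = c("Sk", "Sk", "Sp", "Sp/Sk", "Sk", "Sk", "Sk", "Sk"),
    ade6 = c("Sk", "Sp", "Sp", "Sp/Sk", "Sp/Sk", "Sk", "Sk", "Sk"),
    ploidy_class = c("haploid-call", "haploid-call", "haploid-call",
                     "het-diploid", "het-chr3-aneuploid", "haploid-call",
                     "haploid-call", "haploid-call"),
    viability = c(rep("alive", 7), "dead"),
    cause = c(rep(NA, 7), "drive-killed"))
  ts <- transmission_summary(tab, marker_panel(ploidy_only = TRUE))
  # lys1: het-diploid row and dead row dropped, Sp/Sk calls dropped
  expect_equal(ts$n[ts$locus == "lys1"], 6L)
  expect_equal(ts$n_killer[ts$locus == "lys1"], 5L)
  # ade6: additionally drops the heterozygous chr3 aneuploid
  expect_equal(ts$n[ts$locus == "ade6"], 5L)
  expect_equal(ts$n_killer[ts$locus == "ade6"], 3L)

  mi <- map_interval(tab, "lys1", "ade6")
  # haploid-call spores with clean calls at both loci: rows 1,2,3,6,7 (7 alive)
  expect_equal(mi$n, 5L)
  expect_equal(mi$recombinants, 1L)

  ps <- ploidy_summary(tab)
  expect_equal(sum(ps$n), 7L)
  expect_equal(ps$fraction[ps$ploidy_class == "het-diploid"], 1 / 7)
})
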