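test_that("the recombination-free class distribution is exactly normalised", {
  for (cfg in list(null_cross(p_dist = 0), null_cross(p_dist = 0.37),
                   cross_preset("KKRxKKK_rec12"))) {
    cls <- enumerate_spore_classes(cfg)
    expect_equal(sum(cls$prob_pre), 1, tolerance = 1e-12)
    expect_true(all(cls$prob_post <= cls$prob_pre + 1e-15))
  }
  expect_error(enumerate_spore_classes(cross_config("PPP", "KKK", rec12 = "wt")),
               "rec12")
})

test_that("fully random segregation of three bivalents gives the exact textbook fractions", {
  # no rearrangement heterozygosity, no killers, p_dist = 0
  pure <- cross_config("KKK", "KKK", rec12 = "null", p_dist = 0,
                       drive = no_drive())
  cls <- enumerate_spore_classes(pure)
  hap <- cls$cn1 == 1 & cls$cn2 == 1 & cls$cn3 == 1
  expect_equal(sum(cls$prob_pre[hap]), 1 / 8)
  expect_equal(sum(cls$prob_post), 13 / 64)
  # a partially effective distributive system pushes the figure to ~25%
  pure2 <- cross_config("KKK", "KKK", rec12 = "null", p_dist = 0.2,
                        drive = no_drive())
  expect_gte(sum(enumerate_spore_classes(pure2)$prob_post), 0.25)
  # perfect distributive segregation: every spore a viable haploid
  pure3 <- cross_config("KKK", "KKK", rec12 = "null", p_dist = 1,
                        drive = no_drive())
  expect_equal(viable_fraction(pure3, "haploid"), 1)
})

test_that("swapping species labels mirrors transmission and preserves viability", {
  d <- 0.65
  a <- null_cross(p_dist = 0.4, drive = drive_model("k", 3L, 1316437, "Sk", d))
  b <- null_cross(p_dist = 0.4, drive = drive_model("k", 3L, 1316437, "Sp", d))
  expect_equal(viable_fraction(a), viable_fraction(b), tolerance = 1e-12)
  expect_equal(expected_transmission(a, "ade6", killer = "Sk"),
               expected_transmission(b, "ade6", killer = "Sp"),
               tolerance = 1e-12)
  expect_equal(expected_transmission(a, "ade6", killer = "Sp"),
               1 - expected_transmission(a, "ade6", killer = "Sk"),
               tolerance = 1e-12)
})

test_that("a single killer at the assayed locus transmits at 1/(2 - d)", {
  for (d in c(0, 0.25, 0.6111, 0.9, 1)) {
    cfg <- null_cross(p_dist = 0.5,
                      drive = drive_model("k", 3L, 1316437, "Sk", d))
    expect_equal(expected_transmission(cfg, "ade6"), 1 / (2 - d),
                 tolerance = 1e-12, label = paste("d =", d))
  }
})

test_that("an all-lethal locus leaves the transmission conditional undefined", {
  dm <- drive_model(c("a", "b"), c(1L, 1L), c(4.3e6, 4.3e6),
                    c("Sk", "Sp"), c(1, 1))
  cfg <- null_cross(p_dist = 0.5, drive = dm)
  expect_error(expected_transmission(cfg, "lys1"), "undefined")
})

test_that("Monte Carlo simulation agrees with the exact enumeration", {
  cfg <- null_cross(p_dist = 0.35,
                    drive = drive_model(c("k2", "k3"), c(2L, 3L),
                                        c(3.3e6, 1.3e6), c("Sk", "Sk"),
                                        c(0.5, 0.8)))
  cls <- enumerate_spore_classes(cfg)
  key_cols <- c("lys1", "his5", "ade6", "ploidy_class")
  model <- tapply(cls$prob_post / sum(cls$prob_post),
                  do.call(paste, cls[key_cols]), sum)
  tab <- simulate_cross(cfg, 4000, seed = 17)
  obs <- table(do.call(paste, tab[key_cols])) / nrow(tab)
  expect_true(all(names(obs) %in% names(model)))
  p <- model[names(obs)]
  tol <- 3 * sqrt(p * (1 - p) / nrow(tab)) + 2 / nrow(tab)
  expect_true(all(abs(obs - p) < tol))
  expect_lt(abs(nrow(tab) / 16000 - sum(cls$prob_post)),
            3 * sqrt(sum(cls$prob_post) * (1 - sum(cls$prob_post)) / 16000))
})
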