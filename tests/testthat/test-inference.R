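test_that("the single-locus estimator inverts the transmission curve", {
  expect_equal(mle_single_locus(50, 50), 0)
  expect_equal(round(mle_single_locus(72, 28), 4), 0.6111)
  expect_equal(mle_single_locus(100, 0), 1)
  expect_equal(mle_single_locus(30, 70), 0)   # clamped below one half
  expect_error(mle_single_locus(0, 0), "positive")

  # plugging in exact expected counts recovers d exactly; sampling bias
  # shrinks with n
  for (d in c(0.2, 0.5, 0.85)) {
    t_exp <- transmission_curve(d, 0)
    expect_equal(mle_single_locus(1e6 * t_exp, 1e6 * (1 - t_exp)), d)
  }
  withr::with_seed(41, {
    bias <- vapply(c(100, 1000, 10000), function(n) {
      k <- rbinom(400, n, transmission_curve(0.6, 0))
      mean(mle_single_locus(k, n - k)) - 0.6
    }, 1)
  })
  expect_lt(abs(bias[3]), abs(bias[1]) + 0.02)
  expect_lt(abs(bias[3]), 0.01)
})

test_that("killer strengths are recovered by the multinomial fit", {
  dm <- drive_model(c("k1", "k2", "k3"), 1:3, c(4.3e6, 3.3e6, 1.3e6),
                    rep("Sk", 3), c(0.7, 0.5, 0.85))
  cfg <- cross_config("PPP", "KKK", rec12 = "null", drive = dm)
  tab <- simulate_cross(cfg, 1500, seed = 23)
  fit <- fit_drive_model(tab, cfg, seed = 2)
  est <- tidy(fit)
  expect_true(all(est$identifiable))
  expect_true(all(abs(est$d_hat - c(0.7, 0.5, 0.85)) < 0.1))
  expect_true(all(est$ci_lo <= est$d_hat & est$d_hat <= est$ci_hi))
  expect_equal(glance(fit)$n_spores, nrow(tab) - glance(fit)$n_dropped)

  # local optimality: the fitted optimum beats nearby perturbations
  refit_ll <- function(d) {
    cfg2 <- cfg; cfg2$drive$strength <- d
    cls <- enumerate_spore_classes(cfg2)
    key <- do.call(paste, c(cls[c("lys1", "his5", "ade6", "ploidy_class")],
                            sep = "|"))
    p <- tapply(cls$prob_post, key, sum)
    obs <- table(paste(tab$lys1, tab$his5, tab$ade6, tab$ploidy_class,
                       sep = "|"))
    obs <- obs[names(obs) %in% names(p)[p > 0]]
    sum(obs * log(p[names(obs)] / sum(p)))
  }
  ll_hat <- refit_ll(est$d_hat)
  expect_equal(ll_hat, glance(fit)$loglik, tolerance = 1e-6)
  for (j in 1:3) for (eps in c(-0.03, 0.03)) {
    d2 <- est$d_hat; d2[j] <- min(1 - 1e-9, max(1e-9, d2[j] + eps))
    expect_lt(refit_ll(d2), ll_hat + 1e-8)
  }
})

test_that("killers on homozygous chromosomes are flagged non-identifiable", {
  cfg <- cross_preset("PKKxKKK_rec12")
  tab <- simulate_cross(cfg, 800, seed = 29)
  fit <- fit_drive_model(tab, cfg, seed = 1)
  est <- tidy(fit)
  expect_true(est$identifiable[est$chrom == 1L & est$killer == "Sk"])
  expect_false(any(est$identifiable[est$chrom != 1L]))
  expect_true(all(is.na(est$d_hat[!est$identifiable])))

  # no heterozygous killer at all: the fit refuses rather than succeeding
  expect_error(
    fit_drive_model(simulate_cross(cross_preset("KKKxKKK_rec12"), 50, seed = 1),
                    cross_preset("KKKxKKK_rec12")),
    "no active killer|non-identifiable")
})

test_that("identical seeds reproduce the fit exactly", {
  cfg <- cross_preset("PKKxKKK_rec12")
  tab <- simulate_cross(cfg, 400, seed = 31)
  f1 <- fit_drive_model(tab, cfg, seed = 9)
  f2 <- fit_drive_model(tab, cfg, seed = 9)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("likelihood-ratio intervals cover a killer-free truth", {
  cfg <- cross_preset("PKKxKKK_rec12")
  cfg$drive <- drive_model("k1", 1L, 4300000, "Sk", 0.5)  # free parameter slot
  truth0 <- cfg
  truth0$drive$strength <- 0
  withr::with_seed(47, {
    covered <- vapply(1:60, function(i) {
      tab <- simulate_cross(truth0, 250)
      fit <- fit_drive_model(tab, cfg, seed = i, n_restarts = 2)
      fit$estimates$ci_lo[1] <= 1e-6
    }, logical(1))
  })
  expect_gte(mean(covered), 0.9)
})

test_that("transmission gradients localise a killer between its markers", {
  # the printed chromosome 1 pattern: 72% at lys1 versus 55% at ura1 puts the
  # killer nearer lys1
  counts <- tibble::tibble(pos = c(4240000, 1450000),
                           n_killer = c(72, 55), n_other = c(28, 45))
  lm <- localize_driver(counts, chrom_length = 5579133)
  expect_true(lm$identifiable)
  expect_lt(abs(lm$position - 4240000), abs(lm$position - 1450000))

  single <- localize_driver(counts[1, ], chrom_length = 5579133)
  expect_false(single$identifiable)
  expect_true(is.na(single$position))
  expect_equal(single$interval, c(1, 5579133))

  flat <- localize_driver(tibble::tibble(pos = c(1e6, 2e6, 3e6),
                                         n_killer = c(500, 500, 500),
                                         n_other = c(500, 500, 500)),
                          chrom_length = 5579133)
  expect_false(flat$identifiable)
  expect_equal(flat$d_hat, 0, tolerance = 1e-3)
})
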