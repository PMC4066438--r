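test_that("crossover counts follow the interference-free Poisson law", {
  expect_length(draw_crossovers(0), 0)
  withr::with_seed(11, {
    counts <- replicate(3000, length(draw_crossovers(50)))
  })
  # mean 2d = 1.0 per bivalent at 50 cM; 3 SE of the mean
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 3000))
  expect_error(draw_crossovers(-1), "non-negative")
})

test_that("achiasmate segregation matches the four-pole-configuration oracle", {
  # brute force: two homologs each pick a pole independently; per spore
  # P(2 copies) = P(0) = 1/4, P(1) = 1/2
  sis1 <- list("a1", "a2"); sis2 <- list("b1", "b2")
  withr::with_seed(21, {
    copies <- replicate(4000, lengths(segregate_bivalent(sis1, sis2,
                                                         chiasmate = FALSE,
                                                         p_dist = 0))[1])
  })
  expect_lt(abs(mean(copies == 2) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  expect_lt(abs(mean(copies == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))

  # chiasmate, and achiasmate at p_dist = 1, always disjoin properly
  for (arg in list(list(ch = TRUE, p = 0), list(ch = FALSE, p = 1))) {
    out <- segregate_bivalent(sis1, sis2, arg$ch, arg$p)
    expect_equal(lengths(out), rep(1L, 4))
    sides <- vapply(out, function(s) substr(s[[1]], 1, 1), "")
    expect_equal(sort(table(sides)), sort(c(a = 2, b = 2)), ignore_attr = TRUE)
  }
})

test_that("pure-species meiosis yields only viable parental haploids", {
  tab <- simulate_cross(cross_config("PPP", "PPP", drive = no_drive()),
                        50, seed = 5, full_census = TRUE)
  expect_equal(nrow(tab), 200L)
  expect_true(all(tab$viability == "alive"))
  expect_true(all(tab$ploidy_class == "haploid-call"))
  expect_true(all(tab[, c("lys1", "his5", "ade6")] == "Sp"))
})

test_that("chromatids and ancestry content are conserved across a tetrad", {
  cfgs <- list(cross_preset("PPPxKKK_wt"), cross_preset("KRKxKKK_rec12"),
               null_cross(p_dist = 0.3, residual_rate = 0.5))
  withr::with_seed(31, {
    for (cfg in cfgs) {
      ctx <- sporedrive:::prepare_cross(cfg)
      parental <- sporedrive:::ancestry_totals(
        c(ctx$parents[[1]], ctx$parents[[2]]))
      for (rep in 1:40) {
        tet <- simulate_tetrad(ctx)
        all_tds <- do.call(c, tet$spores)
        cen_counts <- table(factor(vapply(all_tds, `[[`, 1L, "cen"), 1:3))
        expect_equal(as.integer(cen_counts), c(4L, 4L, 4L))
        expect_equal(sporedrive:::ancestry_totals(all_tds), 2 * parental)
      }
    }
  })
})

test_that("crossovers in a heterozygous inversion produce unbalanced spore deaths", {
  tab <- simulate_cross(cross_preset("PPPxKKK_wt"), 60, seed = 9,
                        full_census = TRUE)
  expect_true(any(tab$cause == "unbalanced", na.rm = TRUE))
  # homokaryotypic meioses never produce unbalanced products
  tab2 <- simulate_cross(cross_preset("KKKxKKK_wt"), 60, seed = 9,
                         full_census = TRUE)
  expect_false(any(tab2$cause == "unbalanced", na.rm = TRUE))
})

test_that("genotype lookup follows ancestry through translocated and recombinant chromosomes", {
  expect_equal(genotype_at(parent_spore("KKK"), 3L, 1316437), "Sk")
  disome <- c(parent_spore("KKK", chroms = 3), parent_spore("PPP", chroms = 3))
  expect_setequal(genotype_at(disome, 3L, 1316437), c("Sk", "Sp"))

  krk <- sporedrive:::parent_chromosomes(
    default_genome(), cross_preset("KRKxKKK_rec12")$parents[[1]],
    tibble::tibble(chrom = integer(), pos = numeric()))
  r2 <- list(krk[[2]])
  expect_equal(genotype_at(r2, 2L, 2900000), "Sp")   # his5, distal of mat1
  expect_equal(genotype_at(r2, 2L, 1000000), "Sk")   # proximal of the breakpoint
  expect_equal(genotype_at(r2, 3L, 2200000), "Sk")   # translocated chr3R content
  expect_error(genotype_at(r2, 2L, 9e9), "outside")
})

test_that("the ploidy assay classifies spores as the markers would", {
  cfg <- cross_config("PPP", "KKK")
  hap_k <- parent_spore("KKK")
  expect_equal(classify_spore(hap_k, cfg), "haploid-call")
  diploid <- c(parent_spore("KKK"), parent_spore("PPP"))
  expect_equal(classify_spore(diploid, cfg), "het-diploid")
  aneu <- c(parent_spore("KKK"), parent_spore("PPP", chroms = 3))
  expect_equal(classify_spore(aneu, cfg), "het-chr3-aneuploid")
  # a true homozygous disome is invisible to the assay
  k3k3 <- c(parent_spore("KKK"), parent_spore("KKK", chroms = 3))
  expect_equal(classify_spore(k3k3, cfg), "haploid-call")
})
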