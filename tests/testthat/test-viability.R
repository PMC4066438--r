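test_that("inversion-crossover parity decides structural balance", {
  spore <- parent_spore("PPP")
  expect_true(structurally_balanced(spore, inv_het = TRUE))
  spore[[1]]$inv_xo <- 1L
  expect_false(structurally_balanced(spore, inv_het = TRUE))
  expect_true(structurally_balanced(spore, inv_het = FALSE))  # homokaryotypic
  spore[[1]]$inv_xo <- 2L
  expect_true(structurally_balanced(spore, inv_het = TRUE))   # even parity
})

test_that("essential-gene complement rules out non-parental chromosome 2/3 combinations", {
  k2_p3 <- c(parent_spore("KKK", chroms = 2), parent_spore("PPP", chroms = 3))
  expect_false(essential_complement_ok(k2_p3))
  p2_k3 <- c(parent_spore("PPP", chroms = 2), parent_spore("KKK", chroms = 3))
  expect_false(essential_complement_ok(p2_k3))
  expect_true(essential_complement_ok(parent_spore("KKK")))
  # a chromosome 3 heterozygous disome complements either chromosome 2
  for (two in c("PPP", "KKK")) {
    disome <- c(parent_spore(two, chroms = 1:2),
                parent_spore("KKK", chroms = 3), parent_spore("PPP", chroms = 3))
    expect_true(essential_complement_ok(disome), label = two)
  }
})

test_that("only haploid, diploid and chromosome 3 disome copy numbers survive", {
  expect_true(copy_number_viable(c(1, 1, 1)))
  expect_true(copy_number_viable(c(2, 2, 2)))
  expect_true(copy_number_viable(c(1, 1, 2)))
  expect_false(copy_number_viable(c(2, 1, 1)))
  expect_false(copy_number_viable(c(1, 2, 1)))
  expect_false(copy_number_viable(c(1, 0, 1)))
  expect_false(copy_number_viable(c(2, 2, 1)))
})

test_that("killer survival is the product of independent per-locus rescues", {
  g <- default_genome()
  spore_p <- parent_spore("PPP")
  one <- drive_model("k3", 3L, 1316437, "Sk", 0.9)
  expect_equal(drive_survival_prob(spore_p, one, g), 0.1)
  three <- drive_model(c("k1", "k2", "k3"), 1:3, c(4.3e6, 3.3e6, 1.3e6),
                       rep("Sk", 3), c(0.6, 0.8, 0.9))
  expect_equal(drive_survival_prob(spore_p, three, g), 0.4 * 0.2 * 0.1)
  # a chromosome 3 heterozygote carries both chr3 alleles: immune to both
  disome <- c(parent_spore("PPP", chroms = 1:2),
              parent_spore("KKK", chroms = 3), parent_spore("PPP", chroms = 3))
  both3 <- drive_model(c("sk3", "sp3"), c(3L, 3L), c(1.3e6, 1.3e6),
                       c("Sk", "Sp"), c(0.9, 0.4))
  expect_equal(drive_survival_prob(disome, both3, g), 1.0)
})

test_that("viability verdicts apply deterministic rules before killer deaths", {
  cfg <- cross_config("PPP", "PPP", drive = no_drive(), p_dist = 1)
  withr::with_seed(3, {
    tet <- apply_viability(simulate_tetrad(cfg), cfg)
  })
  expect_true(all(tet$verdicts$alive))

  # at full strength, every spore lacking any Sk killer allele dies
  dm <- drive_model(c("k1", "k2", "k3"), 1:3, c(4.3e6, 3.3e6, 1.3e6),
                    rep("Sk", 3), c(1, 1, 1))
  tab <- simulate_cross(cross_config("PPP", "KKK", rec12 = "null",
                                     residual_rate = 0, drive = dm),
                        400, seed = 8)
  hap <- tab[tab$ploidy_class == "haploid-call", ]
  expect_true(all(hap$lys1 == "Sk" & hap$his5 == "Sk" & hap$ade6 == "Sk"))
})

test_that("recombination-free hybrid haploids keep chromosomes 2 and 3 from one species", {
  tab <- simulate_cross(null_cross(p_dist = 0.5), 800, seed = 13)
  hap <- tab[tab$ploidy_class == "haploid-call", ]
  expect_gt(nrow(hap), 100)
  expect_true(all((hap$his5 == "Sk") == (hap$ade6 == "Sk")))
})

test_that("stronger killers lower the viable fraction and raise killer transmission", {
  strengths <- c(0, 0.3, 0.6, 0.9)
  res <- vapply(strengths, function(d) {
    cfg <- null_cross(p_dist = 0.5,
                      drive = drive_model("k3", 3L, 1316437, "Sk", d))
    c(viable_fraction(cfg),
      expected_transmission(cfg, "ade6"))
  }, numeric(2))
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) > 0))
  expect_equal(res[2, 1], 0.5)
})

test_that("translocation pseudo-linkage boosts a chromosome 2 killer's apparent drive", {
  dm <- drive_model(c("k2", "k3"), c(2L, 3L), c(3.3e6, 1.3e6),
                    c("Sk", "Sk"), c(0.4, 0.9))
  # translocation heterozygous: P-karyotype chromosomes 2/3 against K
  het <- cross_config(
    parent_spec(list(chromosome_spec("K", "Sk"),
                     chromosome_spec("P", "Sp"), chromosome_spec("P", "Sp"))),
    "KKK", rec12 = "null", drive = dm)
  # translocation homozygous: same heterozygous ancestry, all-K karyotype
  hom <- cross_config(
    parent_spec(list(chromosome_spec("K", "Sk"),
                     chromosome_spec("K", "Sp"), chromosome_spec("K", "Sp"))),
    "KKK", rec12 = "null", drive = dm)
  expect_gt(expected_transmission(het, "his5"),
            expected_transmission(hom, "his5"))
})
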