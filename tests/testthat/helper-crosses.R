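# Shared fixtures built in code.

no_drive <- function() drive_model()

# recombination-free cross with no killers, used for the segregation oracle
null_cross <- function(p1 = "PPP", p2 = "KKK", p_dist = 0, drive = no_drive(),
                       residual_rate = 0) {
  cross_config(p1, p2, rec12 = "null", residual_rate = residual_rate,
               p_dist = p_dist, drive = drive)
}

# chromosome 1 "introgression" cross: identical karyotypes (no inversion or
# translocation heterozygosity), heterozygous ancestry on chromosome 1 only —
# a clean bivalent for recombination and killer-mapping fixtures
introgression_cross <- function(panel, drive = no_drive(), rec12 = "wt") {
  p1 <- parent_spec(list(chromosome_spec("K", "Sp"),
                         chromosome_spec("K", "Sk"),
                         chromosome_spec("K", "Sk")))
  cross_config(p1, "KKK", drive = drive, rec12 = rec12, panel = panel)
}

chr1_panel <- function(pos, names = paste0("m", seq_along(pos))) {
  dplyr::bind_rows(
    tibble::tibble(name = names, chrom = 1L, pos = pos),
    marker_panel(ploidy_only = TRUE)[-1, ])
}

# a single parental chromatid set, as a "spore" (list of chromatid records)
parent_spore <- function(spec, chroms = 1:3, genome = default_genome()) {
  tds <- sporedrive:::parent_chromosomes(
    genome, parent_spec(spec),
    tibble::tibble(chrom = integer(), pos = numeric()))
  tds[chroms]
}
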