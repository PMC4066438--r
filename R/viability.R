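# Spore-death rules, applied in a fixed order: structural balance (inversion
# crossovers), essential-gene complement (translocation blocks), copy-number
# lethality (chromosome 1/2 aneuploidy), then stochastic killing by active
# gamete-killer loci. A spore carrying the killer allele at a locus is fully
# resistant to that killer.

.VIABLE_CN <- list(c(1L, 1L, 1L), c(2L, 2L, 2L), c(1L, 1L, 2L))

spore_copy_number <- function(spore) {
  cn <- integer(3)
  for (td in spore) cn[td$cen] <- cn[td$cen] + 1L
  cn
}

#' Structural balance of a spore
#'
#' A chromatid produced by an odd number of crossovers inside the chromosome 1
#' inversion of an inversion-heterozygous meiosis is unbalanced (duplication
#' of one arm, deletion of the other) and lethal. In homokaryotypic meioses
#' crossovers in the same interval are harmless.
#'
#' @param spore List of chromatid records.
#' @param inv_het Was the meiosis heterozygous for the inversion?
#' @return `TRUE` if no chromatid is unbalanced.
#' @export
structurally_balanced <- function(spore, inv_het = TRUE) {
  if (!inv_het) return(TRUE)
  for (td in spore) if (td$inv_xo %% 2L == 1L) return(FALSE)
  TRUE
}

#' Essential-gene complement of a spore
#'
#' Each arm block created by the chromosome 2/3 translocation carries
#' essential genes; a spore is viable only if every essential block is covered
#' by at least one chromatid. A haploid spore combining an intact K2 with an
#' intact P3 (or P2 with K3) fails this test, which is what makes the
#' translocation heterozygote half-sterile and pseudo-links the two
#' chromosomes.
#'
#' @param spore List of chromatid records.
#' @param genome Genome specification providing the essential blocks.
#' @return `TRUE` iff every essential block is covered.
#' @export
essential_complement_ok <- function(spore, genome = default_genome()) {
  if (!length(spore)) return(FALSE)
  cov <- Reduce(`|`, lapply(spore, `[[`, "cov"))
  # recombinant chromatids may carry partial blocks; fall back to the exact
  # union test when the cached all-or-nothing bits do not already decide
  if (all(cov)) return(TRUE)
  pieces <- do.call(c, lapply(spore, `[[`, "pieces"))
  fast <- .fast_genome(genome, tibble::tibble(chrom = integer(), pos = numeric()))
  all(.td_coverage(pieces, fast))
}

#' Copy-number viability
#'
#' Viable spores are haploid (1,1,1), diploid (2,2,2) or chromosome 3 disomes
#' (1,1,2); aneuploidy for chromosome 1 or 2, and any missing chromosome, is
#' lethal.
#'
#' @param spore Either a list of chromatid records or an integer copy-number
#'   vector of length 3.
#' @return `TRUE` iff the copy-number vector is one of the tolerated states.
#' @export
#' @examples
#' copy_number_viable(c(1, 1, 2))
#' copy_number_viable(c(2, 1, 1))
copy_number_viable <- function(spore) {
  cn <- if (is.numeric(spore)) as.integer(spore) else spore_copy_number(spore)
  for (ok in .VIABLE_CN) if (identical(cn, ok)) return(TRUE)
  FALSE
}

#' Drive survival probability of a spore
#'
#' Killing events at distinct killer loci are independent: the survival
#' probability is the product over killers of 1 (spore carries at least one
#' copy of the killer allele, so it is rescued) or `1 - d` otherwise. Pass
#' only the killers active in the cross — a killer whose allele is absent
#' from both parents produces no poison and must contribute 1
#' ([apply_viability()] filters automatically).
#'
#' @param spore List of chromatid records.
#' @param drive A [drive_model()] tibble of active killers.
#' @param genome Genome specification.
#' @return Survival probability in `[0, 1]`.
#' @export
drive_survival_prob <- function(spore, drive, genome = default_genome()) {
  if (!nrow(drive)) return(1)
  surv <- 1
  for (i in seq_len(nrow(drive))) {
    codes <- unlist(lapply(spore, function(td)
      .td_allele_codes(td$pieces, drive$chrom[i], drive$pos[i])))
    carrier <- any(codes == .SP_CODE[[drive$killer[i]]], na.rm = TRUE)
    if (!carrier) surv <- surv * (1 - drive$strength[i])
  }
  surv
}

# fast verdict used by the simulation loop; `spore` is a list of chromatid
# records with cached coverage/allele vectors
.spore_verdict <- function(spore, ctx) {
  if (ctx$inv_het) {
    for (td in spore) if (td$inv_xo %% 2L == 1L)
      return(list(alive = FALSE, cause = "unbalanced", surv = 0, cn = spore_copy_number(spore)))
  }
  cn <- spore_copy_number(spore)
  if (!length(spore) || !all(Reduce(`|`, lapply(spore, `[[`, "cov"))))
    return(list(alive = FALSE, cause = "missing-essential", surv = 0, cn = cn))
  if (!copy_number_viable(cn))
    return(list(alive = FALSE, cause = "aneuploid-lethal", surv = 0, cn = cn))
  surv <- 1
  drv <- ctx$drvf
  if (drv$n) {
    for (i in seq_len(drv$n)) {
      codes <- .spore_codes_at(spore, drv$loc[i])
      if (!any(codes == drv$code[i])) surv <- surv * (1 - drv$strength[i])
    }
  }
  alive <- surv >= 1 || stats::runif(1) <= surv
  list(alive = alive, cause = if (alive) NA_character_ else "drive-killed",
       surv = surv, cn = cn)
}

#' Apply the viability rules to a tetrad
#'
#' Deterministic rules first (structural balance, essential complement,
#' copy number), then stochastic killer-locus deaths; a dead spore records the
#' first failing cause.
#'
#' @param tetrad A [simulate_tetrad()] result.
#' @param cfg The generating [cross_config()].
#' @return The tetrad with a `$verdicts` tibble: one row per spore with
#'   `alive`, `cause`, `survival_prob` (the killer-survival component) and the
#'   copy-number columns `cn1`-`cn3`.
#' @export
#' @examples
#' set.seed(1)
#' cfg <- cross_config("PPP", "KKK", rec12 = "null")
#' tet <- apply_viability(simulate_tetrad(cfg), cfg)
#' tet$verdicts
apply_viability <- function(tetrad, cfg) {
  stopifnot(inherits(tetrad, "tetrad"))
  ctx <- if (inherits(cfg, "cross_config")) prepare_cross(cfg) else cfg
  v <- lapply(tetrad$spores, .spore_verdict, ctx = ctx)
  tetrad$verdicts <- tibble::tibble(
    spore = 1:4,
    alive = vapply(v, `[[`, TRUE, "alive"),
    cause = vapply(v, `[[`, "", "cause"),
    survival_prob = vapply(v, `[[`, 1, "surv"),
    cn1 = vapply(v, function(x) x$cn[1], 1L),
    cn2 = vapply(v, function(x) x$cn[2], 1L),
    cn3 = vapply(v, function(x) x$cn[3], 1L)
  )
  tetrad
}
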