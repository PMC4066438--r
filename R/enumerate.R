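# Exact spore-class enumeration for recombination-free meiosis: the oracle
# against which the simulator is checked and the likelihood kernel for killer
# strength estimation.
#
# Without crossovers every bivalent is achiasmate, each chromosome's meiosis I
# outcome is independent, and for a given spore each chromosome is in one of
# four states: absent, parent-1 homolog, parent-2 homolog, or both. Proper
# disjunction (probability p_dist) gives each single-homolog state p/2; the
# four equiprobable random pole configurations give absent and both 1/4 each
# and each single 1/4.

.CHR_STATES <- c("-", "par1", "par2", "both")

.state_probs <- function(p_dist) {
  c(`-` = (1 - p_dist) / 4,
    par1 = p_dist / 2 + (1 - p_dist) / 4,
    par2 = p_dist / 2 + (1 - p_dist) / 4,
    both = (1 - p_dist) / 4)
}

# chromatid members of a class (list of parental chromatid records)
.class_members <- function(ctx, states) {
  members <- list()
  for (cc in 1:3) {
    s <- states[cc]
    if (s == "par1" || s == "both") members <- c(members, list(ctx$parents[[1]][[cc]]))
    if (s == "par2" || s == "both") members <- c(members, list(ctx$parents[[2]][[cc]]))
  }
  members
}

#' Enumerate the exact spore-class distribution of a recombination-free cross
#'
#' Enumerates the 64 joint meiosis I outcomes of a `rec12` null cross
#' (residual recombination treated as zero), applies the deterministic
#' viability rules, and weights each class by its expected survival under the
#' active killer loci (killing treated in expectation, not sampled — this is
#' the exact oracle). Marker calls and the assay ploidy class of every class
#' are included so the table doubles as the likelihood kernel for
#' [fit_drive_model()].
#'
#' @param cfg A [cross_config()] with `rec12 = "null"`.
#' @return A tibble with one row per spore class: per-chromosome states
#'   (`chr1`-`chr3`; `-`, `par1`, `par2`, `both`), copy numbers, marker call
#'   columns (one per panel locus), `ploidy_class`, deterministic viability
#'   (`alive`, `cause`), `survival_weight`, and the exact probabilities
#'   `prob_pre` (before viability; sums to 1) and `prob_post` (after; sums to
#'   the viable fraction).
#' @export
#' @examples
#' cfg <- cross_config("PPP", "KKK", rec12 = "null", p_dist = 0,
#'                     drive = drive_model())
#' cls <- enumerate_spore_classes(cfg)
#' sum(cls$prob_post)  # 13/64 once rearrangement lethality is accounted for
enumerate_spore_classes <- function(cfg) {
  ctx <- if (inherits(cfg, "cross_config")) prepare_cross(cfg) else cfg
  if (ctx$cfg$rec12 != "null")
    stop("exact enumeration supports only rec12 = \"null\" crosses ",
         "(crossover-mode distributions are combinatorial; use simulate_cross)")
  pr <- .state_probs(ctx$cfg$p_dist)
  grid <- expand.grid(chr1 = .CHR_STATES, chr2 = .CHR_STATES, chr3 = .CHR_STATES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  panel <- ctx$cfg$panel
  drv <- ctx$drive
  n <- nrow(grid)
  prob_pre <- numeric(n); alive <- logical(n); cause <- character(n)
  weight <- numeric(n)
  cn <- matrix(0L, n, 3)
  calls <- matrix(NA_character_, n, nrow(panel))
  ploidy <- character(n)
  carrier <- matrix(FALSE, n, NROW(drv))

  for (i in seq_len(n)) {
    states <- unlist(grid[i, ], use.names = FALSE)
    prob_pre[i] <- prod(pr[states])
    members <- .class_members(ctx, states)
    cn[i, ] <- spore_copy_number(members)
    for (j in seq_len(nrow(panel)))
      calls[i, j] <- .call_string(.spore_codes_at(members, j))
    pm2 <- .spore_codes_at(members, ctx$ploidy_idx[["chr2"]])
    pm3 <- .spore_codes_at(members, ctx$ploidy_idx[["chr3"]])
    ploidy[i] <- .classify_codes(pm2, pm3)
    if (!length(members) || !all(Reduce(`|`, lapply(members, `[[`, "cov")))) {
      alive[i] <- FALSE; cause[i] <- "missing-essential"
    } else if (!copy_number_viable(cn[i, ])) {
      alive[i] <- FALSE; cause[i] <- "aneuploid-lethal"
    } else {
      alive[i] <- TRUE; cause[i] <- NA_character_
    }
    if (NROW(drv))
      for (k in seq_len(nrow(drv)))
        carrier[i, k] <- any(.spore_codes_at(members, drv$loc_idx[k]) == drv$code[k])
    weight[i] <- if (!alive[i]) 0 else if (NROW(drv))
      prod(ifelse(carrier[i, ], 1, 1 - drv$strength)) else 1
  }

  out <- tibble::as_tibble(grid)
  out$cn1 <- cn[, 1]; out$cn2 <- cn[, 2]; out$cn3 <- cn[, 3]
  for (j in seq_len(nrow(panel))) out[[panel$name[j]]] <- calls[, j]
  out$ploidy_class <- ploidy
  out$alive <- alive
  out$cause <- cause
  out$survival_weight <- weight
  out$prob_pre <- prob_pre
  out$prob_post <- prob_pre * weight
  attr(out, "killer_carrier") <- carrier
  attr(out, "drive") <- drv
  out
}

#' Exact viable fraction of a recombination-free cross
#'
#' @param cfg A [cross_config()] with `rec12 = "null"`.
#' @param classes `"all"` for the full viable fraction, `"haploid"` to
#'   restrict to euploid haploid spore classes (used for the translocation
#'   two-fold-penalty prediction).
#' @return A probability.
#' @export
#' @examples
#' no_drive <- drive_model()
#' hybrid <- cross_config("PPP", "KKK", rec12 = "null", p_dist = 0, drive = no_drive)
#' pure   <- cross_config("KKK", "KKK", rec12 = "null", p_dist = 0, drive = no_drive)
#' viable_fraction(hybrid, "haploid") / viable_fraction(pure, "haploid")  # exactly 1/2
viable_fraction <- function(cfg, classes = c("all", "haploid")) {
  classes <- match.arg(classes)
  cls <- enumerate_spore_classes(cfg)
  if (classes == "haploid")
    cls <- cls[cls$cn1 == 1L & cls$cn2 == 1L & cls$cn3 == 1L, ]
  sum(cls$prob_post)
}

#' Exact expected transmission of the killer-species allele at a marker
#'
#' The probability that a viable spore carrying exactly one allele at the
#' locus carries the killer-species allele, mirroring the assay's exclusions:
#' heterozygous diploids are excluded for all loci, heterozygous chromosome 3
#' aneuploids additionally for chromosome 3 loci, and heterozygous calls at
#' the locus itself never enter the denominator.
#'
#' @param cfg A [cross_config()] with `rec12 = "null"`.
#' @param locus Marker name (must be in the configuration's panel).
#' @param killer Species whose allele transmission is measured (`"Sk"`).
#' @return A probability.
#' @export
#' @examples
#' cfg <- cross_config("PPP", "KKK", rec12 = "null",
#'                     drive = drive_model("k3", 3L, 1316437, "Sk", 0.8))
#' expected_transmission(cfg, "ade6")   # 1 / (2 - 0.8)
expected_transmission <- function(cfg, locus, killer = "Sk") {
  stopifnot(killer %in% .SPECIES)
  cls <- enumerate_spore_classes(cfg)
  ctx_panel <- if (inherits(cfg, "cross_config")) cfg$panel else cfg$cfg$panel
  if (!locus %in% ctx_panel$name)
    stop(sprintf("locus '%s' is not in the marker panel", locus))
  chrom <- ctx_panel$chrom[match(locus, ctx_panel$name)]
  call <- cls[[locus]]
  keep <- !is.na(call) & call %in% .SPECIES & cls$ploidy_class != "het-diploid"
  if (chrom == 3L) keep <- keep & cls$ploidy_class != "het-chr3-aneuploid"
  denom <- sum(cls$prob_post[keep])
  if (denom <= 0)
    stop("undefined transmission: no viable single-allele class at this locus")
  sum(cls$prob_post[keep & call == killer]) / denom
}
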