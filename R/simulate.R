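# Synthetic cross generation: replicates the study's cross designs and
# produces spore tables (one row per surviving spore) for the statistics and
# inference layers.

.PRESET_NAMES <- c("PPPxKKK_wt", "PPPxKKK_rec12",
                   "PKKxKKK_rec12", "KRKxKKK_rec12", "KKRxKKK_rec12",
                   "KKKxKKK_wt", "KKKxKKK_rec12",
                   "PPPxPPP_wt", "PPPxPPP_rec12")

#' Named cross presets
#'
#' Fully specified configurations replicating the study's cross designs:
#' the pure-species controls, the hybrid with and without meiotic
#' recombination, and the single-heterozygous-chromosome crosses used to show
#' each killer acts autonomously. The "R" chromosomes of the `KRK` and `KKR`
#' strains are encoded with their sequenced ancestry breakpoints: `KRK`'s
#' chromosome 2 switches from *Sk* to *Sp* ancestry between the SNPs flanking
#' *mat1* (chr2 ~2,114 kb), and `KKR` carries *Sp* ancestry on chromosome 3
#' proximal of ~1,559 kb and on the chromosome 3 tail of its translocated
#' chromosome 2 distal of ~2,292 kb.
#'
#' All presets share the calibrated drive model (inert wherever a killer
#' locus is homozygous), `p_dist = 0.5` and a residual Rec12-independent
#' crossover rate of 0.005 per chromosome per meiosis in the `rec12` null
#' crosses.
#'
#' @param name One of `preset_names()`.
#' @return A [cross_config()].
#' @export
#' @examples
#' cross_preset("PKKxKKK_rec12")
cross_preset <- function(name) {
  if (!name %in% .PRESET_NAMES)
    stop("unknown preset '", name, "'; see preset_names()")
  g <- default_genome()
  len <- g$lengths
  krk_chr2 <- chromosome_spec("K", tibble::tibble(
    chrom  = c(2, 2, 3),
    start  = c(g$trans[["chr2"]], 2114110, g$trans[["chr3"]]),
    end    = c(2114109, len[2], len[3]),
    species = c("Sk", "Sp", "Sk")))
  kkr_chr2 <- chromosome_spec("K", tibble::tibble(
    chrom  = c(2, 3, 3),
    start  = c(g$trans[["chr2"]], g$trans[["chr3"]], 2291601),
    end    = c(len[2], 2291600, len[3]),
    species = c("Sk", "Sk", "Sp")))
  kkr_chr3 <- chromosome_spec("K", tibble::tibble(
    chrom  = c(2, 3, 3),
    start  = c(1, 1, 1559155),
    end    = c(g$trans[["chr2"]] - 1, 1559154, g$trans[["chr3"]] - 1),
    species = c("Sk", "Sp", "Sk")))
  parent1 <- switch(name,
    PPPxKKK_wt = , PPPxKKK_rec12 = , PPPxPPP_wt = , PPPxPPP_rec12 = "PPP",
    PKKxKKK_rec12 = "PKK",
    KRKxKKK_rec12 = parent_spec(list(chromosome_spec("K", "Sk"), krk_chr2,
                                     chromosome_spec("K", "Sk"))),
    KKRxKKK_rec12 = parent_spec(list(chromosome_spec("K", "Sk"), kkr_chr2,
                                     kkr_chr3)),
    KKKxKKK_wt = , KKKxKKK_rec12 = "KKK")
  parent2 <- if (grepl("xPPP", name)) "PPP" else "KKK"
  rec12 <- if (grepl("_wt$", name)) "wt" else "null"
  panel <- if (name == "PPPxKKK_wt") marker_panel() else marker_panel(ploidy_only = TRUE)
  cross_config(parent1, parent2, genome = g, rec12 = rec12, panel = panel)
}

#' @rdname cross_preset
#' @export
preset_names <- function() .PRESET_NAMES

#' Simulate a cross and genotype the surviving spores
#'
#' Simulates `n_meioses` tetrads, applies the viability rules, and genotypes
#' the spores at the configured marker panel, recording the assay's ploidy
#' call for each. By default only viable spores are recorded (dead spores are
#' invisible to the assay); `full_census = TRUE` keeps all `4 * n_meioses`
#' products with their causes of death, for model checking.
#'
#' @param cfg A [cross_config()] or preset name.
#' @param n_meioses Number of meioses to simulate.
#' @param seed Optional integer seed (restored on exit); identical seed and
#'   configuration give identical tables.
#' @param full_census Record dead spores too?
#' @return A tibble with columns `meiosis_id`, `spore_id`, one call column
#'   per panel marker (`"Sp"`, `"Sk"`, `"Sp/Sk"` or `NA`), `ploidy_class`,
#'   `viability`, `cause`. Attributes: `config_hash`, `seed`, `n_meioses`.
#' @export
#' @examples
#' tab <- simulate_cross(cross_preset("PPPxKKK_rec12"), 200, seed = 1)
#' transmission_summary(tab, marker_panel(ploidy_only = TRUE))
simulate_cross <- function(cfg, n_meioses, seed = NULL, full_census = FALSE) {
  if (is.character(cfg)) cfg <- cross_preset(cfg)
  stopifnot(n_meioses > 0)
  ctx <- prepare_cross(cfg)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  panel <- ctx$cfg$panel
  npanel <- nrow(panel)
  ntot <- 4L * n_meioses
  meiosis_id <- integer(ntot); spore_id <- integer(ntot)
  calls <- matrix(NA_character_, ntot, npanel)
  ploidy <- character(ntot); viability <- character(ntot); cause <- character(ntot)
  filled <- 0L

  for (m in seq_len(n_meioses)) {
    tet <- simulate_tetrad(ctx)
    for (s in 1:4) {
      spore <- tet$spores[[s]]
      v <- .spore_verdict(spore, ctx)
      if (!v$alive && !full_census) next
      filled <- filled + 1L
      meiosis_id[filled] <- m; spore_id[filled] <- s
      for (j in seq_len(npanel))
        calls[filled, j] <- .call_string(.spore_codes_at(spore, j))
      ploidy[filled] <- .classify_codes(
        .spore_codes_at(spore, ctx$ploidy_idx[["chr2"]]),
        .spore_codes_at(spore, ctx$ploidy_idx[["chr3"]]))
      viability[filled] <- if (v$alive) "alive" else "dead"
      cause[filled] <- if (v$alive) NA_character_ else v$cause
    }
  }
  idx <- seq_len(filled)
  out <- tibble::tibble(meiosis_id = meiosis_id[idx], spore_id = spore_id[idx])
  for (j in seq_len(npanel)) out[[panel$name[j]]] <- calls[idx, j]
  out$ploidy_class <- ploidy[idx]
  out$viability <- viability[idx]
  out$cause <- cause[idx]
  attr(out, "config_hash") <- hash_config(cfg)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "n_meioses") <- n_meioses
  out
}

# FNV-1a hash of the canonical configuration string; stable across sessions.
# 32-bit arithmetic kept in doubles (R's bitwXor is limited to signed ints).
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' @rdname simulate_cross
#' @export
hash_config <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  canon <- list(
    parents = lapply(cfg$parents, function(p) lapply(p, function(ch)
      list(ch$karyotype,
           if (is.character(ch$ancestry)) ch$ancestry else as.data.frame(ch$ancestry)))),
    drive = as.data.frame(cfg$drive),
    rec12 = cfg$rec12, residual_rate = cfg$residual_rate, p_dist = cfg$p_dist,
    panel = as.data.frame(cfg$panel), ploidy_markers = cfg$ploidy_markers,
    genome = cfg$genome[c("lengths", "centromeres", "inversion", "trans", "cM_per_kb")])
  .fnv1a(paste(deparse(canon), collapse = ""))
}
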