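# Genome model: the two-species karyotype, rearrangements, loci and cross
# configurations. All coordinates are 1-based, inclusive, on the S. pombe (Sp)
# reference; ancestry of any chromatid is expressed in these coordinates no
# matter which physical arrangement (karyotype) carries it.

# Sp reference chromosome lengths (bp). The exact values only need to exceed
# every locus and breakpoint used by the model.
.SP_LENGTHS <- c(5579133, 4539804, 2452883)

# Approximate centromere midpoints (bp); cen2 lies distal of the chr2
# translocation junction and cen3 proximal of the chr3 junction, which is what
# the rearrangement topology requires.
.SP_CENTROMERES <- c(3753687, 1602264, 1070904)

.SPECIES <- c("Sp", "Sk")

#' Two-species genome specification
#'
#' Builds the default genome shared by every cross: three chromosomes, the
#' large chromosome 1 inversion carried by the *Sp* lineage (*Sk* retains the
#' ancestral arrangement), and the reciprocal chromosome 2/3 translocation
#' carried by the *Sk* lineage. The translocation junctions partition
#' chromosomes 2 and 3 into four essential blocks; every viable genome must
#' carry each block at least once. Essential genes are modelled coarsely as
#' one block per arm segment (the blocks that swapped chromosomes carry the
#' landmark essential genes *alr2* and *SPCP1E11.08*).
#'
#' @param lengths Integer vector of three chromosome lengths in bp.
#' @param inversion Length-2 vector, start/end of the chromosome 1 inversion
#'   (Sp reference bp).
#' @param trans_chr2,trans_chr3 Translocation junction positions on
#'   chromosomes 2 and 3 (Sp reference bp).
#' @param cM_per_kb Genome-average genetic map rate (centimorgan per kb).
#' @param centromeres Centromere midpoints (bp), one per chromosome.
#'
#' @return An object of class `genome_spec`: a list with the chromosome
#'   lengths, centromeres, rearrangement breakpoints, map rate, and a tibble
#'   of homology regions (`$regions`) used as essential blocks.
#' @export
#' @examples
#' g <- default_genome()
#' diff(g$inversion)   # inversion span in bp
#' g$regions
default_genome <- function(lengths = .SP_LENGTHS,
                           inversion = c(2683632, 4911515),
                           trans_chr2 = 676281,
                           trans_chr3 = 1932034,
                           cM_per_kb = 0.16,
                           centromeres = .SP_CENTROMERES) {
  stopifnot(length(lengths) == 3, all(lengths > 0),
            length(inversion) == 2, inversion[1] < inversion[2],
            inversion[2] <= lengths[1],
            trans_chr2 > 1, trans_chr2 < lengths[2],
            trans_chr3 > 1, trans_chr3 < lengths[3],
            cM_per_kb >= 0,
            length(centromeres) == 3, all(centromeres < lengths))
  if (centromeres[2] <= trans_chr2)
    stop("chromosome 2 centromere must lie distal of the translocation junction")
  if (centromeres[3] >= trans_chr3)
    stop("chromosome 3 centromere must lie proximal of the translocation junction")
  regions <- tibble::tibble(
    region   = c("chr1", "chr2L", "chr2R", "chr3L", "chr3R"),
    chrom    = c(1L, 2L, 2L, 3L, 3L),
    start    = c(1, 1, trans_chr2, 1, trans_chr3),
    end      = c(lengths[1], trans_chr2 - 1, lengths[2], trans_chr3 - 1, lengths[3]),
    landmark = c(NA, "alr2", NA, NA, "SPCP1E11.08")
  )
  structure(
    list(lengths = as.numeric(lengths),
         centromeres = as.numeric(centromeres),
         inversion = as.numeric(inversion),
         trans = c(chr2 = as.numeric(trans_chr2), chr3 = as.numeric(trans_chr3)),
         cM_per_kb = cM_per_kb,
         regions = regions),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec>\n")
  cat(sprintf("  chromosomes: %s bp\n", paste(format(x$lengths, big.mark = ","), collapse = ", ")))
  cat(sprintf("  chr1 inversion (Sp lineage): %s..%s\n",
              format(x$inversion[1], big.mark = ","), format(x$inversion[2], big.mark = ",")))
  cat(sprintf("  chr2/chr3 translocation (Sk lineage): chr2:%s / chr3:%s\n",
              format(x$trans[1], big.mark = ","), format(x$trans[2], big.mark = ",")))
  cat(sprintf("  map rate: %.2f cM/kb\n", x$cM_per_kb))
  invisible(x)
}

#' Convert physical span to genetic distance
#'
#' Linear conversion at the genome-average map rate (default 0.16 cM/kb), the
#' rate used when an interval is too large to measure directly from crosses.
#'
#' @param span_bp Physical span in bp (scalar or vector, >= 0).
#' @param cM_per_kb Map rate in cM per kb (>= 0).
#' @return Genetic length in centimorgans.
#' @seealso [genetic_to_physical()] for the exact inverse.
#' @export
#' @examples
#' physical_to_genetic(4911515 - 2683632)  # the chr1 inversion, > 350 cM
physical_to_genetic <- function(span_bp, cM_per_kb = 0.16) {
  if (any(span_bp < 0)) stop("span_bp must be non-negative")
  if (any(cM_per_kb < 0)) stop("cM_per_kb must be non-negative")
  span_bp / 1000 * cM_per_kb
}

#' @rdname physical_to_genetic
#' @param cM Genetic length in centimorgans (>= 0).
#' @export
genetic_to_physical <- function(cM, cM_per_kb = 0.16) {
  if (any(cM < 0)) stop("cM must be non-negative")
  if (any(cM_per_kb <= 0)) stop("cM_per_kb must be positive to invert")
  cM / cM_per_kb * 1000
}

#' Default marker panel
#'
#' The genetic markers used to genotype viable spores, as a tibble. Positions
#' are approximate (the model only uses them through the linear bp-to-cM map):
#' `lys1` and `lys7` lie inside the chromosome 1 inversion, `leu1` and `ade6`
#' sit closest to the chromosome 2 and 3 killer loci, and `his5`/`ade6` are
#' the codominant ploidy markers on chromosomes 2 and 3.
#'
#' @param ploidy_only If `TRUE`, return only the three-locus panel
#'   (`lys1`, `his5`, `ade6`) used in the recombination-free crosses.
#' @return Tibble with columns `name`, `chrom`, `pos`.
#' @export
#' @examples
#' marker_panel()
marker_panel <- function(ploidy_only = FALSE) {
  panel <- tibble::tibble(
    name  = c("ura1", "arg3", "lys7", "lys1",
              "lys4", "his4", "ade8", "his5", "leu1",
              "ura4", "ade6"),
    chrom = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L),
    pos   = c(1450000, 2300000, 3450000, 4240000,
              1800000, 2200000, 2500000, 2900000, 3260000,
              115589, 1316437)
  )
  if (ploidy_only) panel <- panel[panel$name %in% c("lys1", "his5", "ade6"), ]
  panel
}

#' Killer (meiotic drive) locus models
#'
#' A drive model is a tibble of gamete-killer loci. Each row is one killer:
#' its chromosome, position, the ancestry that carries the killer allele, and
#' the strength `d` — the probability that a spore *lacking* the killer allele
#' at that locus dies. A spore carrying at least one copy of the killer allele
#' is fully resistant (poison/antidote at one locus), which makes heterozygous
#' diploids and chromosome 3 heterozygous disomes immune.
#'
#' `drive_model()` builds a model from vectors; `calibrated_drive_model()`
#' returns the package's calibrated default: one *Sk* killer per chromosome
#' with strengths derived as single-locus maximum-likelihood estimates from
#' the observed 72% / 94% / 82% transmissions of the nearest markers, plus the
#' hypothesised weak *Sp* counter-killer on chromosome 3 (default strength
#' 0.2; a hypothesis parameter, not a measured value).
#'
#' @param locus Character names for the killer loci.
#' @param chrom Integer chromosome ids (1-3).
#' @param pos Positions in Sp reference bp.
#' @param killer Ancestry carrying the killer allele, `"Sk"` or `"Sp"`.
#' @param strength Kill probabilities in `[0, 1]`.
#' @return Tibble of class `drive_model` with columns
#'   `locus`, `chrom`, `pos`, `killer`, `strength`.
#' @export
#' @examples
#' calibrated_drive_model()
#' drive_model("k1", 1L, 4.3e6, "Sk", 0.7)
drive_model <- function(locus = character(), chrom = integer(),
                        pos = numeric(), killer = character(),
                        strength = numeric()) {
  dm <- tibble::tibble(locus = as.character(locus), chrom = as.integer(chrom),
                       pos = as.numeric(pos), killer = as.character(killer),
                       strength = as.numeric(strength))
  if (nrow(dm)) {
    stopifnot(all(dm$killer %in% .SPECIES))
    if (any(dm$strength < 0 | dm$strength > 1))
      stop("drive strengths must be in [0, 1]")
    if (anyDuplicated(dm[, c("chrom", "killer")]))
      stop("at most one killer per ancestry per chromosome")
  }
  class(dm) <- c("drive_model", class(dm))
  dm
}

#' @rdname drive_model
#' @param d1,d2,d3 Strengths of the *Sk* killers on chromosomes 1-3. Defaults
#'   are the single-locus MLEs `2 - 1/t` of the nearest-marker transmissions
#'   (t = 0.72, 0.94, 0.82).
#' @param counter3 Strength of the hypothesised *Sp* chromosome 3
#'   counter-killer (0 disables it).
#' @export
calibrated_drive_model <- function(d1 = 2 - 1 / 0.72,
                                   d2 = 2 - 1 / 0.94,
                                   d3 = 2 - 1 / 0.82,
                                   counter3 = 0.2) {
  dm <- drive_model(
    locus    = c("sk1", "sk2", "sk3", "sp3"),
    chrom    = c(1L, 2L, 3L, 3L),
    pos      = c(4300000, 3300000, 1300000, 1300000),
    killer   = c("Sk", "Sk", "Sk", "Sp"),
    strength = c(d1, d2, d3, counter3)
  )
  dm[dm$strength > 0, ]
}

# ---- parental chromosomes and cross configuration -------------------------

#' Specify one parental chromosome
#'
#' @param karyotype `"P"` (Sp physical arrangement) or `"K"` (Sk arrangement;
#'   for chromosomes 2/3 this means the translocated arrangement, for
#'   chromosome 1 the ancestral, non-inverted arrangement).
#' @param ancestry Either a single species (`"Sp"`/`"Sk"`) giving uniform
#'   ancestry, or a tibble/data.frame with columns `chrom`, `start`, `end`,
#'   `species` giving the ancestry mosaic of the chromosome's content in Sp
#'   reference coordinates (used for recombinant "R" chromosomes).
#' @return A `chromosome_spec` list.
#' @export
#' @examples
#' chromosome_spec("K", "Sk")
#' # KRK-style recombinant chromosome 2: Sk karyotype, Sp alleles distal of mat1
#' chromosome_spec("K", tibble::tibble(
#'   chrom = c(2, 2, 3), start = c(676281, 2114110, 1932034),
#'   end = c(2114109, 4539804, 2452883), species = c("Sk", "Sp", "Sk")))
chromosome_spec <- function(karyotype, ancestry = "Sp") {
  stopifnot(karyotype %in% c("P", "K"))
  if (is.character(ancestry)) {
    stopifnot(length(ancestry) == 1, ancestry %in% .SPECIES)
  } else {
    ancestry <- tibble::as_tibble(ancestry)
    stopifnot(all(c("chrom", "start", "end", "species") %in% names(ancestry)),
              all(ancestry$species %in% .SPECIES))
  }
  structure(list(karyotype = karyotype, ancestry = ancestry),
            class = "chromosome_spec")
}

#' Specify a haploid parent
#'
#' A parent is three chromosome specifications. The shorthand string form
#' `"PKK"` means chromosome 1 has Sp karyotype and uniform Sp ancestry,
#' chromosomes 2 and 3 Sk karyotype and Sk ancestry, etc.
#'
#' @param spec Either a 3-character string over `{P, K}` or a list of three
#'   [chromosome_spec()] objects.
#' @return A list of three `chromosome_spec`s (class `parent_spec`).
#' @export
#' @examples
#' parent_spec("PKK")
parent_spec <- function(spec) {
  if (is.character(spec)) {
    stopifnot(length(spec) == 1, nchar(spec) == 3)
    letters3 <- strsplit(spec, "")[[1]]
    stopifnot(all(letters3 %in% c("P", "K")))
    out <- lapply(letters3, function(k)
      chromosome_spec(k, if (k == "P") "Sp" else "Sk"))
  } else {
    stopifnot(is.list(spec), length(spec) == 3,
              all(vapply(spec, inherits, TRUE, "chromosome_spec")))
    out <- spec
  }
  structure(out, class = "parent_spec")
}

#' Configure a cross
#'
#' Bundles everything that defines one cross: the genome, the two haploid
#' parents, the recombination regime (`rec12` wild type with Haldane
#' crossovers, or `rec12` null with only rare residual events), the fidelity
#' of the recombination-independent (distributive) segregation system for
#' achiasmate chromosomes, the killer-locus model, and the marker panel used
#' to genotype spores.
#'
#' @param parent1,parent2 [parent_spec()] objects or shorthand strings.
#' @param genome A [default_genome()] specification.
#' @param drive A [drive_model()] tibble.
#' @param rec12 `"wt"` or `"null"`.
#' @param residual_rate Probability per chromosome per meiosis of one
#'   Rec12-independent crossover in `rec12 = "null"` mode.
#' @param p_dist Probability that an achiasmate homolog pair still disjoins
#'   properly at meiosis I (0 = fully random, 1 = always proper).
#' @param panel Marker panel tibble (`name`, `chrom`, `pos`).
#' @param ploidy_markers Named character vector giving the codominant markers
#'   used for the ploidy assay on chromosomes 2 and 3.
#' @return An object of class `cross_config`.
#' @export
#' @examples
#' cfg <- cross_config("PPP", "KKK", rec12 = "null")
#' validate_cross(cfg)
cross_config <- function(parent1, parent2,
                         genome = default_genome(),
                         drive = calibrated_drive_model(),
                         rec12 = c("wt", "null"),
                         residual_rate = 0.005,
                         p_dist = 0.5,
                         panel = marker_panel(ploidy_only = TRUE),
                         ploidy_markers = c(chr2 = "his5", chr3 = "ade6")) {
  rec12 <- match.arg(rec12)
  cfg <- structure(
    list(genome = genome,
         parents = list(parent_spec(parent1), parent_spec(parent2)),
         drive = drive,
         rec12 = rec12,
         residual_rate = residual_rate,
         p_dist = p_dist,
         panel = tibble::as_tibble(panel),
         ploidy_markers = ploidy_markers),
    class = "cross_config")
  cfg
}

#' @export
print.cross_config <- function(x, ...) {
  karyo <- function(p) paste(vapply(p, function(ch) {
    unif <- is.character(ch$ancestry)
    if (unif) ch$karyotype else "R"
  }, ""), collapse = "")
  cat("<cross_config>\n")
  cat(sprintf("  parents: %s x %s   rec12: %s   p_dist: %.2f\n",
              karyo(x$parents[[1]]), karyo(x$parents[[2]]), x$rec12, x$p_dist))
  cat(sprintf("  killers: %s\n", if (nrow(x$drive) == 0) "none" else
    paste(sprintf("%s(chr%d %s d=%.2f)", x$drive$locus, x$drive$chrom,
                  x$drive$killer, x$drive$strength), collapse = ", ")))
  invisible(x)
}

#' Validate a cross configuration
#'
#' Checks that probabilities and rates lie in `[0, 1]`, that every locus lies
#' on its chromosome, and that each parent's haploid genome covers every
#' essential block exactly once (a parent built from an intact K2 and an
#' intact P3, for example, is missing the chr2L block that carries *alr2*).
#'
#' @param cfg A [cross_config()].
#' @return A tibble of violations with columns `field` and `message`;
#'   zero rows means the configuration is valid.
#' @export
validate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  bad <- list()
  note <- function(field, message)
    bad[[length(bad) + 1]] <<- tibble::tibble(field = field, message = message)

  g <- cfg$genome
  for (p in c("residual_rate", "p_dist"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      note(p, sprintf("%s = %g outside [0, 1]", p, cfg[[p]]))
  if (nrow(cfg$drive)) {
    off <- cfg$drive$strength < 0 | cfg$drive$strength > 1
    if (any(off))
      note("drive", sprintf("strength %g at locus '%s' outside [0, 1]",
                            cfg$drive$strength[off][1], cfg$drive$locus[off][1]))
    out <- cfg$drive$pos < 1 | cfg$drive$pos > g$lengths[cfg$drive$chrom]
    if (any(out))
      note("drive", sprintf("locus '%s' outside chromosome %d",
                            cfg$drive$locus[out][1], cfg$drive$chrom[out][1]))
  }
  out <- cfg$panel$pos < 1 | cfg$panel$pos > g$lengths[cfg$panel$chrom]
  if (any(out))
    note("panel", sprintf("marker '%s' outside chromosome %d",
                          cfg$panel$name[out][1], cfg$panel$chrom[out][1]))
  for (pm in cfg$ploidy_markers)
    if (!pm %in% cfg$panel$name)
      note("ploidy_markers", sprintf("ploidy marker '%s' not in panel", pm))

  for (i in 1:2) {
    chroms <- try(parent_chromosomes(g, cfg$parents[[i]]), silent = TRUE)
    if (inherits(chroms, "try-error")) {
      note(sprintf("parent%d", i), "cannot construct parental chromosomes")
      next
    }
    cov <- Reduce(`+`, lapply(chroms, function(td) td$cov))
    miss <- cov == 0
    if (any(miss))
      note(sprintf("parent%d", i),
           sprintf("missing essential segment %s",
                   paste(g$regions$region[miss], collapse = ", ")))
    if (any(cov > 1))
      note(sprintf("parent%d", i),
           sprintf("essential segment %s present more than once in a haploid set",
                   paste(g$regions$region[cov > 1], collapse = ", ")))
  }
  if (length(bad)) dplyr::bind_rows(bad) else
    tibble::tibble(field = character(), message = character())
}
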