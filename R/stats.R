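# Descriptive statistics on spore tables: viable spore yield, G-test
# transmission bias, Haldane map distances, aneuploid rates.

#' Viable spore yield
#'
#' Fertility measured as viable colonies recovered per cell induced to
#' undergo meiosis. Because cells may divide before meiosis, the assay is
#' relative and values can exceed 4 (the number of spores per ascus).
#'
#' @param viable_colonies Colony-forming units recovered (>= 0).
#' @param cells_plated Cells plated on sporulation medium (> 0).
#' @return Tibble with `viable_colonies`, `cells_plated`, `yield`.
#' @export
#' @examples
#' viable_spore_yield(360, 100)   # yield 3.6
viable_spore_yield <- function(viable_colonies, cells_plated) {
  if (any(cells_plated <= 0)) stop("cells_plated must be positive")
  if (any(viable_colonies < 0)) stop("viable_colonies must be non-negative")
  tibble::tibble(viable_colonies = viable_colonies,
                 cells_plated = cells_plated,
                 yield = viable_colonies / cells_plated)
}

#' G-test of 50:50 transmission
#'
#' Likelihood-ratio goodness-of-fit test of the observed allele counts
#' against Mendelian 1:1 expectation: `G = 2 * sum(O * ln(O/E))` with one
#' degree of freedom; empty cells contribute zero. The Williams small-sample
#' correction (`G / (1 + 1/(2n))`) is available but off by default.
#'
#' @param n_killer,n_other Allele counts (vectors of equal length).
#' @param williams Apply the Williams correction?
#' @return Tibble with `n`, `n_killer`, `n_other`, `t` (killer-allele
#'   proportion), `G`, `p` (chi-square, 1 df).
#' @export
#' @examples
#' transmission_test(72, 28)  # t = 0.72, G = 20.04
transmission_test <- function(n_killer, n_other, williams = FALSE) {
  n <- n_killer + n_other
  if (any(n <= 0)) stop("at least one allele count must be positive")
  if (any(n_killer < 0 | n_other < 0)) stop("counts must be non-negative")
  gterm <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  G <- 2 * (gterm(n_killer, n / 2) + gterm(n_other, n / 2))
  if (williams) G <- G / (1 + 1 / (2 * n))
  tibble::tibble(n = n, n_killer = n_killer, n_other = n_other,
                 t = n_killer / n, G = G,
                 p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Haldane mapping function
#'
#' `haldane_cM()` converts a recombinant fraction to map distance,
#' `cM = -50 * ln(1 - 2r)`; `haldane_r()` is the exact inverse,
#' `r = (1 - exp(-2 cM/100)) / 2`. Both assume crossovers without
#' interference.
#'
#' @param r Recombinant fraction(s) in `[0, 0.5)`.
#' @return Map distance in centimorgans / recombinant fraction.
#' @export
#' @examples
#' haldane_cM(0.2)        # 25.54 cM
#' haldane_r(16)          # 0.1370
haldane_cM <- function(r) {
  if (any(r < 0)) stop("recombinant fraction must be non-negative")
  if (any(r >= 0.5)) stop("recombinant fraction >= 0.5: loci are unlinked")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cM
#' @param cM Map distance(s) in centimorgans (>= 0).
#' @export
haldane_r <- function(cM) {
  if (any(cM < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * cM / 100)) / 2
}

#' Genetic interval from parental and recombinant counts
#'
#' @param parentals,recombinants Spore counts (total > 0).
#' @return Tibble with `n`, `parentals`, `recombinants`, `r`, `cM` (Haldane;
#'   `NA` when unlinked) and `unlinked` (`TRUE` when `r >= 0.5`).
#' @export
#' @examples
#' interval_from_counts(90, 10)   # r = 0.10, 11.16 cM
interval_from_counts <- function(parentals, recombinants) {
  n <- parentals + recombinants
  if (any(n <= 0)) stop("total spore count must be positive")
  r <- recombinants / n
  unlinked <- r >= 0.5
  cM <- rep(NA_real_, length(r))
  cM[!unlinked] <- -50 * log(1 - 2 * r[!unlinked])
  tibble::tibble(n = n, parentals = parentals, recombinants = recombinants,
                 r = r, cM = cM, unlinked = unlinked)
}

#' Aneuploids and diploids produced per meiosis
#'
#' The product of the viable spore yield (viable spores per cell induced to
#' undergo meiosis) and the fraction of viable spores that are aneuploid or
#' diploid: a rate per cell that separates "aneuploids arise more often" from
#' "haploids die more often".
#'
#' @param yield Viable spore yield (numeric, or a [viable_spore_yield()]
#'   tibble).
#' @param fraction_aneuploid_or_diploid Proportion in `[0, 1]`.
#' @return Numeric rate per cell.
#' @export
#' @examples
#' aneuploids_per_meiosis(3.6, 0.055)
aneuploids_per_meiosis <- function(yield, fraction_aneuploid_or_diploid) {
  if (is.data.frame(yield)) yield <- yield$yield
  f <- fraction_aneuploid_or_diploid
  if (any(f < 0 | f > 1)) stop("fraction must be in [0, 1]")
  if (any(yield < 0)) stop("yield must be non-negative")
  yield * f
}

#' Expected transmission of a killer allele at a linked marker
#'
#' Closed form for a single killer of strength `d` observed through a marker
#' at recombinant fraction `r`, with haploid survivors only:
#' `t = (1 - r d) / (2 - d)`. At `r = 0` this is `1 / (2 - d)`; at `d = 0`
#' it is 1/2 everywhere; and at `r = 1/2` the algebra collapses to exactly
#' 1/2 for every `d` — under this single-killer haploid model an unlinked
#' marker carries no drive signal.
#'
#' @param d Killer strength(s) in `[0, 1]`.
#' @param r Recombinant fraction(s) in `[0, 0.5]`.
#' @return Expected killer-allele transmission among viable spores.
#' @export
#' @examples
#' transmission_curve(0.8, 0.1)   # 0.7667
transmission_curve <- function(d, r) {
  if (any(d < 0 | d > 1)) stop("d must be in [0, 1]")
  if (any(r < 0 | r > 0.5)) stop("r must be in [0, 0.5]")
  (1 - r * d) / (2 - d)
}

# ---- spore-table statistics ------------------------------------------------

.viable_rows <- function(table) {
  if ("viability" %in% names(table)) table[table$viability == "alive", , drop = FALSE]
  else table
}

#' Per-locus transmission summary of a spore table
#'
#' Applies the assay's exclusion rules (heterozygous diploids dropped for all
#' loci, heterozygous chromosome 3 aneuploids dropped for chromosome 3 loci,
#' heterozygous calls at the locus itself dropped) and G-tests each marker
#' against 50:50.
#'
#' @param table A spore table ([simulate_cross()] output or
#'   [read_spore_table()]).
#' @param panel Marker panel tibble (`name`, `chrom`, `pos`); only panel loci
#'   present as columns of `table` are summarised.
#' @param killer Species counted in the numerator (default `"Sk"`).
#' @param williams Apply the Williams correction in the G-test?
#' @return Tibble with one row per locus: `locus`, `chrom`, `pos`, counts,
#'   `t`, `G`, `p`.
#' @export
transmission_summary <- function(table, panel = marker_panel(), killer = "Sk",
                                 williams = FALSE) {
  stopifnot(killer %in% .SPECIES)
  other <- setdiff(.SPECIES, killer)
  tab <- .viable_rows(table)
  tab <- tab[tab$ploidy_class != "het-diploid", , drop = FALSE]
  panel <- panel[panel$name %in% names(table), , drop = FALSE]
  purrr::pmap_dfr(panel, function(name, chrom, pos) {
    rows <- tab
    if (chrom == 3L)
      rows <- rows[rows$ploidy_class != "het-chr3-aneuploid", , drop = FALSE]
    call <- rows[[name]]
    nk <- sum(call == killer, na.rm = TRUE)
    no <- sum(call == other, na.rm = TRUE)
    res <- transmission_test(nk, no, williams = williams)
    dplyr::bind_cols(tibble::tibble(locus = name, chrom = chrom, pos = pos), res)
  })
}

#' Two-point map distance from a spore table
#'
#' Scores each viable haploid-call spore with unambiguous calls at both loci
#' as parental (same-species alleles) or recombinant, and converts the
#' recombinant fraction to centimorgans with Haldane's formula. Spores are
#' scored individually, not as tetrads.
#'
#' @param table A spore table.
#' @param locus_a,locus_b Marker column names.
#' @return One-row tibble as [interval_from_counts()], plus the locus names.
#' @export
map_interval <- function(table, locus_a, locus_b) {
  stopifnot(all(c(locus_a, locus_b) %in% names(table)))
  tab <- .viable_rows(table)
  tab <- tab[tab$ploidy_class == "haploid-call", , drop = FALSE]
  a <- tab[[locus_a]]; b <- tab[[locus_b]]
  ok <- a %in% .SPECIES & b %in% .SPECIES
  rec <- sum(a[ok] != b[ok])
  par <- sum(a[ok] == b[ok])
  dplyr::bind_cols(tibble::tibble(locus_a = locus_a, locus_b = locus_b),
                   interval_from_counts(par, rec))
}

#' Ploidy-class composition of the viable spores
#'
#' @param table A spore table.
#' @return Tibble with `ploidy_class`, `n`, `fraction` over viable spores.
#' @export
ploidy_summary <- function(table) {
  tab <- .viable_rows(table)
  all_classes <- c("haploid-call", "het-diploid", "het-chr3-aneuploid")
  counts <- table(factor(tab$ploidy_class, levels = all_classes))
  tibble::tibble(ploidy_class = all_classes,
                 n = as.integer(counts),
                 fraction = if (nrow(tab)) as.numeric(counts) / nrow(tab) else 0)
}
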