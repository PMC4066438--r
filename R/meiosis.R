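# Meiosis engine: crossover placement (interference-free, Haldane-consistent),
# MI/MII segregation with a partially effective distributive system for
# achiasmate bivalents, and spore packaging.

# Crossover events are processed per chromosome arm, outward from the
# centromere, with axis-occupancy tracking: a crossover at position x pairs
# two synaptic axes (one chromatid slot of each parent), but the molecules
# exchanging their distal tails are the ones currently *occupying* those axes
# at x — occupancy swaps at every crossover. Without this, multi-crossover
# ancestry switches are undercounted and two-point recombination falls below
# Haldane's function. Occupancy carries across the translocation junctions
# (e.g. the chr2L arm continues the chr2R-left path on a P2 axis and the
# chr3L-right path on a K3 axis).

#' Draw crossover events for one bivalent interval
#'
#' The crossover model is a Poisson process with no chiasma or chromatid
#' interference: the event count for a bivalent of genetic length d Morgans is
#' Poisson with mean 2d (two of the four chromatids are involved in each
#' event, so per-chromatid map length is d), and positions are uniform in
#' genetic distance. This reproduces Haldane's mapping function exactly.
#'
#' @param cM Genetic length of the interval in centimorgans (>= 0).
#' @return Numeric vector of event positions in cM from the interval start
#'   (length is the Poisson draw; possibly empty).
#' @export
#' @examples
#' set.seed(1)
#' mean(replicate(2000, length(draw_crossovers(50))))  # ~ 1.0
draw_crossovers <- function(cM) {
  if (cM < 0) stop("genetic length must be non-negative")
  if (cM == 0) return(numeric())
  n <- stats::rpois(1L, 2 * cM / 100)
  sort(stats::runif(n, 0, cM))
}

#' Segregate one bivalent into four chromatid sets
#'
#' Meiosis I disjoins the two homologs to opposite poles whenever the bivalent
#' received at least one crossover (obligate disjunction of chiasmate
#' bivalents). An achiasmate bivalent disjoins properly with probability
#' `p_dist` (the recombination-independent distributive system); otherwise
#' each homolog picks a pole independently, so a spore receives 1 copy with
#' probability 1/2 and 0 or 2 copies with probability 1/4 each. Meiosis II
#' always separates sisters.
#'
#' @param sisters1,sisters2 Lists of the two sister chromatids of each
#'   homolog (any R objects; the engine passes chromatid records).
#' @param chiasmate Did the bivalent receive a crossover?
#' @param p_dist Distributive-segregation fidelity in `[0, 1]`.
#' @return List of four lists: the chromatids each spore receives from this
#'   bivalent (0, 1 or 2 chromatids per spore).
#' @export
#' @examples
#' set.seed(1)
#' lengths(segregate_bivalent(list("a1", "a2"), list("b1", "b2"),
#'                            chiasmate = TRUE, p_dist = 0))
segregate_bivalent <- function(sisters1, sisters2, chiasmate, p_dist) {
  stopifnot(p_dist >= 0, p_dist <= 1)
  proper <- chiasmate || stats::runif(1) < p_dist
  if (proper) {
    pole1 <- if (stats::runif(1) < 0.5) 1L else 2L
    poles <- c(pole1, 3L - pole1)
  } else {
    poles <- c(sample(2L, 1L), sample(2L, 1L))
  }
  out <- list(list(), list(), list(), list())
  for (h in 1:2) {
    sis <- if (h == 1) sisters1 else sisters2
    slots <- if (poles[h] == 1L) c(1L, 2L) else c(3L, 4L)
    ord <- sample.int(2L)
    out[[slots[1]]] <- c(out[[slots[1]]], sis[ord[1]])
    out[[slots[2]]] <- c(out[[slots[2]]], sis[ord[2]])
  }
  out
}

# ---- prepared cross context ----------------------------------------------

# Precomputes everything reused across meioses: parental chromatids with
# cached region coverage and allele codes, region carrier lookup, active
# killers, panel indices.
prepare_cross <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  viol <- validate_cross(cfg)
  if (nrow(viol))
    stop("invalid cross configuration: ",
         paste(sprintf("[%s] %s", viol$field, viol$message), collapse = "; "))
  g <- cfg$genome
  loci <- dplyr::bind_rows(
    tibble::tibble(name = cfg$panel$name, chrom = cfg$panel$chrom, pos = cfg$panel$pos),
    tibble::tibble(name = paste0(".drv_", cfg$drive$locus),
                   chrom = cfg$drive$chrom, pos = cfg$drive$pos))
  parents <- lapply(cfg$parents, function(p) parent_chromosomes(g, p, loci))
  inv_het <- parents[[1]][[1]]$arr != parents[[2]][[1]]$arr

  regions <- g$regions
  # which of each parent's three chromosomes carries each region
  carrier <- sapply(parents, function(chroms) {
    apply(vapply(chroms, function(td) td$cov, logical(nrow(regions))), 1, which)
  })
  region_morgans <- physical_to_genetic(regions$end - regions$start + 1,
                                        g$cM_per_kb) / 100

  # regions where the parents' content differs; crossover events elsewhere
  # exchange identical material and only need to count as chiasmata
  # (chromosome 1 stays "informative" in inversion heterozygotes because
  # events inside the inversion set the unbalanced parity)
  informative <- vapply(seq_len(nrow(regions)), function(r) {
    tdA <- parents[[1]][[carrier[r, 1]]]
    tdB <- parents[[2]][[carrier[r, 2]]]
    pts <- sort(unique(c(regions$start[r],
                         unlist(lapply(c(tdA$pieces, tdB$pieces), function(pc)
                           if (pc$chrom == regions$chrom[r])
                             pc$bp[pc$bp >= regions$start[r] & pc$bp <= regions$end[r]]
                           else numeric())))))
    a <- .td_allele_codes(tdA$pieces, rep(regions$chrom[r], length(pts)), pts)
    b <- .td_allele_codes(tdB$pieces, rep(regions$chrom[r], length(pts)), pts)
    !identical(a, b)
  }, logical(1))
  if (inv_het) informative[regions$region == "chr1"] <- TRUE

  drv <- cfg$drive
  if (nrow(drv)) {
    drv$code <- unname(.SP_CODE[drv$killer])
    drv$loc_idx <- nrow(cfg$panel) + seq_len(nrow(drv))
    drv$active <- vapply(seq_len(nrow(drv)), function(i) {
      any(vapply(parents, function(chroms) {
        a <- .td_allele_codes(do.call(c, lapply(chroms, `[[`, "pieces")),
                              drv$chrom[i], drv$pos[i])
        any(a == drv$code[i], na.rm = TRUE)
      }, logical(1)))
    }, logical(1))
    drv <- drv[drv$active & drv$strength > 0, , drop = FALSE]
  }

  # processing units: one per chromosome arm, in an order that finishes the
  # proximal translocation arms (units 3, 5) before the arms that continue
  # them across the junctions (units 7, 8). side_slots = which chromosome of
  # each parent provides the unit's axes; inherit = unit whose final axis
  # occupancy carries over.
  units <- list(
    list(region = 1L, side_slots = carrier[1, ], inherit = c(NA, NA)),  # chr1 left
    list(region = 1L, side_slots = carrier[1, ], inherit = c(NA, NA)),  # chr1 right
    list(region = 3L, side_slots = carrier[3, ], inherit = c(NA, NA)),  # chr2R left
    list(region = 3L, side_slots = carrier[3, ], inherit = c(NA, NA)),  # chr2R right
    list(region = 4L, side_slots = carrier[4, ], inherit = c(NA, NA)),  # chr3L right
    list(region = 4L, side_slots = carrier[4, ], inherit = c(NA, NA)),  # chr3L left
    list(region = 2L, side_slots = carrier[2, ],                        # chr2L
         inherit = ifelse(carrier[2, ] == 2L, 3L, 5L)),
    list(region = 5L, side_slots = carrier[5, ],                        # chr3R
         inherit = ifelse(carrier[5, ] == 3L, 5L, 3L))
  )

  list(cfg = cfg, genome = g, loci = loci, parents = parents,
       inv_het = inv_het, regions = regions, carrier = carrier,
       region_morgans = region_morgans, informative = informative, drive = drv,
       units = units,
       proc_chr1 = informative[1], proc_g23 = any(informative[2:5]),
       fast = .fast_genome(g, loci),
       drvf = if (NROW(drv)) list(n = nrow(drv), loc = drv$loc_idx,
                                  code = drv$code, strength = drv$strength)
              else list(n = 0L),
       morgans2 = 2 * region_morgans,
       panel_idx = seq_len(nrow(cfg$panel)),
       ploidy_idx = c(chr2 = match(cfg$ploidy_markers[["chr2"]], cfg$panel$name),
                      chr3 = match(cfg$ploidy_markers[["chr3"]], cfg$panel$name)))
}

# draw the crossover event table for one meiosis: tibble-free list of
# (region index, processing unit, cut position), in processing order
# (units ascending, then outward from the centromere)
.draw_meiosis_events <- function(ctx) {
  fast <- ctx$fast
  if (ctx$cfg$rec12 == "wt") {
    counts <- stats::rpois(length(ctx$morgans2), ctx$morgans2)
    if (sum(counts) == 0) return(NULL)
    reg <- rep.int(seq_along(counts), counts)
    pos <- floor(stats::runif(length(reg), fast$rs[reg], fast$re[reg]))
  } else {
    hit <- which(stats::runif(3) < ctx$cfg$residual_rate)
    if (!length(hit)) return(NULL)
    pos <- floor(stats::runif(length(hit), 1, fast$lengths[hit]))
    reg <- vapply(seq_along(hit), function(i) {
      which(fast$rc == hit[i] & fast$rs <= pos[i] & fast$re >= pos[i])[1]
    }, integer(1))
  }
  dup <- duplicated(pos + 6e6 * reg)   # coincident cuts cancel; drop repeats
  if (any(dup)) { reg <- reg[!dup]; pos <- pos[!dup] }
  cens <- fast$cens
  unit <- integer(length(reg))
  for (k in seq_along(reg)) {
    unit[k] <- switch(reg[k],
      if (pos[k] < cens[1]) 1L else 2L,   # chr1
      7L,                                 # chr2L
      if (pos[k] < cens[2]) 3L else 4L,   # chr2R
      if (pos[k] >= cens[3]) 5L else 6L,  # chr3L
      8L)                                 # chr3R
  }
  cen_d <- abs(pos - cens[fast$rc[reg]])
  o <- order(unit, cen_d)
  list(region = reg[o], unit = unit[o], pos = pos[o])
}

.midx <- function(side, chrom, sister) (side - 1L) * 6L + (chrom - 1L) * 2L + sister

#' Simulate one meiosis
#'
#' Runs crossover placement, meiosis I/II segregation and spore packaging for
#' one diploid cell of the configured cross. Viability rules are not applied;
#' see [apply_viability()].
#'
#' @param cfg A [cross_config()] (or the internal prepared context).
#' @return An object of class `tetrad`: a list with `spores` (four lists of
#'   chromatid records), the per-bivalent `chiasmate` flags, and whether the
#'   meiosis was heterozygous for the chromosome 1 inversion (`inv_het`).
#' @export
#' @examples
#' set.seed(1)
#' tet <- simulate_tetrad(cross_config("PPP", "KKK", rec12 = "null"))
#' lengths(tet$spores)
simulate_tetrad <- function(cfg) {
  ctx <- if (inherits(cfg, "cross_config")) prepare_cross(cfg) else cfg
  events <- .draw_meiosis_events(ctx)
  # molecules in a flat store indexed by (side, chromosome slot, sister);
  # sisters start as references to the parental chromosome (copy-on-modify
  # keeps the no-crossover path cheap)
  molecules <- vector("list", 12L)
  for (side in 1:2) for (cc in 1:3) {
    td <- ctx$parents[[side]][[cc]]
    molecules[[.midx(side, cc, 1L)]] <- td
    molecules[[.midx(side, cc, 2L)]] <- td
  }
  chiasmate <- c(FALSE, FALSE, FALSE)
  if (!is.null(events)) {
    perms <- vector("list", 8L)
    inherited <- c(rep(FALSE, 6L), TRUE, TRUE)
    for (u in 1:6) {
      ss <- ctx$units[[u]]$side_slots
      perms[[u]] <- list(c(.midx(1L, ss[1], 1L), .midx(1L, ss[1], 2L)),
                         c(.midx(2L, ss[2], 1L), .midx(2L, ss[2], 2L)))
    }
    for (k in seq_along(events$region)) {
      r <- events$region[k]
      u <- events$unit[k]
      un <- ctx$units[[u]]
      chiasmate[un$side_slots[1]] <- TRUE
      chiasmate[un$side_slots[2]] <- TRUE
      if (if (r == 1L) !ctx$proc_chr1 else !ctx$proc_g23) next
      if (inherited[u] && is.null(perms[[u]]))
        perms[[u]] <- list(perms[[un$inherit[1]]][[1]], perms[[un$inherit[2]]][[2]])
      s1 <- sample(2L, 1L); s2 <- sample(2L, 1L)
      mA <- perms[[u]][[1]][s1]; mB <- perms[[u]][[2]][s2]
      res <- crossover_exchange(molecules[[mA]], molecules[[mB]],
                                ctx$fast$rc[r], events$pos[k],
                                ctx$fast, ctx$inv_het)
      molecules[[mA]] <- res[[1]]
      molecules[[mB]] <- res[[2]]
      perms[[u]][[1]][s1] <- mB
      perms[[u]][[2]][s2] <- mA
    }
  }
  spores <- list(list(), list(), list(), list())
  for (cc in 1:3) {
    got <- segregate_bivalent(
      list(molecules[[.midx(1L, cc, 1L)]], molecules[[.midx(1L, cc, 2L)]]),
      list(molecules[[.midx(2L, cc, 1L)]], molecules[[.midx(2L, cc, 2L)]]),
      chiasmate[cc], ctx$cfg$p_dist)
    for (s in 1:4) spores[[s]] <- c(spores[[s]], got[[s]])
  }
  structure(list(spores = spores, chiasmate = chiasmate, inv_het = ctx$inv_het),
            class = "tetrad")
}

# ---- spore-level queries ---------------------------------------------------

#' Genotype a spore at a position
#'
#' Looks up the ancestry of every chromatid covering the position. The lookup
#' is by content (ancestry segments in Sp reference coordinates), so it works
#' unchanged on translocated arrangements and recombinant chromosomes.
#'
#' @param spore A list of chromatid records (one element of
#'   `simulate_tetrad(...)$spores`).
#' @param chrom Sp reference chromosome id (1-3).
#' @param pos Position in bp.
#' @param genome The genome specification (for bounds checking).
#' @return Character vector of ancestries, one per covering chromatid
#'   (possibly empty for a nullisomic spore).
#' @export
genotype_at <- function(spore, chrom, pos, genome = default_genome()) {
  stopifnot(chrom %in% 1:3)
  if (pos < 1 || pos > genome$lengths[chrom])
    stop(sprintf("position %g outside chromosome %d", pos, chrom))
  codes <- integer()
  for (td in spore) {
    a <- .td_allele_codes(td$pieces, chrom, pos)
    if (!is.na(a)) codes <- c(codes, a)
  }
  names(.SP_CODE)[codes]
}

# allele codes of a spore at a cached locus index
.spore_codes_at <- function(spore, loc_idx) {
  codes <- integer(length(spore))
  n <- 0L
  for (td in spore) {
    a <- td$alleles[loc_idx]
    if (!is.na(a)) { n <- n + 1L; codes[n] <- a }
  }
  codes[seq_len(n)]
}

.call_string <- function(codes) {
  u <- sort(unique(codes))
  if (!length(u)) return(NA_character_)
  paste(names(.SP_CODE)[u], collapse = "/")
}

#' Classify a spore's ploidy the way the marker assay would
#'
#' Emulates the codominant-marker assay: a spore with both species' alleles at
#' the chromosome 2 marker is called a heterozygous diploid; both alleles at
#' the chromosome 3 marker but a single chromosome 2 allele is a heterozygous
#' chromosome 3 aneuploid; everything else — including true homozygous
#' diploids and homozygous disomes, which the assay cannot see — is counted as
#' haploid.
#'
#' @param spore A list of chromatid records.
#' @param cfg The [cross_config()] whose panel defines the ploidy markers.
#' @return One of `"haploid-call"`, `"het-diploid"`, `"het-chr3-aneuploid"`.
#' @export
classify_spore <- function(spore, cfg) {
  pm <- cfg$panel[match(cfg$ploidy_markers, cfg$panel$name), ]
  g2 <- unique(unlist(lapply(spore, function(td)
    .td_allele_codes(td$pieces, pm$chrom[1], pm$pos[1]))))
  g3 <- unique(unlist(lapply(spore, function(td)
    .td_allele_codes(td$pieces, pm$chrom[2], pm$pos[2]))))
  .classify_codes(g2[!is.na(g2)], g3[!is.na(g3)])
}

.classify_codes <- function(codes2, codes3) {
  if (length(unique(codes2)) == 2) "het-diploid"
  else if (length(unique(codes3)) == 2) "het-chr3-aneuploid"
  else "haploid-call"
}
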