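# Internal chromatid representation.
#
# A chromatid is a connected physical chromosome: an ordered (left telomere ->
# right telomere) list of content pieces. Each piece is an interval [lo, hi]
# of one Sp reference chromosome, with an orientation flag (dir = +1 if
# physical left-to-right runs with increasing reference coordinate) and an
# ancestry map over the interval (segment starts `bp` plus species codes
# `anc`; 1 = Sp, 2 = Sk). Translocated karyotypes are chromatids whose pieces
# come from two reference chromosomes; ancestry is always recorded in Sp
# reference coordinates regardless of arrangement.

.SP_CODE <- c(Sp = 1L, Sk = 2L)

new_piece <- function(chrom, lo, hi, dir, bp, anc) {
  list(chrom = chrom, lo = lo, hi = hi, dir = dir, bp = bp, anc = anc)
}

anc_code_at <- function(piece, pos) {
  piece$anc[findInterval(pos, piece$bp)]
}

# plain-vector view of the genome/loci used by the per-meiosis hot path
.fast_genome <- function(genome, loci) {
  regions <- genome$regions
  lchrom <- as.integer(loci$chrom)
  list(rs = as.numeric(regions$start), re = as.numeric(regions$end),
       rc = as.integer(regions$chrom),
       rlen = as.numeric(regions$end - regions$start + 1),
       rbc = lapply(1:3, function(cc) which(regions$chrom == cc)),
       lchrom = lchrom, lpos = as.numeric(loci$pos),
       lbc = lapply(1:3, function(cc) which(lchrom == cc)),
       cens = genome$centromeres, inv = genome$inversion,
       lengths = genome$lengths)
}

# ancestry spec (uniform species string or tibble chrom/start/end/species)
# restricted to [lo, hi] of `chrom` -> list(bp, anc)
.build_anc_map <- function(ancestry, chrom, lo, hi) {
  if (is.character(ancestry))
    return(list(bp = lo, anc = unname(.SP_CODE[ancestry])))
  rows <- ancestry[ancestry$chrom == chrom, , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  rows <- rows[rows$end >= lo & rows$start <= hi, , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("ancestry spec does not cover chr%d:%g-%g", chrom, lo, hi))
  starts <- pmax(rows$start, lo)
  ends <- pmin(rows$end, hi)
  if (starts[1] > lo || ends[nrow(rows)] < hi ||
      (nrow(rows) > 1 && any(starts[-1] != ends[-nrow(rows)] + 1)))
    stop(sprintf("ancestry spec has gaps over chr%d:%g-%g", chrom, lo, hi))
  anc <- unname(.SP_CODE[rows$species])
  keep <- c(TRUE, anc[-1] != anc[-length(anc)])
  list(bp = starts[keep], anc = anc[keep])
}

# region coverage bitset: TRUE where the chromatid's pieces fully cover the
# homology region. Pieces of one chromatid never overlap on the same
# reference chromosome (homologous exchanges preserve disjointness), so full
# coverage is equivalent to the summed overlap reaching the region length.
.td_coverage <- function(pieces, fast) {
  covlen <- numeric(length(fast$rs))
  for (pc in pieces) {
    for (r in fast$rbc[[pc$chrom]]) {
      ov <- min(pc$hi, fast$re[r]) - max(pc$lo, fast$rs[r]) + 1
      if (ov > 0) covlen[r] <- covlen[r] + ov
    }
  }
  covlen >= fast$rlen
}

# allele codes (NA when not covered) at loci given as plain vectors
.td_allele_codes <- function(pieces, loci_chrom, loci_pos) {
  out <- rep(NA_integer_, length(loci_pos))
  for (pc in pieces) {
    for (i in seq_along(loci_pos)) {
      if (loci_chrom[i] == pc$chrom && loci_pos[i] >= pc$lo && loci_pos[i] <= pc$hi)
        out[i] <- pc$anc[findInterval(loci_pos[i], pc$bp)]
    }
  }
  out
}

.td_alleles_fast <- function(pieces, fast) {
  out <- rep(NA_integer_, length(fast$lpos))
  lpos <- fast$lpos
  for (pc in pieces) {
    for (i in fast$lbc[[pc$chrom]]) {
      p <- lpos[i]
      if (p >= pc$lo && p <= pc$hi)
        out[i] <- pc$anc[findInterval(p, pc$bp)]
    }
  }
  out
}

new_chromatid <- function(pieces, cen, arr, fast, inv_xo = 0L) {
  list(pieces = pieces, cen = cen, arr = arr, inv_xo = inv_xo,
       cov = .td_coverage(pieces, fast),
       alleles = .td_alleles_fast(pieces, fast))
}

# parental chromosome (chromatid prototype) from a chromosome_spec
build_parent_chromosome <- function(genome, chrom_index, cspec, loci,
                                    fast = .fast_genome(genome, loci)) {
  len <- genome$lengths
  t2 <- genome$trans[["chr2"]]; t3 <- genome$trans[["chr3"]]
  amap <- function(chrom, lo, hi) {
    m <- .build_anc_map(cspec$ancestry, chrom, lo, hi)
    new_piece(chrom, lo, hi, +1, m$bp, m$anc)
  }
  if (cspec$karyotype == "P" || chrom_index == 1L) {
    pieces <- list(amap(chrom_index, 1, len[chrom_index]))
  } else if (chrom_index == 2L) {
    p1 <- amap(3, t3, len[3]); p1$dir <- -1
    pieces <- list(p1, amap(2, t2, len[2]))
  } else {
    p2 <- amap(3, 1, t3 - 1); p2$dir <- -1
    pieces <- list(amap(2, 1, t2 - 1), p2)
  }
  new_chromatid(pieces, cen = chrom_index, arr = cspec$karyotype, fast = fast)
}

parent_chromosomes <- function(genome, pspec, loci = NULL) {
  if (is.null(loci)) loci <- tibble::tibble(chrom = integer(), pos = numeric())
  fast <- .fast_genome(genome, loci)
  lapply(1:3, function(i)
    build_parent_chromosome(genome, i, pspec[[i]], loci, fast))
}

# ---- splitting and crossover exchange -------------------------------------

.reverse_pieces <- function(pl) {
  pl <- rev(pl)
  for (j in seq_along(pl)) pl[[j]]$dir <- -pl[[j]]$dir
  pl
}

.cut_piece <- function(pc, cut) {
  # content split of [lo, hi] into [lo, cut] and [cut+1, hi]
  j <- findInterval(cut, pc$bp)
  left <- new_piece(pc$chrom, pc$lo, cut, pc$dir, pc$bp[seq_len(j)], pc$anc[seq_len(j)])
  i <- findInterval(cut + 1, pc$bp)
  keep <- pc$bp > cut + 1
  right <- new_piece(pc$chrom, cut + 1, pc$hi, pc$dir,
                     c(cut + 1, pc$bp[keep]), c(pc$anc[i], pc$anc[keep]))
  list(left = left, right = right)
}

.side_has_cen <- function(pieces, cen_chrom, cen_pos) {
  for (pc in pieces)
    if (pc$chrom == cen_chrom && pc$lo <= cen_pos && pc$hi >= cen_pos) return(TRUE)
  FALSE
}

# Split a chromatid at the cut between `cutpos` and `cutpos + 1` on reference
# chromosome `chrom`. Returns prox (centromere side, cut end at its right) and
# dist (acentric side, cut end at its left), each an ordered piece list.
split_chromatid <- function(td, chrom, cutpos, cen_pos) {
  idx <- NULL
  for (j in seq_along(td$pieces)) {
    pc <- td$pieces[[j]]
    if (pc$chrom == chrom && pc$lo <= cutpos && cutpos < pc$hi) { idx <- j; break }
  }
  if (is.null(idx))
    stop(sprintf("chromatid does not span a cut at chr%d:%g", chrom, cutpos))
  pc <- td$pieces[[idx]]
  halves <- .cut_piece(pc, cutpos)
  before <- if (idx > 1) td$pieces[seq_len(idx - 1)] else list()
  after <- if (idx < length(td$pieces)) td$pieces[(idx + 1):length(td$pieces)] else list()
  if (pc$dir == 1) {
    left <- c(before, list(halves$left)); right <- c(list(halves$right), after)
  } else {
    left <- c(before, list(halves$right)); right <- c(list(halves$left), after)
  }
  if (.side_has_cen(left, td$cen, cen_pos)) {
    list(prox = left, dist = right)                  # cut end already at prox right
  } else {
    list(prox = .reverse_pieces(right), dist = .reverse_pieces(left))
  }
}

# Reciprocal exchange of the acentric tails of two chromatids at a homologous
# cut point. Inside a heterozygous inversion each product counts one more
# inversion-internal crossover (odd parity = unbalanced).
crossover_exchange <- function(tdA, tdB, chrom, cutpos, fast, inv_het) {
  sA <- split_chromatid(tdA, chrom, cutpos, fast$cens[tdA$cen])
  sB <- split_chromatid(tdB, chrom, cutpos, fast$cens[tdB$cen])
  in_inv <- chrom == 1L && inv_het &&
    cutpos >= fast$inv[1] && cutpos < fast$inv[2]
  newA <- new_chromatid(c(sA$prox, sB$dist), tdA$cen, tdA$arr, fast,
                        inv_xo = tdA$inv_xo + as.integer(in_inv))
  newB <- new_chromatid(c(sB$prox, sA$dist), tdB$cen, tdB$arr, fast,
                        inv_xo = tdB$inv_xo + as.integer(in_inv))
  list(newA, newB)
}

# total content (bp) of each ancestry across a list of chromatids, for
# conservation checks
ancestry_totals <- function(chromatids) {
  tot <- c(Sp = 0, Sk = 0)
  for (td in chromatids) for (pc in td$pieces) {
    ends <- c(pc$bp[-1] - 1, pc$hi)
    lens <- ends - pc$bp + 1
    tot[1] <- tot[1] + sum(lens[pc$anc == 1L])
    tot[2] <- tot[2] + sum(lens[pc$anc == 2L])
  }
  tot
}
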