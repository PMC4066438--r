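# File formats: spore tables as commented TSV, cross configurations as YAML.

.REQUIRED_COLS <- c("meiosis_id", "spore_id", "ploidy_class", "viability")

#' Read and write spore tables
#'
#' Spore tables are tab-separated UTF-8 text with `#`-prefixed header lines
#' carrying the configuration hash, the seed and the meiosis count, so a
#' table is diffable and self-describing. Unknown columns round-trip
#' unchanged.
#'
#' @param table A spore table tibble ([simulate_cross()] output).
#' @param path File path.
#' @return `read_spore_table()` returns the tibble with header attributes
#'   restored; `write_spore_table()` returns `path` invisibly.
#' @export
write_spore_table <- function(table, path) {
  stopifnot(all(.REQUIRED_COLS %in% names(table)))
  header <- c(
    "# sporedrive spore table v1",
    sprintf("# config_hash=%s", attr(table, "config_hash") %||% "NA"),
    sprintf("# seed=%s", attr(table, "seed") %||% "NA"),
    sprintf("# n_meioses=%s", attr(table, "n_meioses") %||% "NA"))
  writeLines(header, path)
  readr::write_tsv(table, path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_spore_table
#' @export
read_spore_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 10L)
  head_lines <- head_lines[startsWith(head_lines, "#")]
  get_field <- function(key) {
    hit <- grep(paste0("^# ", key, "="), head_lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           meiosis_id = readr::col_integer(),
                           spore_id = readr::col_integer(),
                           .default = readr::col_character()))
  probs <- readr::problems(tab)
  if (nrow(probs))
    stop(sprintf("malformed spore table '%s': %s at line %d", path,
                 probs$expected[1], probs$row[1]))
  missing <- setdiff(.REQUIRED_COLS, names(tab))
  if (length(missing))
    stop("spore table is missing required column(s): ",
         paste(missing, collapse = ", "))
  attr(tab, "config_hash") <- get_field("config_hash")
  seed <- get_field("seed")
  attr(tab, "seed") <- if (is.na(seed) || seed == "NA") NA_integer_ else as.integer(seed)
  nm <- get_field("n_meioses")
  attr(tab, "n_meioses") <- if (is.na(nm) || nm == "NA") NA_integer_ else as.integer(nm)
  tab
}

# ---- cross configuration YAML ---------------------------------------------

.anc_to_list <- function(ancestry) {
  if (is.character(ancestry)) return(ancestry)
  lapply(seq_len(nrow(ancestry)), function(i)
    list(chrom = ancestry$chrom[i], start = ancestry$start[i],
         end = ancestry$end[i], species = ancestry$species[i]))
}

.anc_from_list <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)
  dplyr::bind_rows(lapply(x, tibble::as_tibble))
}

#' Read and write cross configurations
#'
#' Cross configurations serialise to YAML with blocks for the parents (per
#' chromosome: karyotype and ancestry mosaic), the killer loci, the
#' recombination regime, the segregation fidelity, the marker panel, and any
#' genome overrides.
#'
#' @param cfg A [cross_config()].
#' @param path File path.
#' @return `read_cross_config()` returns a [cross_config()];
#'   `write_cross_config()` returns `path` invisibly.
#' @export
write_cross_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cross_config"))
  g <- cfg$genome
  obj <- list(
    parents = lapply(cfg$parents, function(p)
      lapply(p, function(ch) list(karyotype = ch$karyotype,
                                  ancestry = .anc_to_list(ch$ancestry)))),
    drive = lapply(seq_len(nrow(cfg$drive)), function(i)
      list(locus = cfg$drive$locus[i], chrom = cfg$drive$chrom[i],
           pos = cfg$drive$pos[i], killer = cfg$drive$killer[i],
           strength = cfg$drive$strength[i])),
    recombination = list(rec12 = cfg$rec12, residual_rate = cfg$residual_rate),
    segregation = list(p_dist = cfg$p_dist),
    panel = lapply(seq_len(nrow(cfg$panel)), function(i)
      list(name = cfg$panel$name[i], chrom = cfg$panel$chrom[i],
           pos = cfg$panel$pos[i])),
    ploidy_markers = as.list(cfg$ploidy_markers),
    genome = list(lengths = g$lengths, inversion = g$inversion,
                  trans_chr2 = unname(g$trans[["chr2"]]),
                  trans_chr3 = unname(g$trans[["chr3"]]),
                  cM_per_kb = g$cM_per_kb, centromeres = g$centromeres))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_cross_config
#' @export
read_cross_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- yaml::read_yaml(path)
  for (blk in c("parents", "recombination", "segregation"))
    if (is.null(obj[[blk]])) stop("config is missing the '", blk, "' block")
  gb <- obj$genome
  genome <- if (is.null(gb)) default_genome() else
    default_genome(lengths = unlist(gb$lengths),
                   inversion = unlist(gb$inversion),
                   trans_chr2 = gb$trans_chr2, trans_chr3 = gb$trans_chr3,
                   cM_per_kb = gb$cM_per_kb,
                   centromeres = unlist(gb$centromeres))
  parents <- lapply(obj$parents, function(p)
    parent_spec(lapply(p, function(ch)
      chromosome_spec(ch$karyotype, .anc_from_list(ch$ancestry)))))
  drive <- if (length(obj$drive))
    drive_model(locus = vapply(obj$drive, `[[`, "", "locus"),
                chrom = vapply(obj$drive, `[[`, 1L, "chrom"),
                pos = vapply(obj$drive, function(x) as.numeric(x$pos), 1),
                killer = vapply(obj$drive, `[[`, "", "killer"),
                strength = vapply(obj$drive, function(x) as.numeric(x$strength), 1))
  else drive_model()
  panel <- if (length(obj$panel))
    tibble::tibble(name = vapply(obj$panel, `[[`, "", "name"),
                   chrom = as.integer(vapply(obj$panel, function(x) as.numeric(x$chrom), 1)),
                   pos = vapply(obj$panel, function(x) as.numeric(x$pos), 1))
  else marker_panel(ploidy_only = TRUE)
  cross_config(parents[[1]], parents[[2]], genome = genome, drive = drive,
               rec12 = obj$recombination$rec12,
               residual_rate = obj$recombination$residual_rate,
               p_dist = obj$segregation$p_dist,
               panel = panel,
               ploidy_markers = unlist(obj$ploidy_markers) %||%
                 c(chr2 = "his5", chr3 = "ade6"))
}
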