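# Killer-strength and killer-position inference: single-locus closed form,
# multinomial maximum likelihood over the exact enumeration kernel, and
# coarse position mapping from the transmission-vs-distance curve.

#' Single-locus killer strength estimate
#'
#' Closed-form MLE for a killer assayed at a fully linked marker with haploid
#' survivors: inverting `t = 1/(2 - d)` gives `d = 2 - 1/t`, clamped to 0
#' when the observed transmission is at or below one half.
#'
#' @param n_killer,n_other Allele counts among viable spores.
#' @return Estimated strength(s) in `[0, 1]`.
#' @export
#' @examples
#' mle_single_locus(72, 28)   # 0.6111
mle_single_locus <- function(n_killer, n_other) {
  n <- n_killer + n_other
  if (any(n <= 0)) stop("at least one allele count must be positive")
  t_hat <- n_killer / n
  pmin(1, pmax(0, 2 - 1 / t_hat))
}

# observable class key of a spore-table row / enumeration class
.obs_key <- function(df, panel_names) {
  keys <- df[[panel_names[1]]]
  for (nm in panel_names[-1]) keys <- paste(keys, df[[nm]], sep = "|")
  paste(keys, df$ploidy_class, sep = "|")
}

#' Fit killer strengths by multinomial maximum likelihood
#'
#' Maximises the multinomial log-likelihood of the observed viable-spore
#' classes (marker calls plus assay ploidy class) over the free killer
#' strengths, using the exact recombination-free enumeration as the
#' likelihood kernel. Only viable spores enter the likelihood (dead spores
#' are unobservable in the assay), so class probabilities are conditioned on
#' survival. Killers whose allele is carried by both parents (or neither)
#' produce no signal in the cross and are reported as non-identifiable.
#'
#' Observed classes outside the exact kernel's support — rare residual
#' recombinants in simulated `rec12` null tables — are dropped from the
#' likelihood and counted in `n_dropped`.
#'
#' @param table A spore table from a `rec12 = "null"` cross.
#' @param cfg The cross configuration template; its drive-model strengths are
#'   the free parameters.
#' @param seed Seed for the optimiser's random restarts.
#' @param n_restarts Number of bounded quasi-Newton restarts.
#' @param conf_level Confidence level of the likelihood-ratio intervals.
#' @return An object of class `drive_fit`; see [tidy.drive_fit()] and
#'   [glance.drive_fit()].
#' @export
fit_drive_model <- function(table, cfg, seed = 1L, n_restarts = 5L,
                            conf_level = 0.95) {
  ctx <- prepare_cross(cfg)
  if (ctx$cfg$rec12 != "null")
    stop("the exact likelihood kernel requires a rec12 = \"null\" configuration")
  drv <- ctx$drive
  if (!NROW(drv))
    stop("no active killer locus in this configuration; nothing to fit")

  cls <- enumerate_spore_classes(ctx)
  carrier <- attr(cls, "killer_carrier")
  panel_names <- ctx$cfg$panel$name

  # identifiable = exactly one parent carries the killer allele at the locus
  par_codes <- vapply(seq_len(nrow(drv)), function(i) {
    vapply(ctx$parents, function(chroms) {
      a <- .td_allele_codes(do.call(c, lapply(chroms, `[[`, "pieces")),
                            drv$chrom[i], drv$pos[i])
      any(a == drv$code[i], na.rm = TRUE)
    }, logical(1))
  }, logical(2))
  free <- which(colSums(par_codes) == 1L)
  if (!length(free))
    stop("non-identifiable configuration: no killer locus is heterozygous ",
         "between the parents")

  tab <- .viable_rows(table)
  missing_cols <- setdiff(panel_names, names(tab))
  if (length(missing_cols))
    stop("spore table lacks marker columns: ", paste(missing_cols, collapse = ", "))
  obs <- table(.obs_key(tab, panel_names))
  model_key <- .obs_key(cls, panel_names)

  det_ok <- cls$alive
  base_pre <- cls$prob_pre
  fixed_w <- rep(1, nrow(cls))  # survival factors of non-free killers
  fixed_idx <- setdiff(seq_len(nrow(drv)), free)
  for (k in fixed_idx)
    fixed_w <- fixed_w * ifelse(carrier[, k], 1, 1 - drv$strength[k])

  class_prob <- function(d_free) {
    w <- fixed_w
    for (j in seq_along(free))
      w <- w * ifelse(carrier[, free[j]], 1, 1 - d_free[j])
    p <- base_pre * det_ok * w
    rowsum(p, model_key)
  }
  support0 <- class_prob(rep(0.5, length(free)))
  in_support <- names(obs) %in% rownames(support0)[support0 > 0]
  n_dropped <- sum(obs[!in_support])
  obs <- obs[in_support]
  if (!length(obs)) stop("no observed spore class lies in the kernel support")
  obs_names <- names(obs)
  counts <- as.numeric(obs)

  negll <- function(d_free) {
    q <- class_prob(d_free)
    qk <- q[obs_names, 1]
    tot <- sum(q)
    if (any(qk <= 0) || tot <= 0) return(1e10)
    -sum(counts * (log(qk) - log(tot)))
  }

  starts <- withr::with_seed(seed, {
    s <- matrix(stats::runif(n_restarts * length(free), 0.05, 0.95),
                nrow = n_restarts)
    s[1, ] <- 0.5
    s
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                        lower = 1e-9, upper = 1 - 1e-9)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  d_hat <- pmin(1, pmax(0, best$par))
  llmax <- -best$value

  # profile likelihood-ratio confidence intervals
  crit <- stats::qchisq(conf_level, df = 1)
  prof_ll <- function(j, v) {
    others <- setdiff(seq_along(free), j)
    if (!length(others)) return(-negll(v))
    f <- function(po) {
      d <- numeric(length(free)); d[j] <- v; d[others] <- po
      negll(d)
    }
    -stats::optim(d_hat[others], f, method = "L-BFGS-B",
                  lower = 1e-9, upper = 1 - 1e-9)$value
  }
  ci <- t(vapply(seq_along(free), function(j) {
    g <- function(v) 2 * (llmax - prof_ll(j, v)) - crit
    lo <- if (g(1e-9) < 0) 0 else
      stats::uniroot(g, c(1e-9, max(d_hat[j], 2e-9)), tol = 1e-6)$root
    hi <- if (g(1 - 1e-9) < 0) 1 else
      stats::uniroot(g, c(min(d_hat[j], 1 - 2e-9), 1 - 1e-9), tol = 1e-6)$root
    c(lo, hi)
  }, numeric(2)))

  estimates <- tibble::tibble(
    locus = drv$locus, chrom = drv$chrom, pos = drv$pos, killer = drv$killer,
    identifiable = seq_len(nrow(drv)) %in% free,
    d_true_template = drv$strength,
    d_hat = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  estimates$d_hat[free] <- d_hat
  estimates$ci_lo[free] <- ci[, 1]
  estimates$ci_hi[free] <- ci[, 2]

  structure(list(estimates = estimates, loglik = llmax,
                 n_spores = sum(counts), n_dropped = as.numeric(n_dropped),
                 convergence = best$convergence, seed = seed,
                 conf_level = conf_level),
            class = "drive_fit")
}

#' @export
print.drive_fit <- function(x, ...) {
  cat(sprintf("<drive_fit> %d viable spores, logLik %.2f (%d dropped off-support)\n",
              x$n_spores, x$loglik, x$n_dropped))
  print(x$estimates)
  invisible(x)
}

#' Tidy a killer-strength fit
#'
#' @param x A [fit_drive_model()] result.
#' @param ... Unused.
#' @return The estimates tibble (one row per killer locus).
#' @export
tidy.drive_fit <- function(x, ...) x$estimates

#' @rdname tidy.drive_fit
#' @return For `glance()`: a one-row tibble with `loglik`, `n_spores`,
#'   `n_dropped`, `convergence`, `seed`.
#' @export
glance.drive_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_spores = x$n_spores,
                 n_dropped = x$n_dropped, convergence = x$convergence,
                 seed = x$seed)
}

#' Localise a killer locus from marker transmission gradients
#'
#' Markers nearer a killer show stronger transmission bias. Given per-marker
#' killer/other counts along one chromosome, this maximises the binomial
#' likelihood under `t(x) = (1 - r(x) d) / (2 - d)`, with `r(x)` the Haldane
#' recombinant fraction of the marker-to-candidate distance at the
#' genome-average map rate. The search runs on a coarse position grid
#' (default 10 kb) followed by local refinement — killer loci are only
#' coarsely mappable from marker data.
#'
#' @param markers Tibble with columns `pos`, `n_killer`, `n_other` (>= 2 rows
#'   for a position estimate).
#' @param chrom_length Length of the chromosome searched.
#' @param cM_per_kb Map rate.
#' @param grid_bp Grid spacing of the position search.
#' @return An object of class `driver_map` with `position`, `d_hat`,
#'   `loglik`, the grid `profile`, and flags; `position` is `NA` (interval =
#'   whole chromosome) when a single marker or a no-drive signal makes it
#'   unidentifiable.
#' @export
localize_driver <- function(markers, chrom_length, cM_per_kb = 0.16,
                            grid_bp = 10000) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("pos", "n_killer", "n_other") %in% names(markers)),
            nrow(markers) >= 1)
  ll_at <- function(x, d) {
    r <- haldane_r(physical_to_genetic(abs(markers$pos - x), cM_per_kb))
    t <- transmission_curve(d, r)
    t <- pmin(pmax(t, 1e-12), 1 - 1e-12)
    sum(markers$n_killer * log(t) + markers$n_other * log(1 - t))
  }
  prof <- function(x) stats::optimize(function(d) ll_at(x, d),
                                      c(0, 1), maximum = TRUE)
  if (nrow(markers) == 1) {
    d_hat <- mle_single_locus(markers$n_killer, markers$n_other)
    return(structure(list(position = NA_real_, d_hat = d_hat,
                          loglik = ll_at(markers$pos, d_hat),
                          profile = tibble::tibble(pos = numeric(), d_hat = numeric(),
                                                   loglik = numeric()),
                          interval = c(1, chrom_length),
                          identifiable = FALSE,
                          note = "single marker: position unidentifiable"),
                     class = "driver_map"))
  }
  grid <- seq(1, chrom_length, by = grid_bp)
  fits <- lapply(grid, prof)
  lls <- vapply(fits, `[[`, 1, "objective")
  ds <- vapply(fits, `[[`, 1, "maximum")
  best <- which.max(lls)
  # at d = 0 (and equally at unlinked distances) the curve is flat at 1/2,
  # so position is identified only if the fit beats the no-killer likelihood
  ll_null <- ll_at(markers$pos[1], 0)
  if (lls[best] <= ll_null + 1e-6 || ds[best] < 1e-4) {
    return(structure(list(position = NA_real_, d_hat = 0, loglik = ll_null,
                          profile = tibble::tibble(pos = grid, d_hat = ds, loglik = lls),
                          interval = c(1, chrom_length),
                          identifiable = FALSE,
                          note = "no transmission bias: position undefined"),
                     class = "driver_map"))
  }
  lo <- max(1, grid[best] - grid_bp); hi <- min(chrom_length, grid[best] + grid_bp)
  refine <- stats::optimize(function(x) prof(x)$objective, c(lo, hi), maximum = TRUE)
  at <- prof(refine$maximum)
  structure(list(position = refine$maximum, d_hat = at$maximum,
                 loglik = at$objective,
                 profile = tibble::tibble(pos = grid, d_hat = ds, loglik = lls),
                 interval = c(lo, hi), identifiable = TRUE, note = NA_character_),
            class = "driver_map")
}

#' @export
print.driver_map <- function(x, ...) {
  if (x$identifiable)
    cat(sprintf("<driver_map> position %.0f bp, d_hat = %.3f, logLik %.2f\n",
                x$position, x$d_hat, x$loglik))
  else
    cat(sprintf("<driver_map> unidentifiable (%s); d_hat = %.3f\n", x$note, x$d_hat))
  invisible(x)
}

#' Tidy a killer-position profile
#'
#' @param x A [localize_driver()] result.
#' @param ... Unused.
#' @return The grid profile tibble (`pos`, `d_hat`, `loglik`).
#' @export
tidy.driver_map <- function(x, ...) x$profile

#' @rdname tidy.driver_map
#' @export
glance.driver_map <- function(x, ...) {
  tibble::tibble(position = x$position, d_hat = x$d_hat, loglik = x$loglik,
                 identifiable = x$identifiable)
}
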