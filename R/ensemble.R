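#' Combine p-values with Fisher's method
#'
#' `chi2 = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2k` degrees of freedom. Zeros are floored at `eps` before taking
#' logs so the statistic stays finite. Fisher's method assumes
#' independent p-values; the six rhythm detectors are positively
#' correlated, so combined p-values are anti-conservative (see the
#' methods vignette and the optional Brown correction in
#' [call_rhythmic_genes()]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (k >= 1).
#' @param eps Floor applied to zero p-values before the log.
#' @return A one-row tibble with `chi2`, `df` and `p`.
#' @export
#' @examples
#' fisher_combine(rep(0.05, 6))
fisher_combine <- function(pvals, eps = 1e-300) {
  if (!length(pvals)) abort("At least one p-value is required.")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  chi2 <- -2 * sum(log(pmax(pvals, eps)))
  df <- 2L * length(pvals)
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, returning q-values
#' in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Names of the six available rhythmicity detectors
#'
#' @return Character vector of detector names accepted by
#'   [call_rhythmic_genes()].
#' @export
detector_registry <- function() {
  c("harmonic", "lomb_scargle", "jtk", "arser", "rain", "f24")
}

#' Call rhythmic genes in one group with the six-detector ensemble
#'
#' Runs the requested detectors on every gene of one group's samples,
#' combines the per-gene detector p-values with Fisher's method,
#' adjusts across genes with Benjamini-Hochberg, and flags genes with
#' `q < alpha` as rhythmic. Phase (fitted peak time) and relative
#' amplitude (cosinor amplitude / mesor) come from the harmonic
#' regression fit.
#'
#' @param study An [expr_study()], already expression-filtered (see
#'   [filter_expressed()]).
#' @param group One of `"C"`, `"W"`, `"WRF"`.
#' @param alpha FDR threshold for the rhythmic call.
#' @param detectors Subset of
#'   `c("harmonic", "lomb_scargle", "jtk", "arser", "rain", "f24")`.
#' @param period Target period in hours.
#' @param n_perm Permutations for the F24 null. All genes of one call
#'   share one seeded permutation set (each gene's p-value remains valid
#'   under exchangeability; see the methods vignette).
#' @param seed Seed for the F24 permutations.
#' @param brown Apply an empirical Brown-style scaling to the combined
#'   chi-square (estimated from the across-gene covariance of the log
#'   p-values) to offset detector correlation. Off by default: the
#'   reference procedure combines with plain Fisher.
#' @return A tibble of class `rhythm_calls`: one row per gene with the
#'   six detector p-values, `combined_chi2`, `combined_p`, `q`,
#'   `rhythmic`, `phase` and `rel_amplitude`.
#' @export
call_rhythmic_genes <- function(study, group, alpha = 0.05,
                                detectors = detector_registry(),
                                period = 24, n_perm = 1000, seed = 1,
                                brown = FALSE) {
  stopifnot(inherits(study, "expr_study"))
  detectors <- match.arg(detectors, detector_registry(),
                         several.ok = TRUE)
  sub <- study_group_subset(study, group)
  times <- sub$samples$zt
  values <- sub$values
  n_genes <- nrow(values)

  plans <- list()
  if ("lomb_scargle" %in% detectors) plans$ls <- ls_plan(times)
  if ("jtk" %in% detectors) plans$jtk <- jtk_plan(times, period)
  if ("rain" %in% detectors) plans$rain <- rain_plan(times, period)
  if ("f24" %in% detectors) {
    plans$f24 <- f24_plan(times, period)
    plans$perms <- withr::with_seed(seed, {
      matrix(replicate(n_perm, sample.int(length(times))),
             nrow = length(times))
    })
  }

  run_gene <- function(y) {
    out <- list()
    fit <- harmonic_regression_test(times, y, period)
    if ("harmonic" %in% detectors) out$harmonic <- fit$p
    if ("lomb_scargle" %in% detectors) {
      out$lomb_scargle <- lomb_scargle_test(times, y, period,
                                            plan = plans$ls)$p
    }
    if ("jtk" %in% detectors) {
      out$jtk <- jtk_cycle_test(times, y, period, plan = plans$jtk)$p
    }
    if ("arser" %in% detectors) out$arser <- arser_test(times, y, period)$p
    if ("rain" %in% detectors) {
      out$rain <- rain_test(times, y, period, plan = plans$rain)$p
    }
    if ("f24" %in% detectors) {
      out$f24 <- f24_test(times, y, period, plan = plans$f24,
                          perms = plans$perms)$p
    }
    c(unlist(out), phase = fit$phase,
      rel_amplitude = if (fit$mesor > 0) fit$amplitude / fit$mesor else NA)
  }

  res <- t(vapply(seq_len(n_genes), function(i) run_gene(values[i, ]),
                  numeric(length(detectors) + 2)))
  pmat <- res[, seq_along(detectors), drop = FALSE]
  colnames(pmat) <- detectors

  if (brown) {
    combined <- brown_combine(pmat)
  } else {
    chi2 <- -2 * rowSums(log(pmax(pmat, 1e-300)))
    combined <- tibble(chi2 = chi2,
                       p = pchisq(chi2, 2 * ncol(pmat),
                                  lower.tail = FALSE))
  }
  q <- bh_adjust(combined$p)

  out <- tibble(gene_id = rownames(values),
                group = factor(group, levels = study_groups()))
  for (d in detectors) out[[paste0("p_", d)]] <- pmat[, d]
  out$combined_chi2 <- combined$chi2
  out$combined_p <- combined$p
  out$q <- q
  out$rhythmic <- q < alpha
  out$phase <- res[, "phase"]
  out$rel_amplitude <- res[, "rel_amplitude"]
  class(out) <- c("rhythm_calls", class(out))
  out
}

# Empirical Brown-style correction: rescale the Fisher chi-square by
# the ratio of its empirical across-gene variance to the nominal 2*df,
# with matched mean (most genes are null, so genome-wide moments
# approximate the null moments).
brown_combine <- function(pmat) {
  lp <- -2 * log(pmax(pmat, 1e-300))
  chi2 <- rowSums(lp)
  df_nom <- 2 * ncol(pmat)
  v <- stats::var(chi2)
  m <- mean(chi2)
  c_scale <- v / (2 * m)
  df_eff <- 2 * m^2 / v
  tibble(chi2 = chi2,
         p = pchisq(chi2 / c_scale, df_eff, lower.tail = FALSE))
}

#' Call rhythmic genes in every group
#'
#' @inheritParams call_rhythmic_genes
#' @param groups Groups to analyze (default all three). BH adjustment
#'   is performed within each group's analysis.
#' @return A `rhythm_calls` tibble with one row per gene per group.
#' @export
call_rhythmic_genes_all <- function(study, groups = study_groups(),
                                    ...) {
  out <- purrr::map(groups, function(g) call_rhythmic_genes(study, g, ...))
  out <- bind_rows(out)
  class(out) <- c("rhythm_calls", setdiff(class(out), "rhythm_calls"))
  out
}

#' Overlap of rhythmic gene sets between the three groups
#'
#' Counts the seven exclusive Venn regions of the rhythmic sets; the
#' region counts sum to the size of the union.
#'
#' @param calls Either a `rhythm_calls` tibble covering all three
#'   groups over one gene universe, or a named list of three character
#'   vectors of rhythmic gene ids.
#' @return A tibble with columns `region` and `n`.
#' @export
overlap_rhythmic_sets <- function(calls) {
  if (is.data.frame(calls)) {
    universes <- split(calls$gene_id, calls$group)
    if (length(unique(lapply(universes, sort))) != 1) {
      abort("All groups must share the same gene universe.")
    }
    sets <- lapply(split(calls, calls$group),
                   function(d) d$gene_id[d$rhythmic])
  } else {
    sets <- calls
  }
  if (length(sets) != 3 || is.null(names(sets))) {
    abort("Three named rhythmic sets are required.")
  }
  nm <- names(sets)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0) member <- matrix(FALSE, 0, 3, dimnames = list(NULL, nm))
  patterns <- list(
    c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
    c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE)
  )
  region_name <- vapply(patterns, function(p) {
    paste(nm[p], collapse = "&")
  }, "")
  n <- vapply(patterns, function(p) {
    sum(apply(member, 1, function(r) all(r == p)))
  }, 0L)
  tibble(region = region_name, n = as.integer(n))
}

#' Phase histogram of rhythmic genes
#'
#' Bins the fitted peak phases of rhythmic genes into equal-width bins
#' over the 24 h day (bin i covers \[i, i+1) hours at the default 24
#' bins). This is the tabular form of the rose plots summarizing where
#' in the day rhythmic expression peaks; see [plot_phase_rose()].
#'
#' @param calls A `rhythm_calls` tibble.
#' @param n_bins Number of bins; must divide 24 evenly.
#' @return A tibble with `group`, `bin_start`, `bin_end`, `n`; per
#'   group, counts sum to the number of rhythmic genes.
#' @export
phase_histogram <- function(calls, n_bins = 24) {
  if (24 %% n_bins != 0) {
    abort("`n_bins` must divide 24 evenly.")
  }
  width <- 24 / n_bins
  rhythmic <- dplyr::filter(calls, .data$rhythmic)
  grid <- tidyr::expand_grid(
    group = unique(calls$group),
    bin_start = seq(0, 24 - width, by = width)
  )
  counts <- rhythmic |>
    mutate(bin_start = floor((.data$phase %% 24) / width) * width) |>
    dplyr::count(.data$group, .data$bin_start)
  grid |>
    left_join(counts, by = c("group", "bin_start")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           bin_end = .data$bin_start + width) |>
    select("group", "bin_start", "bin_end", "n")
}
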