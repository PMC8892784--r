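#' Cross-reference and size-filter a module catalog
#'
#' Modules are intersected with the expressed-gene universe first and
#' then restricted to those retaining at least `min_size` genes, which
#' avoids unstable statistics on small modules. The null module is
#' always retained but must itself meet the size bound.
#'
#' @param modules A [module_set()].
#' @param universe Character vector of expressed gene ids.
#' @param min_size Minimum module size after cross-referencing.
#' @return A filtered `module_set`.
#' @export
filter_modules <- function(modules, universe, min_size = 50) {
  stopifnot(inherits(modules, "module_set"))
  crossed <- lapply(modules$modules, intersect, universe)
  null_id <- modules$null_module_id
  if (length(crossed[[null_id]]) < min_size) {
    abort(sprintf(
      "Null module %s keeps only %d universe genes (< %d); it cannot serve as the reference.",
      null_id, length(crossed[[null_id]]), min_size
    ))
  }
  keep <- lengths(crossed) >= min_size | names(crossed) == null_id
  module_set(crossed[keep], null_module_id = null_id)
}

#' Module enrichment for up-regulated genes versus the null module
#'
#' For each module M (other than the null module M0), builds the 2x2
#' table (gene in M vs in M0) x (gene in `up_set` vs not) and computes
#' a one-sided (enrichment) Fisher's exact p-value; modules with
#' `p < 0.05` are flagged. The contrast is against the null module
#' specifically, not against the whole universe.
#'
#' @param up_set Character vector of up-regulated gene ids (subset of
#'   the universe).
#' @param modules A filtered [module_set()].
#' @param universe Expressed-gene universe (module genes outside it are
#'   ignored).
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @param alpha Flagging threshold.
#' @return A tibble of class `module_stats`: `module_id`,
#'   `size_in_universe`, `n_up`, `percent_up`, `fisher_p`, `flagged`
#'   (the null module row carries `NA` p).
#' @export
module_enrichment <- function(up_set, modules, universe,
                              alternative = c("greater", "two.sided"),
                              alpha = 0.05) {
  stopifnot(inherits(modules, "module_set"))
  alternative <- match.arg(alternative)
  up_set <- intersect(up_set, universe)
  null_id <- modules$null_module_id
  crossed <- lapply(modules$modules, intersect, universe)
  m0 <- crossed[[null_id]]
  m0_up <- sum(m0 %in% up_set)
  rows <- purrr::map(names(crossed), function(id) {
    genes <- crossed[[id]]
    n_up <- sum(genes %in% up_set)
    size <- length(genes)
    p <- if (id == null_id) {
      NA_real_
    } else if (length(up_set) == 0) {
      1
    } else {
      tab <- matrix(c(n_up, size - n_up, m0_up, length(m0) - m0_up), 2)
      fisher.test(tab, alternative = alternative)$p.value
    }
    tibble(module_id = id, size_in_universe = size, n_up = n_up,
           percent_up = 100 * n_up / size, fisher_p = p,
           flagged = !is.na(p) & p < alpha)
  })
  out <- bind_rows(rows)
  class(out) <- c("module_stats", class(out))
  out
}

#' Per-module expression-shift distributions between two groups
#'
#' Computes, for each universe gene, the log2 ratio of group medians
#' (`median(a) / median(b)` over the 18 samples of each group). Genes
#' with a zero median in either group have no defined log ratio and
#' are excluded (no pseudocount) and counted. Each module's ratio
#' distribution is then compared to the null module's by a
#' Kruskal-Wallis test; modules with `p < 0.05` are flagged. The null
#' module's interquartile band is reported as the reference spread.
#'
#' @param study An expression-filtered [expr_study()].
#' @param modules A filtered [module_set()].
#' @param group_a,group_b Numerator and denominator groups.
#' @param alpha Flagging threshold.
#' @return A list of class `module_shift` with `ratios` (tibble
#'   `gene_id`, `log2_ratio`), `stats` (tibble per module:
#'   `module_id`, `size_in_universe`, `median_log2_ratio`, `iqr_low`,
#'   `iqr_high`, `kw_p_vs_M0`, `flagged`), `n_excluded` (zero-median
#'   genes) and `m0_iqr`.
#' @export
module_expression_shift <- function(study, modules, group_a = "WRF",
                                    group_b = "C", alpha = 0.05) {
  stopifnot(inherits(study, "expr_study"), inherits(modules, "module_set"))
  sub_a <- study_group_subset(study, group_a)
  sub_b <- study_group_subset(study, group_b)
  med_a <- apply(sub_a$values, 1, median)
  med_b <- apply(sub_b$values, 1, median)
  ok <- med_a > 0 & med_b > 0
  n_excluded <- sum(!ok)
  ratios <- tibble(gene_id = rownames(study$values)[ok],
                   log2_ratio = unname(log2(med_a[ok] / med_b[ok])))
  null_id <- modules$null_module_id
  get_ratios <- function(id) {
    ratios$log2_ratio[ratios$gene_id %in% modules$modules[[id]]]
  }
  r0 <- get_ratios(null_id)
  if (length(r0) < 2) abort("Null module retains too few ratio genes.")
  m0_iqr <- unname(quantile(r0, c(0.25, 0.75)))
  stats <- purrr::map(names(modules$modules), function(id) {
    r <- get_ratios(id)
    p <- if (id == null_id || length(r) < 2) {
      NA_real_
    } else {
      kruskal_wallis_test(c(r0, r),
                          rep(c("M0", "M"), c(length(r0), length(r))))$p
    }
    qs <- if (length(r)) quantile(r, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
    tibble(module_id = id, size_in_universe = length(r),
           median_log2_ratio = unname(qs[2]), iqr_low = unname(qs[1]),
           iqr_high = unname(qs[3]), kw_p_vs_M0 = p,
           flagged = !is.na(p) & p < alpha)
  })
  structure(list(ratios = ratios, stats = bind_rows(stats),
                 n_excluded = n_excluded, m0_iqr = m0_iqr,
                 group_a = group_a, group_b = group_b,
                 null_module_id = null_id),
            class = "module_shift")
}

#' @export
print.module_shift <- function(x, ...) {
  cat(sprintf(
    "<module_shift> %s/%s log2 ratios: %d genes (%d zero-median excluded), %d modules, %d flagged\n",
    x$group_a, x$group_b, nrow(x$ratios), x$n_excluded, nrow(x$stats),
    sum(x$stats$flagged, na.rm = TRUE)
  ))
  invisible(x)
}

#' @method tidy module_shift
#' @export
tidy.module_shift <- function(x, ...) x$stats

#' Normalize a distribution to a fixed number of quantiles
#'
#' Evaluates the empirical quantile function by linear interpolation at
#' probabilities `(i - 0.5) / n`, `i = 1..n`, so that samples of very
#' different sizes can be compared on an equal footing (removing the
#' raw-size sensitivity of the Kolmogorov-Smirnov test). An input of
#' exactly `n` sorted distinct values is a fixed point.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param n Number of quantiles (default 500).
#' @return Nondecreasing numeric vector of length `n`.
#' @export
quantile_normalize_distribution <- function(values, n = 500) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("At least 2 finite values are required.")
  }
  unname(quantile(values, probs = (seq_len(n) - 0.5) / n, type = 5))
}

#' Quantile-normalized two-sample Kolmogorov-Smirnov shift test
#'
#' Both inputs (typically all genes' log2 ratios and a gene subset's)
#' are normalized to `n_quantiles` points, then compared by the
#' two-sample KS statistic with its asymptotic p-value at effective
#' sample sizes `n_quantiles` each.
#'
#' @param all_gene_ratios Background distribution (e.g. all expressed
#'   genes' log2 ratios).
#' @param subset_ratios Distribution of the gene subset of interest
#'   (>= 2 values).
#' @param n_quantiles Number of quantiles for normalization.
#' @param label Label carried into the result.
#' @return A tibble of class `shift_distribution` with `label`, `D`,
#'   `ks_p`, `n_subset`, and the normalized quantiles as a list
#'   column `quantiles`.
#' @export
ks_shift_test <- function(all_gene_ratios, subset_ratios,
                          n_quantiles = 500, label = "subset") {
  if (length(subset_ratios) < 2) {
    abort("The subset needs at least 2 values.")
  }
  qa <- quantile_normalize_distribution(all_gene_ratios, n_quantiles)
  qs <- quantile_normalize_distribution(subset_ratios, n_quantiles)
  kt <- suppressWarnings(ks.test(qs, qa, exact = FALSE))
  out <- tibble(label = label, D = unname(kt$statistic),
                ks_p = kt$p.value, n_subset = length(subset_ratios),
                quantiles = list(qs))
  class(out) <- c("shift_distribution", class(out))
  out
}

#' Score up/down disease gene sets against the expression shift
#'
#' Applies [ks_shift_test()] to the up and down sets of a
#' [gene_set_pair()] against the background of all universe genes'
#' log2 ratios.
#'
#' @param shift A [module_expression_shift()] result.
#' @param pair A [gene_set_pair()].
#' @return A `shift_distribution` tibble with one row per set.
#' @export
disease_signature_shift <- function(shift, pair) {
  stopifnot(inherits(shift, "module_shift"), inherits(pair, "gene_set_pair"))
  one <- function(genes, direction) {
    r <- shift$ratios$log2_ratio[shift$ratios$gene_id %in% genes]
    ks_shift_test(shift$ratios$log2_ratio, r,
                  label = paste0(pair$label, "_", direction))
  }
  out <- bind_rows(one(pair$up_genes, "up"), one(pair$down_genes, "down"))
  class(out) <- c("shift_distribution", setdiff(class(out),
                                                "shift_distribution"))
  out
}
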