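#' Filter to expressed genes
#'
#' Keeps genes expressed strictly above `threshold` fpkm in at least
#' `min_samples` samples (the screen that yielded ~10,257 expressed
#' genes in the emulated 54-sample design uses fpkm > 1 in >= 18
#' samples). Gene order is preserved; an empty result is allowed.
#'
#' @param study An [expr_study()].
#' @param threshold Expression threshold (strict inequality).
#' @param min_samples Minimum number of samples above threshold.
#' @return A filtered `expr_study`.
#' @export
filter_expressed <- function(study, threshold = 1, min_samples = 18) {
  stopifnot(inherits(study, "expr_study"))
  keep <- rowSums(study$values > threshold) >= min_samples
  out <- study
  out$values <- study$values[keep, , drop = FALSE]
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1
#' degrees of freedom (delegating to `stats::kruskal.test`). A fully
#' tied input returns H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param group_labels Group membership, same length as `values`.
#' @return A one-row tibble with `H`, `df`, `p`.
#' @export
kruskal_wallis_test <- function(values, group_labels) {
  if (length(values) != length(group_labels)) {
    abort("`values` and `group_labels` must have the same length.")
  }
  g <- factor(group_labels)
  if (nlevels(g) < 2) abort("At least 2 groups are required.")
  if (any(tabulate(g) < 2)) abort("Each group needs at least 2 observations.")
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = nlevels(g) - 1L, p = 1))
  }
  kt <- kruskal.test(values, g)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value by enumeration when the combined sample size is at
#' most `exact_max` and there are no ties; otherwise the normal
#' approximation with tie correction and (by default) continuity
#' correction (delegating to `stats::wilcox.test`). Identical samples
#' return p = 1.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Combined size at or below which the exact null is
#'   used (ties force the approximation).
#' @param continuity Apply the continuity correction on the
#'   approximation path.
#' @return A one-row tibble with `U` (the statistic of `a` over `b`)
#'   and `p`.
#' @export
mann_whitney_test <- function(a, b, exact_max = 12, continuity = TRUE) {
  if (!length(a) || !length(b)) abort("Both samples must be non-empty.")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (length(pooled) == length(unique(pooled)) &&
      length(unique(pooled)) <= 1) ties <- TRUE
  # degenerate: tie-corrected variance is zero when all values coincide
  if (length(unique(pooled)) == 1) {
    return(tibble(U = U, p = 1))
  }
  use_exact <- !ties && length(pooled) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = continuity,
                alternative = "two.sided")
  )
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  tibble(U = U, p = min(p, 1))
}

#' Compact letter display for three-group post-hoc comparisons
#'
#' Two groups share a letter iff they are not significantly different.
#' Letters are the maximal cliques of the "not different" graph,
#' lettered in the fixed processing order of the groups, so e.g. with
#' only C-WRF significant the display is C:a, W:ab, WRF:b.
#'
#' @param pairwise_significant Named logical vector over pairs
#'   `"C-W"`, `"C-WRF"`, `"W-WRF"` (or any `"<g1>-<g2>"` pairs over
#'   `group_order`).
#' @param group_order Character vector fixing group processing order.
#' @return Named character vector of letter strings per group.
#' @export
#' @examples
#' assign_letter_groups(c("C-W" = FALSE, "C-WRF" = TRUE, "W-WRF" = TRUE))
assign_letter_groups <- function(pairwise_significant,
                                 group_order = c("C", "W", "WRF")) {
  k <- length(group_order)
  adj <- matrix(TRUE, k, k, dimnames = list(group_order, group_order))
  for (nm in names(pairwise_significant)) {
    gg <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (!all(gg %in% group_order)) {
      abort(paste0("Unknown group in pair '", nm, "'."))
    }
    sig <- isTRUE(pairwise_significant[[nm]])
    adj[gg[1], gg[2]] <- !sig
    adj[gg[2], gg[1]] <- !sig
  }
  # maximal cliques of the "not different" graph by subset enumeration
  subsets <- unlist(lapply(k:1, function(m) {
    utils::combn(k, m, simplify = FALSE)
  }), recursive = FALSE)
  is_clique <- function(s) all(adj[s, s, drop = FALSE])
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, TRUE))
  }, cliques)
  ord <- order(vapply(maximal, min, 0), vapply(maximal, function(s) -length(s), 0))
  maximal <- maximal[ord]
  letters_out <- setNames(rep("", k), group_order)
  for (i in seq_along(maximal)) {
    for (g in maximal[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

de_categories <- function() {
  c("WRF_up_vs_C_and_W", "WRF_down_vs_C_and_W", "W_different", "other",
    "none")
}

classify_de_pattern <- function(letter, medians) {
  share <- function(g1, g2) {
    any(strsplit(letter[[g1]], "")[[1]] %in% strsplit(letter[[g2]], "")[[1]])
  }
  wrf_distinct <- !share("WRF", "C") && !share("WRF", "W")
  w_distinct <- !share("W", "C") && !share("W", "WRF")
  if (wrf_distinct && medians[["WRF"]] > medians[["C"]] &&
      medians[["WRF"]] > medians[["W"]]) {
    "WRF_up_vs_C_and_W"
  } else if (wrf_distinct && medians[["WRF"]] < medians[["C"]] &&
             medians[["WRF"]] < medians[["W"]]) {
    "WRF_down_vs_C_and_W"
  } else if (w_distinct) {
    "W_different"
  } else {
    "other"
  }
}

#' Time-agnostic differential-expression screen
#'
#' Pools each group's 18 samples without regard to collection time and
#' screens every gene with a Kruskal-Wallis omnibus test, adjusts the
#' omnibus p-values across genes with Benjamini-Hochberg, and for genes
#' with `q <= alpha` runs all three pairwise Mann-Whitney post-hoc
#' tests, assigns compact letter groups from the raw post-hoc p-values
#' at `posthoc_alpha`, and categorizes the pattern (e.g.
#' `WRF_up_vs_C_and_W` when WRF carries a distinct letter and the
#' highest median). Post-hoc p-values are not multiplicity-adjusted;
#' only the omnibus layer is.
#'
#' @param study An expression-filtered [expr_study()] with all three
#'   groups present.
#' @param alpha Omnibus q-value threshold.
#' @param posthoc_alpha Raw post-hoc p threshold behind the letters.
#' @param continuity Continuity correction for the Mann-Whitney
#'   approximation path.
#' @return A tibble of class `de_screen`: one row per gene with `H`,
#'   `p_kw`, `q_kw`, pairwise p-values, letters, per-group medians and
#'   `category` (genes with `q > alpha` get `"none"`).
#' @export
differential_expression_screen <- function(study, alpha = 0.05,
                                           posthoc_alpha = 0.05,
                                           continuity = TRUE) {
  stopifnot(inherits(study, "expr_study"))
  groups <- study_groups()
  idx <- lapply(groups, function(g) which(study$samples$group == g))
  names(idx) <- groups
  if (any(lengths(idx) == 0)) {
    missing <- groups[lengths(idx) == 0][1]
    abort(paste0("Group '", missing, "' is missing from the study."))
  }
  g_factor <- study$samples$group
  values <- study$values
  n_genes <- nrow(values)

  kw <- purrr::map(seq_len(n_genes),
                   function(i) kruskal_wallis_test(values[i, ], g_factor))
  kw <- bind_rows(kw)
  q <- bh_adjust(kw$p)

  pairs <- list(c("C", "W"), c("C", "WRF"), c("W", "WRF"))
  pair_names <- vapply(pairs, paste, "", collapse = "-")

  med <- t(vapply(seq_len(n_genes), function(i) {
    vapply(idx, function(j) median(values[i, j]), 0)
  }, numeric(3)))
  colnames(med) <- groups

  one_gene <- function(i) {
    if (q[i] > alpha) {
      return(list(pp = setNames(rep(NA_real_, 3), pair_names),
                  letters = setNames(rep(NA_character_, 3), groups),
                  category = "none"))
    }
    pp <- vapply(pairs, function(pr) {
      mann_whitney_test(values[i, idx[[pr[1]]]], values[i, idx[[pr[2]]]],
                        continuity = continuity)$p
    }, 0)
    names(pp) <- pair_names
    lt <- assign_letter_groups(setNames(pp < posthoc_alpha, pair_names),
                               group_order = groups)
    list(pp = pp, letters = lt,
         category = classify_de_pattern(lt, med[i, ]))
  }
  per_gene <- purrr::map(seq_len(n_genes), one_gene)

  out <- tibble(
    gene_id = rownames(values),
    H = kw$H, p_kw = kw$p, q_kw = q,
    p_C_W = vapply(per_gene, function(x) x$pp[["C-W"]], 0),
    p_C_WRF = vapply(per_gene, function(x) x$pp[["C-WRF"]], 0),
    p_W_WRF = vapply(per_gene, function(x) x$pp[["W-WRF"]], 0),
    letter_C = vapply(per_gene, function(x) x$letters[["C"]], ""),
    letter_W = vapply(per_gene, function(x) x$letters[["W"]], ""),
    letter_WRF = vapply(per_gene, function(x) x$letters[["WRF"]], ""),
    median_C = med[, "C"], median_W = med[, "W"],
    median_WRF = med[, "WRF"],
    category = factor(vapply(per_gene, function(x) x$category, ""),
                      levels = de_categories())
  )
  class(out) <- c("de_screen", class(out))
  out
}
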