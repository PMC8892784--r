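#' Expression study container
#'
#' Bundles a genes-by-samples matrix of non-negative expression values
#' (fpkm scale) with per-sample metadata. The default full design of the
#' emulated study has 54 samples: 3 groups (C, W, WRF) x 6 Zeitgeber
#' times (ZT1, 5, 9, 13, 17, 21) x 3 replicate animals, each animal
#' contributing a single sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns. All values must be finite and non-negative.
#' @param samples Data frame of sample metadata with columns `label`,
#'   `group` (factor or character in C/W/WRF), `animal_id`, `zt`, and
#'   optionally `replicate_index` (assigned by grouping when absent).
#'   Row order must match the column order of `values`.
#'
#' @return An object of class `expr_study`: a list with elements
#'   `values` (the matrix) and `samples` (a tibble).
#' @export
#' @examples
#' samples <- parse_sample_label(c("C1ZT1", "C2ZT1", "C3ZT5"))
#' expr_study(matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), samples$label)),
#'            samples)
expr_study <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values))) {
    abort("`values` must carry gene ids as rownames.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(paste0("Duplicate gene id: '", dup, "'."))
  }
  if (any(!is.finite(values))) {
    abort("Expression values must all be finite.")
  }
  if (any(values < 0)) {
    abort("Expression values must be non-negative.")
  }
  samples <- as_tibble(samples)
  if (nrow(samples) != ncol(values)) {
    abort(sprintf(
      "Metadata has %d rows but the matrix has %d sample columns.",
      nrow(samples), ncol(values)
    ))
  }
  required <- c("label", "group", "animal_id", "zt")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    abort(paste0("Sample metadata lacks column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  samples$group <- validate_group(samples$group)
  if (any(samples$zt < 0 | samples$zt >= 24)) {
    abort("ZT values must lie in [0, 24).")
  }
  key <- paste(samples$group, samples$animal_id)
  if (anyDuplicated(key)) {
    abort("(group, animal_id) pairs must be unique within a study.")
  }
  if (!"replicate_index" %in% names(samples)) {
    samples <- assign_replicates(samples)
  }
  structure(list(values = values, samples = samples), class = "expr_study")
}

study_groups <- function() c("C", "W", "WRF")

validate_group <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), study_groups())
  if (length(bad)) {
    abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", "),
                 ". Groups must be one of C, W, WRF."))
  }
  factor(group, levels = study_groups())
}

# Replicate index = rank of animal_id within each (group, zt) cell.
assign_replicates <- function(samples) {
  samples |>
    group_by(.data$group, .data$zt) |>
    mutate(replicate_index = rank(.data$animal_id, ties.method = "first")) |>
    ungroup()
}

#' Parse sample labels of the form <GROUP><animal>ZT<hour>
#'
#' Sample labels encode the design directly, e.g. `"C29ZT17"` is animal
#' 29 of the control group euthanized at Zeitgeber time 17, and
#' `"WRF42ZT13"` is animal 42 of the shift-work restricted-feeding
#' group at ZT13.
#'
#' @param label Character vector of labels.
#' @return A tibble with one row per label and columns `label`, `group`
#'   (factor C/W/WRF), `animal_id` (integer), `zt` (numeric hours in
#'   \[0, 24)).
#' @export
#' @examples
#' parse_sample_label(c("WRF42ZT13", "C29ZT17"))
parse_sample_label <- function(label) {
  m <- stringr::str_match(label, "^(WRF|W|C)([0-9]+)ZT([0-9]+)$")
  bad <- label[is.na(m[, 1])]
  if (length(bad)) {
    abort(paste0("Malformed sample label(s): ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 ". Expected <GROUP><animal>ZT<hour> with GROUP in C/W/WRF."))
  }
  zt <- as.numeric(m[, 4])
  if (any(zt >= 24)) {
    abort(paste0("ZT out of range [0, 24) in label(s): ",
                 paste(label[zt >= 24], collapse = ", "), "."))
  }
  animal <- as.integer(m[, 3])
  if (any(animal < 1)) {
    abort("Animal ids must be positive integers.")
  }
  tibble(
    label = as.character(label),
    group = factor(m[, 2], levels = study_groups()),
    animal_id = animal,
    zt = zt
  )
}

#' Format sample metadata back into labels
#'
#' Inverse of [parse_sample_label()] over the label grammar.
#'
#' @param group,animal_id,zt Vectors of equal length (or a data frame in
#'   `group` containing those columns).
#' @return Character vector of labels.
#' @export
format_sample_label <- function(group, animal_id = NULL, zt = NULL) {
  if (is.data.frame(group)) {
    df <- group
    group <- df$group
    animal_id <- df$animal_id
    zt <- df$zt
  }
  paste0(as.character(group), animal_id, "ZT", format_zt(zt))
}

format_zt <- function(zt) {
  out <- as.character(zt)
  whole <- zt == floor(zt)
  out[whole] <- as.character(as.integer(zt[whole]))
  out
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf(
    "<expr_study> %d genes x %d samples (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", levels(x$samples$group),
                  tabulate(x$samples$group, 3L)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expr_study <- function(x) dim(x$values)

#' Long-format view of an expression study
#'
#' @param x An `expr_study`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `label`, `group`,
#'   `animal_id`, `zt`, `replicate_index`, `value`.
#' @method tidy expr_study
#' @export
tidy.expr_study <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "label", values_to = "value")
  left_join(long, x$samples, by = "label") |>
    select("gene_id", "label", "group", "animal_id", "zt",
           "replicate_index", "value")
}

#' One-row summary of an expression study
#'
#' @param x An `expr_study`.
#' @param ... Unused.
#' @method glance expr_study
#' @export
glance.expr_study <- function(x, ...) {
  tibble(
    n_genes = nrow(x$values),
    n_samples = ncol(x$values),
    n_groups = dplyr::n_distinct(x$samples$group),
    n_timepoints = dplyr::n_distinct(x$samples$zt),
    median_expression = stats::median(x$values)
  )
}

#' Subset an expression study to one group
#'
#' @param study An `expr_study`.
#' @param group One of `"C"`, `"W"`, `"WRF"`.
#' @return An `expr_study` restricted to that group's samples.
#' @export
study_group_subset <- function(study, group) {
  stopifnot(inherits(study, "expr_study"))
  group <- match.arg(group, study_groups())
  keep <- study$samples$group == group
  if (!any(keep)) {
    abort(paste0("Group '", group, "' has no samples in this study."))
  }
  expr_study(study$values[, keep, drop = FALSE], study$samples[keep, ])
}
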