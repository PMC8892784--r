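#' Read a genes-by-samples expression table
#'
#' Reads a tab-separated table whose first column holds gene ids and
#' whose remaining column headers are parseable sample labels (see
#' [parse_sample_label()]). Values are kept on the scale given in the
#' file (fpkm); no re-normalization is performed anywhere downstream.
#'
#' @param path Path to a TSV file.
#' @param metadata Optional sidecar data frame overriding label-derived
#'   metadata; must contain `label`, `group`, `animal_id`, `zt`.
#' @return An [expr_study()].
#' @export
read_expression_table <- function(path, metadata = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    abort(paste0("'", path, "' holds no expression data."))
  }
  gene_ids <- tab[[1]]
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    abort(paste0("Duplicate gene id in '", path, "': '", dup, "'."))
  }
  labels <- names(tab)[-1]
  values <- matrix(NA_real_, nrow(tab), length(labels),
                   dimnames = list(gene_ids, labels))
  for (j in seq_along(labels)) {
    raw <- tab[[j + 1]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric value '%s' at gene '%s', sample '%s' in '%s'.",
        raw[bad[1]], gene_ids[bad[1]], labels[j], path
      ))
    }
    neg <- which(num < 0)
    if (length(neg)) {
      abort(sprintf(
        "Negative expression value at gene '%s', sample '%s' in '%s'.",
        gene_ids[neg[1]], labels[j], path
      ))
    }
    values[, j] <- num
  }
  samples <- if (is.null(metadata)) {
    parse_sample_label(labels)
  } else {
    meta <- as_tibble(metadata)
    missing <- setdiff(labels, meta$label)
    if (length(missing)) {
      abort(paste0("Sidecar metadata lacks label(s): ",
                   paste(utils::head(missing, 5), collapse = ", "), "."))
    }
    meta[match(labels, meta$label), ]
  }
  expr_study(values, samples)
}

#' Write an expression study as a TSV table
#'
#' Inverse of [read_expression_table()]: `read` after `write` reproduces
#' values and label-encoded metadata exactly (full precision output).
#'
#' @param study An `expr_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(study, path) {
  stopifnot(inherits(study, "expr_study"))
  df <- as_tibble(study$values, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Gene-module catalog with a designated null module
#'
#' @param modules Named list of character vectors (module id -> gene ids).
#'   Gene ids are deduplicated; empty modules are rejected.
#' @param null_module_id Id of the reference (null) module, default
#'   `"M0"`: the set of genes unaffected by cardiac hypertrophy used as
#'   the baseline for enrichment and shift tests.
#' @return A `module_set` object.
#' @export
module_set <- function(modules, null_module_id = "M0") {
  if (is.null(names(modules)) || any(names(modules) == "")) {
    abort("All modules must be named.")
  }
  if (anyDuplicated(names(modules))) {
    abort("Module ids must be unique.")
  }
  modules <- lapply(modules, function(g) unique(as.character(g)))
  sizes <- lengths(modules)
  if (any(sizes == 0)) {
    abort(paste0("Empty module(s): ",
                 paste(names(modules)[sizes == 0], collapse = ", "), "."))
  }
  if (!null_module_id %in% names(modules)) {
    abort(paste0("Null module '", null_module_id, "' is missing."))
  }
  structure(list(modules = modules, null_module_id = null_module_id),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules (null: %s), sizes %d-%d\n",
              length(x$modules), x$null_module_id,
              min(lengths(x$modules)), max(lengths(x$modules))))
  invisible(x)
}

#' Disjoint up/down disease gene sets
#'
#' @param up_genes,down_genes Character vectors of gene ids; must be
#'   disjoint.
#' @param label Set label, e.g. `"ICM"` or `"DCM"`.
#' @return A `gene_set_pair` object.
#' @export
gene_set_pair <- function(up_genes, down_genes, label = "signature") {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  both <- intersect(up_genes, down_genes)
  if (length(both)) {
    abort(paste0("Up and down sets overlap (e.g. '", both[1], "')."))
  }
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 label = label),
            class = "gene_set_pair")
}

#' Read gene sets from a two-column TSV or a GMT file
#'
#' Two-column format: `set_id<TAB>gene_id`, one gene per line, optional
#' header `set_id  gene_id`. GMT format: one set per line,
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Gene ids are
#' deduplicated within each set.
#'
#' @param path Input path.
#' @param as One of `"modules"` (returns a [module_set()]; requires the
#'   null module to be present) or `"pair"` (returns a
#'   [gene_set_pair()]; requires sets named `up` and `down`, or exactly
#'   two sets whose ids end in `_up` / `_down`).
#' @param null_module_id Null module id when `as = "modules"`.
#' @param label Label when `as = "pair"`.
#' @return A `module_set` or `gene_set_pair`.
#' @export
read_gene_sets <- function(path, as = c("modules", "pair"),
                           null_module_id = "M0", label = "signature") {
  as <- match.arg(as)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(paste0("'", path, "' contains no gene sets."))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  sets <- if (all(nf == 2)) {
    first <- fields[[1]]
    if (identical(tolower(first), c("set_id", "gene_id"))) {
      fields <- fields[-1]
    }
    ids <- vapply(fields, `[`, "", 1)
    genes <- vapply(fields, `[`, "", 2)
    split(genes, factor(ids, levels = unique(ids)))
  } else {
    # GMT: second field is a description, dropped
    nm <- vapply(fields, `[`, "", 1)
    out <- lapply(fields, function(f) {
      if (length(f) < 3) abort("GMT lines need set_id, description, >=1 gene.")
      f[-(1:2)]
    })
    names(out) <- nm
    out
  }
  sets <- lapply(sets, unique)
  if (as == "modules") {
    if (!null_module_id %in% names(sets)) {
      abort(paste0("Null module '", null_module_id, "' not found in '",
                   path, "'."))
    }
    module_set(sets, null_module_id = null_module_id)
  } else {
    nm <- tolower(names(sets))
    up_i <- which(nm == "up" | endsWith(nm, "_up"))
    dn_i <- which(nm == "down" | endsWith(nm, "_down"))
    if (length(up_i) != 1 || length(dn_i) != 1) {
      abort("A gene-set pair needs exactly one 'up' and one 'down' set.")
    }
    gene_set_pair(sets[[up_i]], sets[[dn_i]], label = label)
  }
}

#' Write a module set or gene-set pair as two-column TSV
#'
#' @param x A `module_set` or `gene_set_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(x, path) {
  df <- if (inherits(x, "module_set")) {
    tibble(
      set_id = rep(names(x$modules), lengths(x$modules)),
      gene_id = unlist(x$modules, use.names = FALSE)
    )
  } else if (inherits(x, "gene_set_pair")) {
    tibble(
      set_id = rep(c("up", "down"),
                   c(length(x$up_genes), length(x$down_genes))),
      gene_id = c(x$up_genes, x$down_genes)
    )
  } else {
    abort("`x` must be a module_set or gene_set_pair.")
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records package version, seed, and the parameters of a pipeline run
#' so outputs can be reproduced exactly.
#'
#' @param path Output path.
#' @param seed Integer seed used for the run.
#' @param parameters Named list of run parameters.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, parameters = list()) {
  manifest <- list(
    package = "rhythmshift",
    version = as.character(utils::packageVersion("rhythmshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = parameters
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
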