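#' Configuration for a synthetic around-the-clock study
#'
#' Defines the conditions of the emulated design: 3 groups (control C,
#' shift worker W, shift worker with restricted feeding WRF) x 6
#' Zeitgeber times (ZT1, 5, 9, 13, 17, 21; tissue collected every 4 h
#' starting 1 h after lights-on) x 3 replicate animals, one sample per
#' animal, 54 samples in total.
#'
#' Defaults encode the structure of the emulated study: roughly half as
#' many rhythmic genes in W as in C and twice as many in WRF; control
#' phases spread across the day while W phases cluster near ZT12.5 and
#' WRF phases cluster near ZT8 and ZT20.5; dampened WRF amplitudes; one
#' W replicate series running out of phase; and a block of genes
#' up-regulated (plus a smaller block down-regulated) in WRF animals
#' only, gated per animal by a responder flag.
#'
#' @param n_genes Number of genes to simulate.
#' @param frac_rhythmic Named fractions (C, W, WRF) of genes planted
#'   rhythmic per group; draws are independent across groups.
#' @param phase_distribution Named list of per-group phase laws; each is
#'   either `list(type = "uniform")` or `list(type = "von_mises",
#'   mean = <hours>, kappa = <concentrations>, weight = <mixture weights>)`.
#' @param rel_amplitude Cosinor amplitude as a fraction of the baseline
#'   (mesor) for rhythmic genes, before dampening.
#' @param amplitude_dampening Multiplier applied to WRF amplitudes.
#' @param replicate_phase_shift Hours added to the rhythm phase of one W
#'   replicate series (all ZTs of `shifted_replicate`).
#' @param shifted_replicate Which W replicate series is shifted.
#' @param n_de_genes Number of differentially expressed genes (planted
#'   in WRF only); defaults to 9% of `n_genes`.
#' @param de_up_fraction Fraction of DE genes that are up-regulated.
#' @param de_fold Fold change applied in WRF (down genes get `1/de_fold`).
#' @param responder_fraction Probability that a WRF animal expresses the
#'   DE block; non-responders stay at baseline.
#' @param noise_cv Multiplicative coefficient of variation of the
#'   log-normal measurement noise.
#' @param baseline_meanlog,baseline_sdlog Log-normal law of gene
#'   baselines (mesors, fpkm).
#' @param seed Mandatory integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_genes = 10257,
                         frac_rhythmic = c(C = 0.10, W = 0.05, WRF = 0.20),
                         phase_distribution = default_phase_distribution(),
                         rel_amplitude = 0.5,
                         amplitude_dampening = 0.6,
                         replicate_phase_shift = 8,
                         shifted_replicate = 2,
                         n_de_genes = NULL,
                         de_up_fraction = 0.9,
                         de_fold = 2,
                         responder_fraction = 2 / 3,
                         noise_cv = 0.2,
                         baseline_meanlog = log(8),
                         baseline_sdlog = 1,
                         seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  if (n_genes < 1) abort("`n_genes` must be at least 1.")
  frac_rhythmic <- frac_rhythmic[study_groups()]
  if (any(is.na(frac_rhythmic)) ||
      any(frac_rhythmic < 0 | frac_rhythmic > 1)) {
    abort("`frac_rhythmic` needs fractions in [0, 1] for C, W and WRF.")
  }
  if (responder_fraction < 0 || responder_fraction > 1) {
    abort("`responder_fraction` must lie in [0, 1].")
  }
  if (rel_amplitude < 0 || rel_amplitude > 1) {
    abort("`rel_amplitude` must lie in [0, 1] so amplitudes stay below baselines.")
  }
  if (de_fold <= 0) abort("`de_fold` must be positive.")
  n_de_genes <- n_de_genes %||% round(0.09 * n_genes)
  if (n_de_genes > n_genes) abort("`n_de_genes` cannot exceed `n_genes`.")
  structure(list(
    n_genes = as.integer(n_genes),
    frac_rhythmic = frac_rhythmic,
    phase_distribution = phase_distribution,
    rel_amplitude = rel_amplitude,
    amplitude_dampening = amplitude_dampening,
    replicate_phase_shift = replicate_phase_shift,
    shifted_replicate = as.integer(shifted_replicate),
    n_de_genes = as.integer(n_de_genes),
    de_up_fraction = de_up_fraction,
    de_fold = de_fold,
    responder_fraction = responder_fraction,
    noise_cv = noise_cv,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' @rdname study_config
#' @export
default_phase_distribution <- function() {
  list(
    C = list(type = "uniform"),
    W = list(type = "von_mises", mean = 12.5, kappa = 6, weight = 1),
    WRF = list(type = "von_mises", mean = c(8, 20.5), kappa = c(8, 8),
               weight = c(0.5, 0.5))
  )
}

#' The 54-sample design table
#'
#' @return A tibble of 54 samples: 3 groups x ZT 1,5,9,13,17,21 x 3
#'   replicate animals, with labels, per-group animal ids and replicate
#'   indices.
#' @export
study_design <- function() {
  zts <- c(1, 5, 9, 13, 17, 21)
  design <- tidyr::expand_grid(
    group = factor(study_groups(), levels = study_groups()),
    replicate_index = 1:3,
    zt = zts
  )
  design |>
    mutate(
      animal_id = (.data$replicate_index - 1L) * 6L + match(.data$zt, zts),
      label = format_sample_label(.data$group, .data$animal_id, .data$zt)
    ) |>
    select("label", "group", "animal_id", "zt", "replicate_index")
}

# von Mises sampler (Best & Fisher rejection method), mean/sd in hours
# on a 24 h circle; supports mixtures.
r_vonmises_hours <- function(n, mean, kappa, weight = NULL, period = 24) {
  if (length(mean) > 1) {
    weight <- weight %||% rep(1 / length(mean), length(mean))
    comp <- sample.int(length(mean), n, replace = TRUE, prob = weight)
    out <- numeric(n)
    for (k in seq_along(mean)) {
      idx <- comp == k
      if (any(idx)) out[idx] <- r_vonmises_hours(sum(idx), mean[k], kappa[k],
                                                 period = period)
    }
    return(out)
  }
  mu <- mean * 2 * pi / period
  if (kappa < 1e-8) {
    theta <- runif(n, 0, 2 * pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(n)
    i <- 1L
    while (i <= n) {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        theta[i] <- mu + sign(u[3] - 0.5) * acos(f)
        i <- i + 1L
      }
    }
  }
  (theta * period / (2 * pi)) %% period
}

draw_phases <- function(n, law) {
  switch(law$type,
    uniform = runif(n, 0, 24),
    von_mises = r_vonmises_hours(n, law$mean, law$kappa, law$weight),
    abort(paste0("Unknown phase distribution type '", law$type, "'."))
  )
}

#' Simulate one gene's expression profile over a set of samples
#'
#' The value for sample s in group g is
#' `multiplier * (baseline + amplitude_g * cos(2*pi*(zt - phase_g)/24)) * exp(e)`
#' with `e ~ Normal(0, sigma)` and `sigma = sqrt(log(1 + noise_cv^2))`,
#' so the multiplicative coefficient of variation equals `noise_cv`.
#' The multiplier defaults to the gene's per-group fold change.
#'
#' @param truth One row of a ground-truth table (list or one-row data
#'   frame) with fields `baseline`, `noise_cv`, and per-group
#'   `amplitude_<g>`, `phase_<g>`, `de_mult_<g>`.
#' @param samples Sample metadata tibble (`group`, `zt`, ...).
#' @param phase_offset Per-sample hours added to the gene's phase
#'   (recycled); used for the out-of-phase W replicate series.
#' @param multiplier Optional per-sample multiplier overriding the
#'   group-level fold change (used for responder gating).
#' @return Numeric vector of strictly positive values, one per sample.
#' @export
generate_gene_profile <- function(truth, samples, phase_offset = 0,
                                  multiplier = NULL) {
  truth <- as.list(truth)
  g <- as.character(samples$group)
  amp <- vapply(g, function(x) truth[[paste0("amplitude_", x)]], 0)
  phase <- vapply(g, function(x) truth[[paste0("phase_", x)]], 0)
  if (any(amp > truth$baseline)) {
    abort("Amplitude exceeds baseline; expected value would go negative.")
  }
  if (is.null(multiplier)) {
    multiplier <- vapply(g, function(x) truth[[paste0("de_mult_", x)]], 0)
  }
  mu <- multiplier *
    (truth$baseline +
       amp * cos(2 * pi * (samples$zt - phase - phase_offset) / 24))
  if (truth$noise_cv > 0) {
    sigma <- sqrt(log(1 + truth$noise_cv^2))
    mu <- mu * exp(rnorm(nrow(samples), 0, sigma))
  }
  unname(mu)
}

#' Generate a full synthetic study with ground truth
#'
#' Draws per-gene baselines, per-group rhythm parameters, the WRF
#' differential-expression block with animal-level responder gating,
#' the dampened WRF amplitudes and the out-of-phase W replicate series,
#' then simulates all 54 samples. Identical configs (including seed)
#' yield byte-identical output.
#'
#' @param config A [study_config()].
#' @return A list of class `study_sim` with elements `study` (an
#'   [expr_study()]), `truth` (tibble of planted per-gene parameters),
#'   `responders` (WRF animal ids carrying the DE block) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  withr::with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  design <- study_design()
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  truth <- tibble(gene_id = gene_id, baseline = baseline,
                  noise_cv = config$noise_cv)
  for (g in study_groups()) {
    rhythmic <- runif(n) < config$frac_rhythmic[[g]]
    phase <- numeric(n)
    if (any(rhythmic)) {
      phase[rhythmic] <- draw_phases(sum(rhythmic),
                                     config$phase_distribution[[g]])
    }
    amp <- ifelse(rhythmic, config$rel_amplitude * baseline, 0)
    if (g == "WRF") amp <- amp * config$amplitude_dampening
    truth[[paste0("rhythmic_", g)]] <- rhythmic
    truth[[paste0("amplitude_", g)]] <- amp
    truth[[paste0("phase_", g)]] <- phase
    truth[[paste0("de_mult_", g)]] <- rep(1, n)
  }

  if (config$n_de_genes > 0) {
    de_idx <- sort(sample.int(n, config$n_de_genes))
    n_up <- round(config$n_de_genes * config$de_up_fraction)
    up_idx <- de_idx[seq_len(n_up)]
    down_idx <- setdiff(de_idx, up_idx)
    truth$de_mult_WRF[up_idx] <- config$de_fold
    truth$de_mult_WRF[down_idx] <- 1 / config$de_fold
  }

  wrf_animals <- unique(design$animal_id[design$group == "WRF"])
  responders <- wrf_animals[runif(length(wrf_animals)) <
                              config$responder_fraction]

  is_wrf <- design$group == "WRF"
  responder_sample <- !is_wrf | design$animal_id %in% responders
  phase_offset <- ifelse(
    design$group == "W" &
      design$replicate_index == config$shifted_replicate,
    config$replicate_phase_shift, 0
  )

  values <- matrix(NA_real_, n, nrow(design),
                   dimnames = list(gene_id, design$label))
  group_chr <- as.character(design$group)
  for (i in seq_len(n)) {
    mult <- vapply(group_chr,
                   function(x) truth[[paste0("de_mult_", x)]][i], 0)
    mult[is_wrf & !responder_sample] <- 1
    values[i, ] <- generate_gene_profile(truth[i, ], design,
                                         phase_offset = phase_offset,
                                         multiplier = mult)
  }

  structure(list(
    study = expr_study(values, design),
    truth = truth,
    responders = responders,
    config = config
  ), class = "study_sim")
}

#' @export
print.study_sim <- function(x, ...) {
  n_wrf <- sum(x$study$samples$group == "WRF")
  cat(sprintf(
    "<study_sim> %d genes x %d samples; planted rhythmic C/W/WRF: %d/%d/%d; DE: %d; WRF responders: %d/%d\n",
    nrow(x$study$values), ncol(x$study$values),
    sum(x$truth$rhythmic_C), sum(x$truth$rhythmic_W),
    sum(x$truth$rhythmic_WRF), sum(x$truth$de_mult_WRF != 1),
    length(x$responders), n_wrf
  ))
  invisible(x)
}

#' Generate a module catalog with optional planted enrichment
#'
#' Assigns genes to modules M1..Mk (sampling without replacement); the
#' null module M0 receives all unassigned background genes. A planted
#' module draws a stated fraction of its members from `up_gene_set`,
#' creating a known enrichment relative to M0.
#'
#' @param genes Character vector: the gene universe.
#' @param sizes Integer vector of module sizes (module ids M1, M2, ...).
#' @param planted_enrichment Named list/vector mapping module id to the
#'   fraction of its genes drawn from `up_gene_set`.
#' @param up_gene_set Genes to enrich from (must be large enough for
#'   the requested draws).
#' @return A [module_set()] with null module M0.
#' @export
generate_module_catalog <- function(genes, sizes,
                                    planted_enrichment = list(),
                                    up_gene_set = character()) {
  if (any(sizes < 1)) abort("Module sizes must be at least 1.")
  if (sum(sizes) >= length(genes)) {
    abort("Modules would exhaust the universe; M0 needs background genes.")
  }
  planted_enrichment <- unlist(planted_enrichment)
  if (length(planted_enrichment) &&
      any(planted_enrichment < 0 | planted_enrichment > 1)) {
    abort("Planted enrichment fractions must lie in [0, 1].")
  }
  available <- genes
  modules <- list()
  for (k in seq_along(sizes)) {
    id <- paste0("M", k)
    size <- sizes[k]
    frac <- if (id %in% names(planted_enrichment)) {
      planted_enrichment[[id]]
    } else 0
    n_up <- round(frac * size)
    pool_up <- intersect(up_gene_set, available)
    if (n_up > length(pool_up)) {
      abort(sprintf(
        "Module %s needs %d genes from the up set but only %d are available.",
        id, n_up, length(pool_up)
      ))
    }
    picked_up <- if (n_up > 0) sample(pool_up, n_up) else character()
    pool_rest <- setdiff(available, c(up_gene_set, picked_up))
    if (size - n_up > length(pool_rest)) {
      abort(sprintf("Not enough background genes left for module %s.", id))
    }
    picked <- c(picked_up, sample(pool_rest, size - n_up))
    modules[[id]] <- picked
    available <- setdiff(available, picked)
  }
  modules <- c(list(M0 = available), modules)
  module_set(modules, null_module_id = "M0")
}

#' Generate up/down disease gene sets from planted ground truth
#'
#' With `shift_log2 = 0` the sets are uniform random draws from the
#' gene universe (no relation to the planted effects). With
#' `shift_log2 > 0` the up set is drawn from genes whose planted
#' WRF/C log2 fold change is at least `shift_log2`, and the down set
#' symmetrically from genes at or below `-shift_log2`.
#'
#' @param truth Ground-truth tibble from [generate_study()].
#' @param n_up,n_down Set sizes.
#' @param shift_log2 Non-negative log2 fold-change threshold.
#' @param label Label for the pair.
#' @return A [gene_set_pair()].
#' @export
generate_disease_gene_sets <- function(truth, n_up, n_down,
                                       shift_log2 = 1,
                                       label = "synthetic_disease") {
  ratio <- log2(truth$de_mult_WRF / truth$de_mult_C)
  if (shift_log2 == 0) {
    pool_up <- truth$gene_id
    pool_down <- truth$gene_id
  } else {
    pool_up <- truth$gene_id[ratio >= shift_log2]
    pool_down <- truth$gene_id[ratio <= -shift_log2]
  }
  if (n_up > length(pool_up)) {
    abort(sprintf("Only %d genes qualify for the up set (need %d).",
                  length(pool_up), n_up))
  }
  up <- if (n_up > 0) sample(pool_up, n_up) else character()
  pool_down <- setdiff(pool_down, up)
  if (n_down > length(pool_down)) {
    abort(sprintf("Only %d genes qualify for the down set (need %d).",
                  length(pool_down), n_down))
  }
  down <- if (n_down > 0) sample(pool_down, n_down) else character()
  gene_set_pair(up, down, label = label)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
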