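# Shared fixtures, built in code. The cache avoids regenerating the
# same simulated study across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

design_times <- function(reps = 3) rep(c(1, 5, 9, 13, 17, 21), each = reps)

cosine_series <- function(mesor = 10, amplitude = 3, phase = 9,
                          reps = 3, period = 24) {
  t <- design_times(reps)
  list(t = t, y = mesor + amplitude * cos(2 * pi * (t - phase) / period))
}

# A small complete study with planted rhythmic and DE genes.
small_sim <- function() {
  cached("small_sim", {
    cfg <- study_config(
      n_genes = 120, frac_rhythmic = c(C = 0.3, W = 0.3, WRF = 0.3),
      n_de_genes = 15, responder_fraction = 1, noise_cv = 0.15,
      seed = 4711
    )
    generate_study(cfg)
  })
}

flat_truth_row <- function(baseline = 10, noise_cv = 0) {
  row <- list(baseline = baseline, noise_cv = noise_cv)
  for (g in c("C", "W", "WRF")) {
    row[[paste0("amplitude_", g)]] <- 0
    row[[paste0("phase_", g)]] <- 0
    row[[paste0("de_mult_", g)]] <- 1
  }
  row
}
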