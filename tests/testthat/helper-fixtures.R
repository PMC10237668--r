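# Shared fixtures. MCMC fits are memoized so several test files can reuse
# them without refitting.

cp_memo <- new.env(parent = emptyenv())

small_trials <- function() {
  if (is.null(cp_memo$tt)) {
    cp_memo$tt <- gen_responses(15, generative_params(seed = 3, n_pairs = 8))
  }
  cp_memo$tt
}

small_settings <- function(seed = 2) {
  reduced_settings(chains = 2, iterations = 1200, warmup = 300, thin = 1,
                   seed = seed)
}

small_fit <- function(model, prior_sd = 1.5) {
  key <- sprintf("fit_%s_%g", model, prior_sd)
  if (is.null(cp_memo[[key]])) {
    cp_memo[[key]] <- suppressWarnings(
      fit_choice_model(model_spec(model), small_trials(),
                       prior_spec(prior_sd), small_settings()))
  }
  cp_memo[[key]]
}

# A deterministic tiny FPCA training set on a shared grid.
toy_normalized_set <- function(n = 12, grid_size = 21, seed = 5) {
  params <- contour_gen_params(grid_size = grid_size)
  raw <- gen_contours(ceiling(n / 2), params, seed = seed)
  lapply(raw[seq_len(n)], normalize_time, grid_size = grid_size)
}
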