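# Shared small simulated datasets, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# clean 3-species study: no homology, no impurity, no duplicates/errors --
# every downstream count is exactly attributable
clean_sim <- function() {
  if (is.null(.fixtures$clean)) {
    .fixtures$clean <- simulate_msgbs_dataset(
      n_species = 3, genome_length = 1e5, homology = 0,
      yield_factors = c(1, 1, 1), n_calibration = 3,
      depth_monoculture = 3000, depth_calibration = 3000,
      depth_mixture = 3000, duplication_rate = 0, error_rate = 0,
      monoculture_impurity = 0, seed = 401)
  }
  .fixtures$clean
}

# default-condition 4-species study (homology, impurity, duplicates, errors)
messy_sim <- function() {
  if (is.null(.fixtures$messy)) {
    .fixtures$messy <- simulate_msgbs_dataset(
      n_species = 4, genome_length = 2e5, homology = 0.1,
      n_calibration = 4, depth_monoculture = 5000,
      depth_calibration = 5000, depth_mixture = 5000, seed = 402)
  }
  .fixtures$messy
}

clean_run <- function() {
  if (is.null(.fixtures$clean_run)) {
    .fixtures$clean_run <- run_msgbs(clean_sim()$library,
                                     params = filter_params(f3 = 500))
  }
  .fixtures$clean_run
}

messy_run <- function() {
  if (is.null(.fixtures$messy_run)) {
    .fixtures$messy_run <- run_msgbs(messy_sim()$library,
                                     params = filter_params(f3 = 500))
  }
  .fixtures$messy_run
}
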