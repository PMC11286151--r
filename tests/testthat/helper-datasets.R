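# small deterministic fixtures built in code

# a driver-linked dataset with a strong cusp signal (fast to fit)
strong_cusp_data <- function(seed = 42, n = 50, beta_mean = 2) {
  sim_cusp_dataset(n_steps = n, beta_mean = beta_mean, seed = seed)
}

# a dataset whose state is pure white noise, unrelated to the drivers
noise_data <- function(seed = 7, n = 50) {
  set.seed(seed)
  cusp_data(tibble::tibble(
    time = seq_len(n),
    state = rnorm(n),
    driver_a = gen_alpha_ar1(n),
    driver_b = gen_beta_normal(n, 0, 1)
  ))
}
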