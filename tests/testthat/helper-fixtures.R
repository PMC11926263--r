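# Shared fixtures, all built in code.

tiny_cohort <- function() {
  cohort_table(data.frame(
    patient_id = c("a", "b", "c", "d", "e", "f"),
    sex = c("female", "female", "male", "male", "female", "male"),
    age = c(49, 50, 51, NA, 30, 60),
    bmi = c(29.9, 30, 31, 22, NA, 28),
    prl = c(100, 150, 800, 1200, 90, NA),
    invasion = c(0L, 0L, 1L, 1L, NA, 1L),
    treatment = c("surgery", "medical", NA, "surgery", "medical", "medical")))
}

# single posterior draw as used by the closed-form examples
one_draw <- function(alpha = 0, u_f = 0, u_m = 0, sigma_u = 1, beta = 1) {
  list(alpha = alpha, u_female = u_f, u_male = u_m, sigma_u = sigma_u,
       beta = beta)
}

# wrap a hand-made draw matrix into a minimal posterior_sample
fake_sample <- function(draws_df, seed = 1L) {
  draws_df$.chain <- 1L
  structure(list(draws = draws_df, chains = 1L, iter = nrow(draws_df),
                 warmup = 0L, thin = 1L,
                 diagnostics = data.frame(), seed = seed, reduced = FALSE,
                 accept_rates = NA_real_, priors = prior_config(),
                 n_obs = NA_integer_),
            class = "posterior_sample")
}

# fast MCMC settings for tests that need a real fit
fit_small <- function(mi, seed, chains = 2L, iter = 500L, warmup = 400L,
                      thin = 2L) {
  fit_invasion_model(mi, chains = chains, iter = iter, warmup = warmup,
                     thin = thin, seed = seed)
}

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
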