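test_that("log_posterior matches a direct evaluation of the formula", {
  pr <- prior_config()
  # empty data -> log prior only
  empty <- new_model_input(numeric(0), integer(0), character(0))
  draw <- one_draw(alpha = 1, u_f = -0.5, u_m = 0.5, sigma_u = 0.8, beta = 2)
  lp_prior <- dnorm(1, 0, 5, log = TRUE) + dnorm(2, 0, 2.5, log = TRUE) +
    log(2) + dnorm(0.8, 0, 1, log = TRUE) +
    dnorm(-0.5, 0, 0.8, log = TRUE) + dnorm(0.5, 0, 0.8, log = TRUE)
  expect_equal(log_posterior(draw, empty, pr), lp_prior, tolerance = 1e-12)

  # one record, linear predictor 0, y = 1 -> adds log(0.5)
  d1 <- new_model_input(0, 1L, "female")
  expect_equal(log_posterior(one_draw(), d1, pr),
               log_posterior(one_draw(), empty, pr) + log(0.5),
               tolerance = 1e-12)

  # 5-record hand dataset against an independent spreadsheet-style sum
  x <- c(1.5, 2.0, 2.5, 3.0, 3.2)
  y <- c(0L, 0L, 1L, 0L, 1L)
  g <- c("female", "male", "female", "male", "male")
  di <- new_model_input(x, y, g)
  dr <- one_draw(alpha = -4, u_f = -0.3, u_m = 0.3, sigma_u = 0.6, beta = 1.5)
  u <- ifelse(g == "male", 0.3, -0.3)
  eta <- -4 + u + 1.5 * x
  p <- 1 / (1 + exp(-eta))
  ll_hand <- sum(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(log_posterior(dr, di, pr) - log_posterior(dr, empty, pr),
               ll_hand, tolerance = 1e-10)

  # record-order invariance
  o <- sample(5)
  expect_equal(log_posterior(dr, new_model_input(x[o], y[o], g[o]), pr),
               log_posterior(dr, di, pr), tolerance = 1e-12)

  # numerically stable at |eta| ~ 700
  dbig <- new_model_input(c(300, -300), c(1L, 0L), c("female", "male"))
  lp <- log_posterior(one_draw(beta = 2), dbig, pr)
  expect_true(is.finite(lp))
})

test_that("predict_probability closed forms and monotonicity", {
  s <- fake_sample(data.frame(alpha = 0, u_female = 0, u_male = 0,
                              sigma_u = 1, beta = 1))
  expect_equal(predict_probability(s, 1, "female"), 0.5)
  expect_equal(predict_probability(s, 10, "female"), plogis(1),
               tolerance = 1e-12)
  expect_error(predict_probability(s, -1, "female"), "prl must be > 0")
  # per-draw monotonicity when beta >= 0
  set.seed(2)
  many <- fake_sample(data.frame(alpha = rnorm(50), u_female = rnorm(50, 0, .3),
                                 u_male = rnorm(50, 0, .3), sigma_u = 1,
                                 beta = abs(rnorm(50))))
  grid <- c(10, 50, 100, 500, 1000)
  for (i in seq_along(grid)[-1]) {
    expect_true(all(predict_probability(many, grid[i], "male") >=
                    predict_probability(many, grid[i - 1], "male")))
  }
})

test_that("fit refuses single-class outcomes and reduces for single gender", {
  one_class <- new_model_input(c(2, 2.5, 3), c(1L, 1L, 1L), rep("female", 3))
  expect_error(fit_invasion_model(one_class, seed = 1), "single class")
  expect_error(fit_invasion_model(new_model_input(2, 1L, "male")),
               "seed is mandatory")
  set.seed(31)
  x <- rnorm(120, 2.5, 0.6)
  y <- rbinom(120, 1, plogis(-5 + 2 * x))
  fem <- new_model_input(x, as.integer(y), rep("female", 120))
  fit <- fit_small(fem, seed = 4)
  expect_true(fit$reduced)
  expect_true(all(fit$draws$u_female == 0) && all(fit$draws$u_male == 0))
  expect_true(all(is.na(fit$draws$sigma_u)))
  expect_true(all(is.finite(fit$draws$beta)))
})

test_that("prior recovery: zero-length data returns the prior", {
  empty <- new_model_input(numeric(0), integer(0), character(0))
  fit <- fit_invasion_model(empty, chains = 2, iter = 2000, warmup = 500,
                            thin = 3, seed = 8)
  expect_equal(sd(fit$draws$beta), 2.5, tolerance = 0.1)
  expect_equal(sd(fit$draws$alpha), 5, tolerance = 0.12)
  # MC error on a prior mean: ~4 SE at the realised ESS
  ess <- fit$diagnostics$ess_bulk[fit$diagnostics$parameter == "beta"]
  expect_lt(abs(mean(fit$draws$beta)), 4 * 2.5 / sqrt(ess))
})

test_that("MAP with wide priors matches the IRLS oracle within 2%", {
  set.seed(77)
  n <- 2000
  x <- rnorm(n, 2.5, 0.7)
  y <- as.integer(rbinom(n, 1, plogis(-6 + 2 * x)))
  g <- rep(c("female", "male"), n / 2)
  mi <- new_model_input(x, y, g)
  map <- map_estimate(mi, prior_config(alpha_sd = 100, beta_sd = 100),
                      offsets = FALSE)
  ml <- coef(glm(y ~ x, family = binomial))  # independent IRLS oracle
  expect_equal(unname(map["alpha"]), unname(ml[1]), tolerance = 0.02)
  expect_equal(unname(map["beta"]), unname(ml[2]), tolerance = 0.02)
})

test_that("perfect separation stays finite under the prior", {
  mi <- new_model_input(c(1, 1.2, 3, 3.5), c(0L, 0L, 1L, 1L),
                        c("female", "male", "female", "male"))
  fit <- fit_small(mi, seed = 5)
  expect_true(all(is.finite(as.matrix(fit$draws[, c("alpha", "beta")]))))
  expect_true(all(c("r_hat", "ess_bulk") %in% names(fit$diagnostics)))
})

test_that("convergence diagnostics separate mixed from pathological chains", {
  set.seed(9)
  iid <- matrix(rnorm(4000), 1000, 4)  # 4 chains from the same normal
  expect_equal(split_rhat(iid), 1, tolerance = 0.01)
  stuck <- cbind(rep(0, 500) + rnorm(500, sd = 1e-3),
                 rep(10, 500) + rnorm(500, sd = 1e-3))
  expect_gt(split_rhat(stuck), 2)
  expect_gt(mcmc_ess(iid)[["ess_bulk"]], 2000)  # near-independent draws
  # single chain flagged
  s1 <- fake_sample(data.frame(alpha = rnorm(100), u_female = 0, u_male = 0,
                               sigma_u = 1, beta = rnorm(100)))
  s1$diagnostics <- data.frame(parameter = "alpha", r_hat = 1,
                               ess_bulk = 100, ess_tail = 100)
  rep1 <- convergence_report(s1)
  expect_true(is.na(attr(rep1, "pass")))
})

test_that("recovery fit: posterior covers truth and passes diagnostics", {
  set.seed(123)
  n <- 2000
  g <- rep(c("female", "male"), n / 2)
  x <- rnorm(n, 3, 0.7)
  eta <- -6 + ifelse(g == "male", 1, -1) + 2 * x
  y <- as.integer(rbinom(n, 1, plogis(eta)))
  mi <- new_model_input(x, y, g)
  fit <- fit_invasion_model(mi, seed = 42)  # default 4 chains x 1000
  q <- quantile(fit$draws$beta, c(0.025, 0.975))
  expect_true(q[1] < 2 && 2 < q[2])
  # posterior mean within 3 posterior SDs of truth
  expect_lt(abs(mean(fit$draws$beta) - 2), 3 * sd(fit$draws$beta))
  rep <- convergence_report(fit)
  expect_true(attr(rep, "pass"))  # max R-hat <= 1.01 and min ESS >= 400
})
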