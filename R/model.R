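# Bayesian mixed-effect logistic regression of cavernous sinus invasion on
# log10 serum prolactin with a per-gender random offset:
#
#   y_i ~ Bernoulli(p_i),  logit(p_i) = alpha + u_{g_i} + beta * x_i
#   x_i = log10(PRL_i),    u_g ~ Normal(0, sigma_u)
#
# Priors (weakly informative on the logit scale): alpha ~ N(0, 5),
# beta ~ N(0, 2.5), sigma_u ~ Half-Normal(1). With only two gender levels
# sigma_u is weakly identified; the half-normal keeps the offsets proper.
# Sampling is centred: adaptive random-walk Metropolis on
# (alpha, u_female, u_male, beta) with a slice-sampling Gibbs update for
# log sigma_u, whose conditional involves only the offsets.

#' Model input for the invasion regression
#'
#' Extracts `x = log10(prl)`, the binary outcome `y` and the gender index
#' from a complete-case cohort. The source cohort rows are retained as an
#' attribute so subgroup restrictions (age/BMI) stay available downstream.
#'
#' @param cohort a `cohort_table`; rows with missing prl or invasion are
#'   dropped (complete-case only).
#' @return A `model_input` list with elements `x`, `y`, `g` and the backing
#'   cohort in `attr(, "cohort")`.
#' @export
model_input <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  cc <- complete_case_filter(cohort, c("prl", "invasion"))
  out <- new_model_input(log10(cc$prl), cc$invasion, cc$sex)
  attr(out, "cohort") <- cc
  out
}

#' Low-level model-input constructor
#'
#' @param x numeric vector of log10 prolactin values (finite).
#' @param y integer vector of invasion indicators in {0,1}.
#' @param g character vector of "female"/"male".
#' @return A `model_input` list.
#' @export
new_model_input <- function(x, y, g) {
  stopifnot(length(x) == length(y), length(y) == length(g),
            all(is.finite(x)), all(y %in% c(0L, 1L)),
            all(g %in% .SEX_LEVELS))
  structure(list(x = as.numeric(x), y = as.integer(y), g = as.character(g)),
            class = "model_input")
}

#' Prior configuration
#'
#' @param alpha_sd SD of the Normal(0, .) prior on the intercept.
#' @param beta_sd SD of the Normal(0, .) prior on the log10-PRL slope.
#' @param sigma_u_sd scale of the Half-Normal prior on the offset SD.
#' @return A `prior_config` list.
#' @export
prior_config <- function(alpha_sd = 5, beta_sd = 2.5, sigma_u_sd = 1) {
  stopifnot(alpha_sd > 0, beta_sd > 0, sigma_u_sd > 0)
  structure(list(alpha_sd = alpha_sd, beta_sd = beta_sd,
                 sigma_u_sd = sigma_u_sd), class = "prior_config")
}

# Numerically stable Bernoulli log likelihood: for eta = linear predictor,
# log p(y) = y*eta - log(1 + exp(eta)), with log1p-exp evaluated so that
# |eta| up to ~700 cannot overflow.
.bernoulli_loglik <- function(eta, y) {
  log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - log1pe)
}

#' Log posterior density of one parameter draw
#'
#' Evaluates the sum of the Bernoulli log likelihood over the data and the
#' log priors at a single parameter point on the natural scale.
#'
#' @param draw named list or vector with `alpha`, `u_female`, `u_male`,
#'   `sigma_u` (> 0) and `beta`.
#' @param data a [model_input()]; may have zero rows (log prior only).
#' @param priors a [prior_config()].
#' @return scalar log density (unnormalised).
#' @export
log_posterior <- function(draw, data, priors = prior_config()) {
  draw <- as.list(draw)
  stopifnot(!is.null(draw$alpha), !is.null(draw$beta))
  u <- c(female = draw$u_female %||% 0, male = draw$u_male %||% 0)
  lp <- dnorm(draw$alpha, 0, priors$alpha_sd, log = TRUE) +
    dnorm(draw$beta, 0, priors$beta_sd, log = TRUE)
  if (!is.null(draw$sigma_u)) {
    if (draw$sigma_u <= 0) return(-Inf)
    lp <- lp + log(2) + dnorm(draw$sigma_u, 0, priors$sigma_u_sd, log = TRUE) +
      sum(dnorm(u, 0, draw$sigma_u, log = TRUE))
  }
  if (length(data$x)) {
    eta <- draw$alpha + u[data$g] + draw$beta * data$x
    ll <- .bernoulli_loglik(eta, data$y)
    if (!is.finite(ll)) {
      i <- which(!is.finite(data$y * eta - abs(eta)))[1]
      stop("non-finite likelihood contribution at record ",
           if (is.na(i)) "?" else i, call. = FALSE)
    }
    lp <- lp + ll
  }
  lp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sampler-space targets. Full model is parameterised centred as
# theta4 = (alpha, u_female, u_male, beta) plus log_sigma handled by a
# dedicated slice step (its conditional never touches the data). Reduced
# model (single gender): theta = (alpha, beta).
.make_reduced_target <- function(data, priors) {
  function(theta) {
    lp <- dnorm(theta[1], 0, priors$alpha_sd, log = TRUE) +
      dnorm(theta[2], 0, priors$beta_sd, log = TRUE)
    if (length(data$x)) {
      eta <- theta[1] + theta[2] * data$x
      lp <- lp + .bernoulli_loglik(eta, data$y)
    }
    lp
  }
}

# log p(theta4 | sigma, data): likelihood + priors on alpha, beta and the
# centred offsets u_g ~ N(0, sigma)
.make_theta4_target <- function(data, priors) {
  g_male <- data$g == "male"
  function(theta, sigma) {
    lp <- dnorm(theta[1], 0, priors$alpha_sd, log = TRUE) +
      sum(dnorm(theta[2:3], 0, sigma, log = TRUE)) +
      dnorm(theta[4], 0, priors$beta_sd, log = TRUE)
    if (length(data$x)) {
      eta <- theta[1] + ifelse(g_male, theta[3], theta[2]) + theta[4] * data$x
      lp <- lp + .bernoulli_loglik(eta, data$y)
    }
    lp
  }
}

# log p(log_sigma | u): half-normal prior with log-scale Jacobian plus the
# offset prior terms
.log_sigma_conditional <- function(u, priors) {
  function(ls) {
    s <- exp(ls)
    log(2) + dnorm(s, 0, priors$sigma_u_sd, log = TRUE) + ls +
      sum(dnorm(u, 0, s, log = TRUE))
  }
}

# full 5-dim centred posterior (alpha, u_f, u_m, log_sigma, beta), used for
# MAP optimisation only
.make_full_target <- function(data, priors) {
  t4 <- .make_theta4_target(data, priors)
  function(theta) {
    s <- exp(theta[4])
    t4(theta[c(1, 2, 3, 5)], s) +
      log(2) + dnorm(s, 0, priors$sigma_u_sd, log = TRUE) + theta[4]
  }
}

# One chain for the full model: adaptive RWM on theta4 within Gibbs with a
# slice update for log_sigma.
.run_full_chain <- function(data, priors, init4, init_ls, cov0,
                            warmup, iter_keep, thin) {
  target <- .make_theta4_target(data, priors)
  lambda <- 2.38^2 / 4
  ch <- .safe_chol(cov0)
  theta <- init4
  ls <- init_ls
  lp <- target(theta, exp(ls))
  warm <- matrix(NA_real_, warmup, 4L)
  for (t in seq_len(warmup)) {
    prop <- .mvrnorm1(theta, sqrt(lambda) * ch)
    lp_prop <- target(prop, exp(ls))
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      lambda <- lambda * exp(0.766 / sqrt(t))
    } else lambda <- lambda * exp(-0.234 / sqrt(t))
    ls <- slice_sample1(.log_sigma_conditional(theta[2:3], priors), ls)
    lp <- target(theta, exp(ls))
    warm[t, ] <- theta
    if (t >= 100L && t %% 100L == 0L) {
      S <- stats::cov(warm[max(1L, t %/% 2L):t, , drop = FALSE])
      if (all(is.finite(S)) && any(diag(S) > 0)) ch <- .safe_chol(S)
    }
  }
  out <- matrix(NA_real_, iter_keep, 5L)
  acc <- 0L
  step_ch <- sqrt(lambda) * ch
  for (k in seq_len(iter_keep)) {
    for (s in seq_len(thin)) {
      prop <- .mvrnorm1(theta, step_ch)
      lp_prop <- target(prop, exp(ls))
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; acc <- acc + 1L
      }
      ls <- slice_sample1(.log_sigma_conditional(theta[2:3], priors), ls)
      lp <- target(theta, exp(ls))
    }
    out[k, ] <- c(theta[1:3], ls, theta[4])
  }
  attr(out, "accept_rate") <- acc / (iter_keep * thin)
  out
}

#' Posterior-mode (MAP) estimate
#'
#' Maximises the log posterior by quasi-Newton optimisation. With wide
#' priors and the offsets disabled this approaches the maximum-likelihood
#' logistic fit.
#'
#' @param data a [model_input()].
#' @param priors a [prior_config()].
#' @param offsets if `FALSE`, fit the reduced model without gender offsets.
#' @return named vector of parameter values at the mode.
#' @export
map_estimate <- function(data, priors = prior_config(), offsets = TRUE) {
  reduced <- !offsets || length(unique(data$g)) < 2L
  target <- if (reduced) .make_reduced_target(data, priors)
            else .make_full_target(data, priors)
  init <- if (reduced) c(0, 0) else c(0, 0, 0, -1, 0)
  fit <- optim(init, function(th) -target(th), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  th <- fit$par
  if (reduced) c(alpha = th[1], beta = th[2])
  else c(alpha = th[1], u_female = th[2], u_male = th[3],
         sigma_u = exp(th[4]), beta = th[5])
}

#' Fit the invasion model by MCMC
#'
#' Samples the posterior with an adaptive-Metropolis random walk started at
#' the posterior mode, using the curvature there as the initial proposal
#' covariance. Single-gender data drop the offset hierarchy (recorded in the
#' result's provenance); a single-class outcome is refused.
#'
#' @param data a [model_input()].
#' @param chains number of chains (default 4).
#' @param iter post-warmup draws kept per chain (default 1000).
#' @param warmup adaptation steps per chain (default 1000).
#' @param thin Markov steps per kept draw (default 5).
#' @param seed integer seed; mandatory, no hidden global RNG state is used.
#' @param priors a [prior_config()].
#' @return A `posterior_sample`: `draws` (data.frame, one row per draw with
#'   columns alpha, u_female, u_male, sigma_u, beta), `chains`, `iter`,
#'   `diagnostics`, `seed`, `reduced`, `accept_rates`.
#' @export
fit_invasion_model <- function(data, chains = 4L, iter = 1000L,
                               warmup = 1000L, thin = 5L, seed,
                               priors = prior_config()) {
  stopifnot(inherits(data, "model_input"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- length(data$x)
  if (n > 0L && length(unique(data$y)) < 2L)
    stop("outcome has a single class: invasion model is not estimable",
         call. = FALSE)
  reduced <- length(unique(data$g)) < 2L && n > 0L
  d <- if (reduced) 2L else 5L
  target <- if (reduced) .make_reduced_target(data, priors)
            else .make_full_target(data, priors)

  init0 <- if (reduced) c(0, 0) else c(0, 0, 0, -1, 0)
  # the MAP can be degenerate (e.g. prior-only fits push sigma_u -> 0);
  # fall back to a prior-scale start when the optimiser fails
  opt <- tryCatch(
    optim(init0, function(th) -target(th), method = "BFGS",
          hessian = TRUE, control = list(maxit = 500)),
    error = function(e) list(par = init0, hessian = NULL))
  fallback <- if (reduced) diag(c(priors$alpha_sd, priors$beta_sd)^2)
              else diag(c(priors$alpha_sd, 1, 1, 0.5, priors$beta_sd)^2)
  cov_full <- if (is.null(opt$hessian)) fallback else
    tryCatch(solve(opt$hessian), error = function(e) fallback)
  if (!all(is.finite(cov_full)) || any(diag(cov_full) <= 0))
    cov_full <- fallback

  draws_by_chain <- vector("list", chains)
  acc <- numeric(chains)
  for (c_i in seq_len(chains)) {
    set.seed(seed * 1000L + c_i)
    if (reduced) {
      init <- .mvrnorm1(opt$par, .safe_chol(cov_full))
      m <- run_chain(target, init, cov_full, warmup = warmup,
                     iter_keep = iter, thin = thin)
    } else {
      init5 <- .mvrnorm1(opt$par, .safe_chol(cov_full))
      cov4 <- cov_full[c(1, 2, 3, 5), c(1, 2, 3, 5)]
      m <- .run_full_chain(data, priors, init4 = init5[c(1, 2, 3, 5)],
                           init_ls = init5[4], cov0 = cov4,
                           warmup = warmup, iter_keep = iter, thin = thin)
    }
    acc[c_i] <- attr(m, "accept_rate")
    draws_by_chain[[c_i]] <- m
  }

  nat <- lapply(draws_by_chain, function(m) {
    if (reduced)
      data.frame(alpha = m[, 1], u_female = 0, u_male = 0,
                 sigma_u = NA_real_, beta = m[, 2])
    else
      data.frame(alpha = m[, 1], u_female = m[, 2], u_male = m[, 3],
                 sigma_u = exp(m[, 4]), beta = m[, 5])
  })
  draws <- do.call(rbind, nat)
  draws$.chain <- rep(seq_len(chains), each = iter)

  pars <- if (reduced) c("alpha", "beta")
          else c("alpha", "u_female", "u_male", "sigma_u", "beta")
  diagnostics <- do.call(rbind, lapply(pars, function(p) {
    m <- sapply(seq_len(chains), function(ci) nat[[ci]][[p]])
    e <- mcmc_ess(m)
    data.frame(parameter = p, r_hat = split_rhat(m),
               ess_bulk = e[["ess_bulk"]], ess_tail = e[["ess_tail"]])
  }))

  structure(list(draws = draws, chains = chains, iter = iter,
                 warmup = warmup, thin = thin, diagnostics = diagnostics,
                 seed = seed, reduced = reduced, accept_rates = acc,
                 priors = priors, n_obs = n),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample:", nrow(x$draws), "draws (", x$chains, "chains x",
      x$iter, "),", if (x$reduced) "reduced (no gender offsets)," else "",
      "n_obs =", x$n_obs, "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Posterior predicted invasion probability
#'
#' @param sample a `posterior_sample`.
#' @param prl prolactin value in ug/L (> 0).
#' @param sex "female" or "male".
#' @return numeric vector: one probability per posterior draw.
#' @export
predict_probability <- function(sample, prl, sex) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (!is.numeric(prl) || prl <= 0) stop("prl must be > 0", call. = FALSE)
  sex <- match.arg(sex, .SEX_LEVELS)
  d <- sample$draws
  u <- if (sex == "female") d$u_female else d$u_male
  plogis(d$alpha + u + d$beta * log10(prl))
}

#' Convergence report
#'
#' @param sample a `posterior_sample` with at least 2 chains.
#' @return the diagnostics data.frame with an overall `pass` attribute:
#'   pass iff max R-hat <= 1.01 and min bulk/tail ESS >= 400.
#' @export
convergence_report <- function(sample) {
  stopifnot(inherits(sample, "posterior_sample"))
  diag <- sample$diagnostics
  if (sample$chains < 2L) {
    diag$r_hat <- NA_real_
    attr(diag, "pass") <- NA
    attr(diag, "note") <- "single chain: R-hat unavailable"
    return(diag)
  }
  ok <- is.finite(diag$r_hat)
  pass <- all(diag$r_hat[ok] <= 1.01) &&
    min(diag$ess_bulk, diag$ess_tail, na.rm = TRUE) >= 400
  attr(diag, "pass") <- pass
  diag
}

#' Export posterior draws to CSV
#'
#' @param sample a `posterior_sample`.
#' @param path output CSV path (one row per draw, columns per parameter).
#' @export
export_draws <- function(sample, path) {
  write.csv(sample$draws, path, row.names = FALSE)
  invisible(path)
}
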