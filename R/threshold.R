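# From posterior to biomarker-scale thresholds, per stratum:
#  1. under a posterior draw, predict each stratum patient's invasion
#     probability;
#  2. find the probability cutoff p* maximising the Kolmogorov-Smirnov
#     distance between the class-conditional empirical CDFs of those
#     probabilities;
#  3. invert p* through that draw's coefficients back to the prolactin scale,
#     T = 10^((logit(p*) - alpha - u_sex) / beta);
#  4. summarise the per-draw thresholds by mode ("most likely estimate"),
#     median and central 95% credible interval.
# Draws with beta <= 0 contradict the model's premise (risk increasing in
# PRL) and are excluded from the inversion with their fraction reported.

#' K-S-optimal probability cutoff
#'
#' Candidates are the sorted unique union of both probability samples. For
#' each candidate c, D(c) = |F0(c) - F1(c)| with F the empirical CDF
#' (proportion <= c); the smallest candidate attaining the maximum D is
#' returned (deterministic tie-break).
#'
#' @param p0 predicted probabilities of the non-invasive class (non-empty).
#' @param p1 predicted probabilities of the invasive class (non-empty).
#' @return list with `p_star`, `ks_distance`, `candidate_count`.
#' @export
ks_optimal_probability_threshold <- function(p0, p1) {
  if (!length(p0) || !length(p1))
    stop("both classes must be non-empty: threshold undefined", call. = FALSE)
  stopifnot(all(p0 >= 0 & p0 <= 1), all(p1 >= 0 & p1 <= 1))
  cand <- sort(unique(c(p0, p1)))
  n0 <- length(p0); n1 <- length(p1)
  # ECDF counts at the candidates; D compared on integers so exact ties
  # break deterministically to the smallest candidate
  c0 <- findInterval(cand, sort(p0))
  c1 <- findInterval(cand, sort(p1))
  Dnum <- abs(c0 * n1 - c1 * n0)
  i <- which.max(Dnum)  # which.max returns the first (smallest) maximiser
  list(p_star = cand[i], ks_distance = Dnum[i] / (n0 * n1),
       candidate_count = length(cand))
}

#' Invert a probability cutoff to the prolactin scale
#'
#' @param p_star probability cutoff in (0,1).
#' @param draw one posterior draw (named list/vector with alpha, u_female,
#'   u_male, beta).
#' @param sex "female", "male", or "population" for a cohort-wide inversion.
#' @param gender_weights for `sex = "population"`: weights `c(female=, male=)`
#'   (typically the stratum's gender counts); the effective offset is the
#'   weighted mean of the two gender offsets.
#' @return threshold in ug/L, or `NA` if `draw$beta <= 0` (callers exclude
#'   and tally such draws).
#' @export
invert_to_prl_threshold <- function(p_star, draw, sex = "population",
                                    gender_weights = c(female = 1, male = 1)) {
  stopifnot(p_star > 0, p_star < 1)
  draw <- as.list(draw)
  if (draw$beta <= 0) return(NA_real_)
  u <- switch(sex,
    female = draw$u_female %||% 0,
    male = draw$u_male %||% 0,
    population = {
      w <- gender_weights[.SEX_LEVELS] / sum(gender_weights[.SEX_LEVELS])
      w[["female"]] * (draw$u_female %||% 0) + w[["male"]] * (draw$u_male %||% 0)
    },
    stop("sex must be female, male or population", call. = FALSE))
  10^((qlogis(p_star) - draw$alpha - u) / draw$beta)
}

#' Summarise a threshold distribution
#'
#' The median and the 2.5th/97.5th percentiles are empirical quantiles. The
#' "most likely estimate" (MLE, the paper's term for the posterior mode) is
#' the argmax of a Gaussian kernel density fitted on the log10 scale
#' (Silverman's bandwidth), mapped back to ug/L: threshold distributions are
#' right-skewed on the natural scale, so mode estimation is done where the
#' distribution is close to symmetric.
#'
#' @param thresholds numeric vector of per-draw thresholds (> 0), length >= 1.
#' @return list with `mle`, `median`, `cri_low`, `cri_high` (ug/L).
#' @export
summarize_threshold <- function(thresholds) {
  t <- thresholds[is.finite(thresholds)]
  stopifnot(length(t) >= 1, all(t > 0))
  q <- quantile(t, c(0.025, 0.5, 0.975), names = FALSE)
  mle <- if (length(unique(t)) == 1L) t[1] else {
    d <- density(log10(t), bw = "nrd0")
    10^(d$x[which.max(d$y)])
  }
  # the KDE argmax lives on a grid slightly wider than the data; clamp to
  # the observed support so the mode invariant holds exactly
  mle <- min(max(mle, min(t)), max(t))
  list(mle = mle, median = q[2], cri_low = q[1], cri_high = q[3])
}

#' Posterior threshold distribution for a stratum
#'
#' By default (`method = "mean_probability"`) a single optimal probability
#' cutoff p* is derived from the posterior-mean predicted probabilities of
#' the stratum's patients and then projected through every posterior draw,
#' yielding one prolactin threshold per draw. The alternative
#' (`method = "per_draw"`) recomputes the K-S step inside the draw loop;
#' note that within a single-gender stratum the predicted probability is a
#' monotone transform of PRL under every draw, so the per-draw variant
#' collapses to the fixed empirical cutpoint (zero-width interval) — it is
#' kept as a cross-check, not as the default.
#'
#' Sex handling at inversion: a single-sex stratum uses that gender's
#' offset; mixed strata use the population offset weighted by the stratum's
#' gender counts.
#'
#' @param sample a `posterior_sample`.
#' @param data a [model_input()] carrying its backing cohort.
#' @param stratum a [subgroup_spec()]; default: all patients.
#' @param method "per_draw" (default) or "mean_probability".
#' @return A `threshold_distribution`: `thresholds` (one per retained draw),
#'   `stratum`, `summaries`, `n_excluded` (beta <= 0 draws), `unreliable`
#'   (TRUE if > 5% of draws excluded), `n_patients`.
#' @export
threshold_distribution <- function(sample, data, stratum = subgroup_spec("all"),
                                   method = c("mean_probability", "per_draw")) {
  stopifnot(inherits(sample, "posterior_sample"), inherits(data, "model_input"))
  method <- match.arg(method)
  cohort <- attr(data, "cohort")
  if (is.null(cohort)) stop("model_input lacks its backing cohort", call. = FALSE)
  sub <- apply_subgroup(cohort, stratum)
  x <- log10(sub$prl); y <- sub$invasion; g <- sub$sex
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("stratum '", stratum$name, "' needs >= 2 members of each invasion class",
         call. = FALSE)

  d <- sample$draws
  ndraw <- nrow(d)
  g_male <- g == "male"
  np <- length(g)
  u_mat <- matrix(d$u_female, ndraw, np)
  if (any(g_male)) u_mat[, g_male] <- d$u_male
  # eta: draws x patients
  eta <- matrix(d$alpha, ndraw, np) + u_mat + outer(d$beta, x)
  p <- plogis(eta)

  sex_for_inv <- if (stratum$sex %in% .SEX_LEVELS) stratum$sex else "population"
  wts <- c(female = sum(!g_male), male = sum(g_male))

  thresholds <- rep(NA_real_, ndraw)
  if (method == "per_draw") {
    for (k in seq_len(ndraw)) {
      if (d$beta[k] <= 0) next
      ks <- ks_optimal_probability_threshold(p[k, y == 0], p[k, y == 1])
      p_star <- ks$p_star
      if (p_star <= 0 || p_star >= 1) p_star <- min(max(p_star, 1e-12), 1 - 1e-12)
      thresholds[k] <- invert_to_prl_threshold(p_star, d[k, ], sex_for_inv, wts)
    }
  } else {
    pbar <- colMeans(p)
    ks <- ks_optimal_probability_threshold(pbar[y == 0], pbar[y == 1])
    for (k in seq_len(ndraw)) {
      if (d$beta[k] <= 0) next
      thresholds[k] <- invert_to_prl_threshold(ks$p_star, d[k, ], sex_for_inv, wts)
    }
  }
  n_excl <- sum(is.na(thresholds))
  kept <- thresholds[!is.na(thresholds)]
  if (!length(kept))
    stop("no draws retained (all beta <= 0) in stratum '", stratum$name, "'",
         call. = FALSE)
  structure(list(thresholds = kept, draw_thresholds = thresholds,
                 stratum = stratum,
                 summaries = summarize_threshold(kept),
                 n_excluded = n_excl,
                 unreliable = n_excl / ndraw > 0.05,
                 n_patients = length(y), method = method),
            class = "threshold_distribution")
}

#' @export
print.threshold_distribution <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("threshold_distribution [%s]: MLE %.1f, median %.1f, 95%% CrI %.1f-%.1f ug/L\n",
              x$stratum$name, s$mle, s$median, s$cri_low, s$cri_high))
  cat(sprintf("  %d draws (%d excluded, beta<=0)%s, %d patients, %s\n",
              length(x$thresholds), x$n_excluded,
              if (x$unreliable) " [UNRELIABLE: >5% excluded]" else "",
              x$n_patients, x$method))
  invisible(x)
}

#' Threshold table across strata
#'
#' Computes [threshold_distribution()] for every stratum, skipping strata
#' that are not estimable (fewer than 2 members of either class) with a
#' flag instead of an error.
#'
#' @param sample a `posterior_sample`.
#' @param data a [model_input()].
#' @param strata list of [subgroup_spec()]s (default [table2_subgroups()]).
#' @param method passed to [threshold_distribution()].
#' @return data.frame: stratum, n, mle, median, cri_low, cri_high,
#'   excluded_draws, unreliable, estimable.
#' @export
threshold_table <- function(sample, data, strata = table2_subgroups(),
                            method = "mean_probability") {
  rows <- lapply(strata, function(sp) {
    td <- tryCatch(threshold_distribution(sample, data, sp, method),
                   error = function(e) NULL)
    if (is.null(td))
      return(data.frame(stratum = sp$name, n = NA_integer_, mle = NA_real_,
                        median = NA_real_, cri_low = NA_real_,
                        cri_high = NA_real_, excluded_draws = NA_integer_,
                        unreliable = NA, estimable = FALSE))
    s <- td$summaries
    data.frame(stratum = sp$name, n = td$n_patients, mle = s$mle,
               median = s$median, cri_low = s$cri_low, cri_high = s$cri_high,
               excluded_draws = td$n_excluded, unreliable = td$unreliable,
               estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
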