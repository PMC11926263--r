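# Threshold evaluation: exact confusion counts at a cutoff (positivity rule
# prl >= t), posterior-propagated sensitivity/specificity/PPV/NPV per
# stratum, and AUROC on raw prolactin with a class-stratified bootstrap
# interval. Within one gender the model probability is a strictly monotone
# transform of PRL, so AUROC on raw PRL coincides with AUROC on the model
# score; for mixed strata raw PRL is the quantity whose discriminatory
# capacity is being measured.

#' Confusion counts and metrics at a fixed threshold
#'
#' @param prl prolactin values in ug/L.
#' @param y invasion labels in {0,1}.
#' @param t threshold in ug/L; positive iff `prl >= t`.
#' @return list with integer `tp`, `fp`, `tn`, `fn` and `sensitivity`,
#'   `specificity`, `ppv`, `npv`; ratios with zero denominator are `NA`
#'   (reported missing, never coerced to 0).
#' @export
confusion_at_threshold <- function(prl, y, t) {
  stopifnot(length(prl) == length(y), all(y %in% c(0, 1)), length(t) == 1)
  pos <- prl >= t
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn))
}

#' AUROC as pairwise concordance
#'
#' Probability that a random invasive patient outscores a random
#' non-invasive one, ties counted half — the normalised Mann-Whitney U,
#' computed from rank sums.
#'
#' @param scores numeric scores (e.g. raw prolactin).
#' @param y labels in {0,1}; both classes required.
#' @return AUROC in [0,1].
#' @export
auroc <- function(scores, y) {
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as half-concordant
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap uncertainty for AUROC
#'
#' Class-stratified patient bootstrap of [auroc()] on raw prolactin.
#' Labelled a bootstrap interval in all outputs.
#'
#' @param prl,y as in [auroc()].
#' @param replicates >= 100.
#' @param seed integer seed.
#' @return list with `mean`, `ci_low`, `ci_high` (2.5th/97.5th percentiles).
#' @export
auroc_uncertainty <- function(prl, y, replicates = 1000L, seed) {
  stopifnot(replicates >= 100)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  i0 <- which(y == 0); i1 <- which(y == 1)
  if (!length(i0) || !length(i1))
    stop("both classes required for AUROC", call. = FALSE)
  set.seed(seed)
  a <- numeric(replicates)
  for (r in seq_len(replicates)) {
    idx <- c(sample(i0, length(i0), replace = TRUE),
             sample(i1, length(i1), replace = TRUE))
    a[r] <- auroc(prl[idx], y[idx])
  }
  q <- quantile(a, c(0.025, 0.975), names = FALSE)
  list(mean = mean(a), ci_low = q[1], ci_high = q[2])
}

#' Posterior-propagated classification metrics for a stratum
#'
#' For every posterior draw, the draw's prolactin threshold is derived with
#' the chosen source (`"global"`: K-S threshold from all patients;
#' `"subgroup_specific"`: from the stratum's own patients; `"fixed_value"`:
#' an externally supplied cutoff, identical across draws) and the stratum's
#' observed data are classified at it. Metrics are summarised by their mean
#' and central 95% interval over draws; draws where PPV or NPV is undefined
#' are excluded from that metric's summary with the count reported.
#'
#' @param sample a `posterior_sample`.
#' @param data a [model_input()] with backing cohort.
#' @param stratum a [subgroup_spec()].
#' @param source "global", "subgroup_specific" or "fixed_value".
#' @param fixed threshold in ug/L when `source = "fixed_value"`.
#' @param method K-S method passed to [threshold_distribution()].
#' @return A `performance_summary`: per-metric `point` (mean), `interval`,
#'   per-draw `distributions`, `auroc` (bootstrap, seeded from the sample's
#'   seed), `n_undefined` per metric.
#' @export
posterior_metric_distribution <- function(sample, data, stratum,
                                          source = c("global",
                                                     "subgroup_specific",
                                                     "fixed_value"),
                                          fixed = NULL,
                                          method = "mean_probability") {
  source <- match.arg(source)
  cohort <- attr(data, "cohort")
  sub <- apply_subgroup(cohort, stratum)
  if (length(unique(sub$invasion)) < 2L)
    stop("stratum '", stratum$name, "' is degenerate (single class)",
         call. = FALSE)

  ndraw <- nrow(sample$draws)
  thresholds <- switch(source,
    fixed_value = {
      if (is.null(fixed)) stop("fixed threshold required", call. = FALSE)
      rep(fixed, ndraw)
    },
    global = threshold_distribution(sample, data, subgroup_spec("all"),
                                    method)$draw_thresholds,
    subgroup_specific = threshold_distribution(sample, data, stratum,
                                               method)$draw_thresholds)

  mets <- c("sensitivity", "specificity", "ppv", "npv")
  dist <- matrix(NA_real_, ndraw, length(mets), dimnames = list(NULL, mets))
  for (k in seq_len(ndraw)) {
    if (is.na(thresholds[k])) next
    cf <- confusion_at_threshold(sub$prl, sub$invasion, thresholds[k])
    dist[k, ] <- unlist(cf[mets])
  }
  point <- colMeans(dist, na.rm = TRUE)
  interval <- apply(dist, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
                    names = FALSE)
  n_undef <- colSums(is.na(dist))
  au <- auroc_uncertainty(sub$prl, sub$invasion, replicates = 1000L,
                          seed = sample$seed + 101L)
  structure(list(stratum = stratum, threshold_source = source,
                 point = point, interval = interval, distributions = dist,
                 auroc = au, n_undefined = n_undef,
                 n_patients = nrow(sub)),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("performance_summary [%s, %s threshold], n = %d\n",
              x$stratum$name, x$threshold_source, x$n_patients))
  for (m in colnames(x$distributions))
    cat(sprintf("  %-12s %.3f (95%% CrI %.3f-%.3f)%s\n", m, x$point[m],
                x$interval[1, m], x$interval[2, m],
                if (x$n_undefined[m] > 0)
                  sprintf(" [%d undefined draws]", x$n_undefined[m]) else ""))
  cat(sprintf("  AUROC (bootstrap) %.3f (%.3f-%.3f)\n", x$auroc$mean,
              x$auroc$ci_low, x$auroc$ci_high))
  invisible(x)
}

#' AUROC table across strata
#'
#' @param cohort complete-case `cohort_table`.
#' @param strata list of [subgroup_spec()]s.
#' @param replicates,seed passed to [auroc_uncertainty()].
#' @return data.frame: stratum, n, auroc_mean, ci_low, ci_high, estimable.
#' @export
auroc_table <- function(cohort, strata = table2_subgroups(),
                        replicates = 1000L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  rows <- lapply(seq_along(strata), function(i) {
    sp <- strata[[i]]
    sub <- apply_subgroup(cohort, sp)
    res <- tryCatch(
      auroc_uncertainty(sub$prl, sub$invasion, replicates, seed + i),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(stratum = sp$name, n = nrow(sub),
                        auroc_mean = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, estimable = FALSE))
    data.frame(stratum = sp$name, n = nrow(sub), auroc_mean = res$mean,
               ci_low = res$ci_low, ci_high = res$ci_high, estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
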