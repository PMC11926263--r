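# Classical cutpoint baseline: Youden's J = sensitivity + specificity - 1,
# maximised over the observed prolactin values with the positivity rule
# prl >= c (high prolactin indicates invasion). Uncertainty by a
# 1000-member patient bootstrap, class-stratified by default so small
# strata cannot produce single-class resamples.

#' Youden-optimal prolactin cutpoint
#'
#' @param prl prolactin values in ug/L (> 0).
#' @param y invasion labels in {0,1}; both classes must be present.
#' @return list with `threshold` (the smallest observed value attaining the
#'   maximal J) and `j_statistic`.
#' @export
youden_threshold <- function(prl, y) {
  stopifnot(length(prl) == length(y), all(prl > 0), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("both classes required for the Youden index", call. = FALSE)
  cand <- sort(unique(prl))
  p1 <- sort(prl[y == 1]); p0 <- sort(prl[y == 0])
  n1 <- length(p1); n0 <- length(p0)
  # positive iff prl >= c: sens(c) = P1(prl >= c), spec(c) = P0(prl < c)
  sens <- 1 - findInterval(cand, p1, left.open = TRUE) / n1
  spec <- findInterval(cand, p0, left.open = TRUE) / n0
  J <- sens + spec - 1
  i <- which.max(J)
  list(threshold = cand[i], j_statistic = J[i])
}

#' Bootstrap distribution of the Youden cutpoint
#'
#' @param prl,y as in [youden_threshold()].
#' @param replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param stratified resample within each class (default TRUE); plain
#'   resampling redraws single-class replicates (tallied).
#' @return A `youden_result`: point `threshold` and `j_statistic` on the
#'   observed data, `bootstrap_thresholds`, `median`, `ci_low`, `ci_high`
#'   (2.5th/97.5th percentiles), `replicates`, `seed`, `redrawn`.
#' @export
bootstrap_youden <- function(prl, y, replicates = 1000L, seed,
                             stratified = TRUE) {
  stopifnot(replicates >= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  point <- youden_threshold(prl, y)
  i0 <- which(y == 0); i1 <- which(y == 1)
  set.seed(seed)
  bt <- numeric(replicates)
  redrawn <- 0L
  for (r in seq_len(replicates)) {
    repeat {
      idx <- if (stratified)
        c(sample(i0, length(i0), replace = TRUE),
          sample(i1, length(i1), replace = TRUE))
      else sample(seq_along(y), length(y), replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redrawn <- redrawn + 1L
    }
    bt[r] <- youden_threshold(prl[idx], y[idx])$threshold
  }
  q <- quantile(bt, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(threshold = point$threshold, j_statistic = point$j_statistic,
                 bootstrap_thresholds = bt, median = q[2], ci_low = q[1],
                 ci_high = q[3], replicates = replicates, seed = seed,
                 stratified = stratified, redrawn = redrawn),
            class = "youden_result")
}

#' @export
print.youden_result <- function(x, ...) {
  cat(sprintf("youden_result: threshold %.1f ug/L (J = %.3f); bootstrap median %.1f, 95%% CI %.1f-%.1f (%d replicates%s)\n",
              x$threshold, x$j_statistic, x$median, x$ci_low, x$ci_high,
              x$replicates, if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Youden cutpoints across strata
#'
#' @param cohort complete-case `cohort_table`.
#' @param strata list of [subgroup_spec()]s.
#' @param replicates,seed,stratified passed to [bootstrap_youden()].
#' @return data.frame: stratum, n, threshold, j, boot_median, ci_low,
#'   ci_high, estimable.
#' @export
youden_table <- function(cohort, strata = table2_subgroups(),
                         replicates = 1000L, seed, stratified = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  rows <- lapply(seq_along(strata), function(i) {
    sp <- strata[[i]]
    sub <- apply_subgroup(cohort, sp)
    res <- tryCatch(
      bootstrap_youden(sub$prl, sub$invasion, replicates, seed + i, stratified),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(stratum = sp$name, n = nrow(sub), threshold = NA_real_,
                        j = NA_real_, boot_median = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, estimable = FALSE))
    data.frame(stratum = sp$name, n = nrow(sub), threshold = res$threshold,
               j = res$j_statistic, boot_median = res$median,
               ci_low = res$ci_low, ci_high = res$ci_high, estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
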