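# Synthetic cohorts share the causal structure the inference model assumes:
# sex ~ Bernoulli, log10(PRL) ~ Normal per sex, invasion ~ Bernoulli through
# the logistic link on alpha + u_sex + beta*log10(PRL). Age and BMI are
# independent covariates used only for subgroup stratification.

#' Generator parameters for a synthetic cohort
#'
#' @param n cohort size.
#' @param p_female probability a patient is female.
#' @param prl_logmu named vector `c(female=, male=)`: mean of log10 PRL.
#' @param prl_logsd named vector: SD of log10 PRL per sex, > 0.
#' @param alpha invasion-model intercept, logit scale.
#' @param u named vector: per-gender offsets, logit scale.
#' @param beta slope per unit log10 PRL, logit scale.
#' @param age_dist `c(mean, sd)` of age in years, truncated at 18.
#' @param bmi_dist `c(mean, sd)` of BMI in kg/m2, truncated at 14.
#' @param missing_rate_prl fraction of PRL values blanked at random, in [0,1).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n, p_female, prl_logmu, prl_logsd, alpha, u, beta,
                             age_dist = c(38, 14), bmi_dist = c(26.5, 5),
                             missing_rate_prl = 0, seed = 1L) {
  stopifnot(n >= 1, p_female >= 0, p_female <= 1,
            all(prl_logsd > 0), missing_rate_prl >= 0, missing_rate_prl < 1,
            all(.SEX_LEVELS %in% names(prl_logmu)),
            all(.SEX_LEVELS %in% names(prl_logsd)),
            all(.SEX_LEVELS %in% names(u)),
            age_dist[2] > 0, bmi_dist[2] > 0)
  structure(list(n = as.integer(n), p_female = p_female,
                 prl_logmu = prl_logmu[.SEX_LEVELS],
                 prl_logsd = prl_logsd[.SEX_LEVELS],
                 alpha = alpha, u = u[.SEX_LEVELS], beta = beta,
                 age_dist = age_dist, bmi_dist = bmi_dist,
                 missing_rate_prl = missing_rate_prl,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Default parameters calibrated to the published cohort summaries
#'
#' The defaults reproduce, in expectation, the published marginal structure:
#' female fraction 106/149 (71.1%), invasion prevalence 37.6% (19.8% in
#' females, 81.4% in males), class-conditional PRL medians of 126 ug/L
#' (non-invasive) and 1510 ug/L (invasive), and a male optimal threshold well
#' above the female one. The numeric values were obtained once by solving
#' those four moment conditions by numerical integration with beta = 2 and
#' per-sex log10-PRL SDs of 0.55 (female) and 0.65 (male) held fixed; they
#' are frozen here, not re-tuned.
#'
#' @param n cohort size (default 149, the published cohort).
#' @param seed integer seed.
#' @param missing_rate_prl default 18/149, so the canonical fixture loses 18
#'   PRL values and the complete-case step reproduces 149 -> 131.
#' @return A `generator_params` object; two calls with equal arguments are
#'   identical.
#' @export
default_paper_params <- function(n = 149L, seed = 1L,
                                 missing_rate_prl = 18 / 149) {
  generator_params(
    n = n, p_female = 106 / 149,
    prl_logmu = c(female = 2.1442, male = 3.4413),
    prl_logsd = c(female = 0.55, male = 0.65),
    alpha = -5.4843, u = c(female = -0.5163, male = 0.5163), beta = 2,
    age_dist = c(38, 14), bmi_dist = c(26.5, 5),
    missing_rate_prl = missing_rate_prl, seed = seed)
}

# Deterministic per-record sub-seed: record i of a run seeded s always gets
# the same draws, so growing n extends a cohort instead of reshuffling it.
.record_seed <- function(seed, i) {
  (48271 * (seed %% 44488) + i) %% 2147483647L
}

.rtruncnorm1 <- function(mean, sd, lower) {
  for (k in 1:100) {
    v <- rnorm(1, mean, sd)
    if (v > lower) return(v)
  }
  lower + abs(rnorm(1, 0, sd)) # extreme parameterisations: fold instead
}

#' Generate a synthetic cohort
#'
#' @param params a [generator_params()] object.
#' @return A [cohort_table()]; bit-identical for equal params.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n
  sex <- character(n); prl <- numeric(n); inv <- integer(n)
  age <- numeric(n); bmi <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.record_seed(params$seed, i))
    s <- if (runif(1) < params$p_female) "female" else "male"
    x <- rnorm(1, params$prl_logmu[[s]], params$prl_logsd[[s]])
    eta <- params$alpha + params$u[[s]] + params$beta * x
    sex[i] <- s
    prl[i] <- 10^x
    inv[i] <- as.integer(runif(1) < plogis(eta))
    age[i] <- .rtruncnorm1(params$age_dist[1], params$age_dist[2], 18)
    bmi[i] <- .rtruncnorm1(params$bmi_dist[1], params$bmi_dist[2], 14)
  }
  if (params$missing_rate_prl > 0) {
    n_blank <- round(params$missing_rate_prl * n)
    set.seed(.record_seed(params$seed, 0L) + 7777L)
    prl[sample.int(n, n_blank)] <- NA_real_
  }
  cohort_table(
    data.frame(patient_id = sprintf("S%04d", seq_len(n)), sex = sex,
               age = age, bmi = bmi, prl = prl, invasion = inv,
               treatment = NA_character_, stringsAsFactors = FALSE),
    provenance = sprintf("synthetic(seed=%d, n=%d)", params$seed, n))
}

#' Check a synthetic cohort against the published summary targets
#'
#' Compares realised frequencies and stratified PRL medians with the printed
#' targets. Tolerances are deliberately loose (relative 20% on medians): the
#' generator's job is to reproduce the structure of the cohort, not its
#' exact quantiles.
#'
#' @param cohort a `cohort_table` with at least 100 records.
#' @param tolerances named list of tolerances; an empty list yields a report
#'   with no verdicts (with a warning).
#' @return data.frame (class `calibration_report`) with columns statistic,
#'   target, realized, tolerance, pass.
#' @export
calibration_check <- function(cohort,
                              tolerances = list(
                                female_fraction = 0.05,
                                invasion_prevalence = 0.05,
                                prl_median_noninvasive_rel = 0.20,
                                prl_median_invasive_rel = 0.20,
                                prl_median_female_rel = 0.25,
                                prl_median_male_rel = 0.25)) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) < 100L) stop("need >= 100 records for calibration")
  cc <- complete_case_filter(cohort, c("prl", "invasion"))
  realized <- list(
    female_fraction = mean(cohort$sex == "female"),
    invasion_prevalence = mean(cohort$invasion, na.rm = TRUE),
    prl_median_noninvasive_rel = median(cc$prl[cc$invasion == 0]),
    prl_median_invasive_rel = median(cc$prl[cc$invasion == 1]),
    prl_median_female_rel = median(cc$prl[cc$sex == "female"]),
    prl_median_male_rel = median(cc$prl[cc$sex == "male"]))
  # marginal per-sex medians implied by the default log-normal components
  targets <- list(female_fraction = 106 / 149, invasion_prevalence = 0.376,
                  prl_median_noninvasive_rel = 126,
                  prl_median_invasive_rel = 1510,
                  prl_median_female_rel = 10^2.1442,
                  prl_median_male_rel = 10^3.4413)
  if (length(tolerances) == 0L) {
    warning("empty tolerance map: report carries no verdicts", call. = FALSE)
    out <- data.frame(statistic = names(targets),
                      target = unlist(targets),
                      realized = unlist(realized[names(targets)]),
                      tolerance = NA_real_, pass = NA)
  } else {
    keep <- intersect(names(tolerances), names(targets))
    out <- do.call(rbind, lapply(keep, function(s) {
      tg <- targets[[s]]; rl <- realized[[s]]; tol <- tolerances[[s]]
      rel <- grepl("_rel$", s)
      pass <- if (rel) abs(rl - tg) / tg <= tol else abs(rl - tg) <= tol
      data.frame(statistic = s, target = tg, realized = rl,
                 tolerance = tol, pass = pass)
    }))
  }
  class(out) <- c("calibration_report", "data.frame")
  out
}
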