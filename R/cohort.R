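#' @importFrom stats chisq.test wilcox.test median quantile rnorm
#'   runif density dnorm plogis qlogis optim sd var acf setNames
#' @importFrom utils read.csv write.csv
NULL

.SEX_LEVELS <- c("female", "male")
.TREATMENT_LEVELS <- c("surgery", "medical")
.COHORT_FIELDS <- c("patient_id", "sex", "age", "bmi", "prl", "invasion",
                    "treatment")

#' Construct and validate a cohort table
#'
#' A cohort table is the observational unit of the package: one row per
#' patient with sex, age (years), BMI (kg/m2), serum prolactin (PRL, ug/L)
#' and the binary cavernous-sinus-invasion outcome. Missing values are kept
#' as `NA` and never imputed; sex must always be observed because the
#' regression model carries a per-gender offset.
#'
#' @param df data.frame with (a subset of) columns `patient_id`, `sex`,
#'   `age`, `bmi`, `prl`, `invasion`, `treatment`.
#' @param provenance character scalar recording where the rows came from
#'   (a file path or a generator seed description).
#' @return A `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(df, provenance = "unknown") {
  stopifnot(is.data.frame(df))
  out <- data.frame(
    patient_id = as.character(if (is.null(df$patient_id)) seq_len(nrow(df)) else df$patient_id),
    sex        = as.character(df$sex),
    age        = if (is.null(df$age)) NA_real_ else as.numeric(df$age),
    bmi        = if (is.null(df$bmi)) NA_real_ else as.numeric(df$bmi),
    prl        = if (is.null(df$prl)) NA_real_ else as.numeric(df$prl),
    invasion   = if (is.null(df$invasion)) NA_integer_ else as.integer(df$invasion),
    treatment  = if (is.null(df$treatment)) NA_character_ else as.character(df$treatment),
    stringsAsFactors = FALSE
  )
  .validate_cohort(out)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

.validate_cohort <- function(df) {
  bad_sex <- which(is.na(df$sex) | !(df$sex %in% .SEX_LEVELS))
  if (length(bad_sex))
    stop("row ", bad_sex[1], ": sex must be one of ",
         paste(.SEX_LEVELS, collapse = "/"), " and never missing", call. = FALSE)
  bad_prl <- which(!is.na(df$prl) & df$prl <= 0)
  if (length(bad_prl))
    stop("row ", bad_prl[1], ": prl must be > 0 (log10 must be defined), got ",
         df$prl[bad_prl[1]], call. = FALSE)
  bad_inv <- which(!is.na(df$invasion) & !(df$invasion %in% c(0L, 1L)))
  if (length(bad_inv))
    stop("row ", bad_inv[1], ": invasion must be 0 or 1, got ",
         df$invasion[bad_inv[1]], call. = FALSE)
  bad_trt <- which(!is.na(df$treatment) & !(df$treatment %in% .TREATMENT_LEVELS))
  if (length(bad_trt))
    stop("row ", bad_trt[1], ": treatment must be one of ",
         paste(.TREATMENT_LEVELS, collapse = "/"), call. = FALSE)
  for (f in c("age", "bmi")) {
    bad <- which(!is.na(df[[f]]) & df[[f]] <= 0)
    if (length(bad))
      stop("row ", bad[1], ": ", f, " must be positive when present", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x), "patients (",
      sum(x$sex == "female"), "female,", sum(x$sex == "male"), "male )\n")
  cat("  provenance:", attr(x, "provenance"), "\n")
  cat("  complete cases (prl + invasion):",
      sum(!is.na(x$prl) & !is.na(x$invasion)), "\n")
  invisible(x)
}

#' Read a cohort CSV
#'
#' Reads a patient-level CSV into a validated [cohort_table()]. Arbitrary
#' clinical exports are adapted through `mapping`, which renames source
#' columns onto the canonical fields. Empty cells and the literal "NA" are
#' both treated as missing; missing values are preserved, never imputed.
#' PRL is expected in ug/L.
#'
#' @param path CSV file with a header row.
#' @param mapping named character vector or list `canonical_field = source_column`;
#'   fields absent from the mapping are looked up by their canonical name.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  colClasses = "character")
  if (!is.null(mapping)) {
    mapping <- unlist(mapping)
    unknown <- setdiff(names(mapping), .COHORT_FIELDS)
    if (length(unknown))
      stop("mapping targets unknown fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src))
      stop("mapped source columns absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    for (f in names(mapping)) raw[[f]] <- raw[[mapping[[f]]]]
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  df$patient_id <- if (is.null(raw$patient_id)) as.character(seq_len(nrow(raw))) else raw$patient_id
  df$sex <- raw$sex
  for (f in c("age", "bmi", "prl", "invasion")) {
    if (is.null(raw[[f]])) { df[[f]] <- NA; next }
    v <- raw[[f]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("row ", bad[1], ": malformed numeric value '", v[bad[1]],
           "' in column ", f, call. = FALSE)
    df[[f]] <- num
  }
  df$treatment <- if (is.null(raw$treatment)) NA_character_ else raw$treatment
  cohort_table(df, provenance = path)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: well-formed files round-trip field-identically.
#'
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  write.csv(as.data.frame(cohort)[, .COHORT_FIELDS], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' Complete-case filter
#'
#' Restricts the cohort to records where every `required` field is observed,
#' preserving row order. The analysis cohort is the complete-case subset on
#' `prl` and `invasion`; nothing is imputed.
#'
#' @param cohort a `cohort_table`.
#' @param required character vector of field names that must be non-missing.
#' @return The filtered `cohort_table`.
#' @export
complete_case_filter <- function(cohort, required = c("prl", "invasion")) {
  stopifnot(inherits(cohort, "cohort_table"))
  bad <- setdiff(required, .COHORT_FIELDS)
  if (length(bad)) stop("unknown required fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(required) == 0L) return(cohort)
  keep <- Reduce(`&`, lapply(required, function(f) !is.na(cohort[[f]])))
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("complete-case filter removed every record", call. = FALSE)
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  out
}

#' Define a subgroup
#'
#' A subgroup is a conjunction of a sex filter, an age filter and a BMI
#' filter. Boundary convention: `over50` means age >= 50 years and `over30`
#' means BMI >= 30 kg/m2 (equality lands in the upper category). Records
#' missing a filtered field are excluded, not errored.
#'
#' @param name label for reporting.
#' @param sex one of "any", "female", "male".
#' @param age one of "any", "under50", "over50".
#' @param bmi one of "any", "under30", "over30".
#' @return A `subgroup_spec`.
#' @export
subgroup_spec <- function(name, sex = "any", age = "any", bmi = "any") {
  sex <- match.arg(sex, c("any", .SEX_LEVELS))
  age <- match.arg(age, c("any", "under50", "over50"))
  bmi <- match.arg(bmi, c("any", "under30", "over30"))
  structure(list(name = name, sex = sex, age = age, bmi = bmi),
            class = "subgroup_spec")
}

#' @export
print.subgroup_spec <- function(x, ...) {
  cat("subgroup_spec:", x$name, sprintf("(sex=%s, age=%s, bmi=%s)\n",
                                        x$sex, x$age, x$bmi))
  invisible(x)
}

#' The 15 reporting strata
#'
#' Three gender levels (all/female/male) crossed with the five row labels
#' (all, age < 50, age >= 50, BMI < 30, BMI >= 30).
#'
#' @return A named list of 15 [subgroup_spec()] objects.
#' @export
table2_subgroups <- function() {
  rows <- list(all = c("any", "any"), age_under50 = c("under50", "any"),
               age_over50 = c("over50", "any"), bmi_under30 = c("any", "under30"),
               bmi_over30 = c("any", "over30"))
  out <- list()
  for (s in c("any", .SEX_LEVELS)) {
    slab <- if (s == "any") "all" else s
    for (r in names(rows)) {
      nm <- paste(slab, r, sep = "_")
      out[[nm]] <- subgroup_spec(nm, sex = s, age = rows[[r]][1],
                                 bmi = rows[[r]][2])
    }
  }
  out
}

#' Apply a subgroup specification
#'
#' @param cohort a `cohort_table`.
#' @param spec a [subgroup_spec()].
#' @return The filtered `cohort_table`.
#' @export
apply_subgroup <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "subgroup_spec"))
  keep <- rep(TRUE, nrow(cohort))
  if (spec$sex != "any") keep <- keep & cohort$sex == spec$sex
  if (spec$age != "any") {
    keep <- keep & !is.na(cohort$age) &
      if (spec$age == "under50") cohort$age < 50 else cohort$age >= 50
  }
  if (spec$bmi != "any") {
    keep <- keep & !is.na(cohort$bmi) &
      if (spec$bmi == "under30") cohort$bmi < 30 else cohort$bmi >= 30
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  out
}

#' Exploratory descriptive statistics by group
#'
#' Summarises every variable against a binary grouping field: counts and
#' frequencies with a chi-square test for categoricals, median and IQR with
#' an unpaired two-sample Wilcoxon rank-sum test for numerics. P-values are
#' unadjusted and the table is flagged exploratory: they are never used for
#' inference downstream. Each row reports its own available-case N.
#'
#' @param cohort a `cohort_table`.
#' @param group_by binary field to split on (default `"invasion"`).
#' @return data.frame with one row per variable (class `descriptive_table`).
#' @export
descriptive_table <- function(cohort, group_by = "invasion") {
  stopifnot(inherits(cohort, "cohort_table"))
  g <- cohort[[group_by]]
  if (is.null(g)) stop("unknown group_by field: ", group_by, call. = FALSE)
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2L)
    stop("group_by must have exactly two observed levels", call. = FALSE)
  if (any(table(g) < 2L))
    stop("each group level needs >= 2 records", call. = FALSE)

  vars <- setdiff(.COHORT_FIELDS, c("patient_id", group_by))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    ok <- !is.na(x) & !is.na(g)
    n_avail <- sum(ok)
    if (n_avail == 0L)
      return(data.frame(variable = v, type = "unavailable", n = 0L,
                        all = NA_character_, group0 = NA_character_,
                        group1 = NA_character_, p_value = NA_real_,
                        note = "no available cases"))
    if (v %in% c("sex", "treatment", "invasion")) {
      ref <- if (v == "sex") "female" else if (v == "treatment") "surgery" else 1L
      hit <- x[ok] == ref
      fmt <- function(idx) sprintf("%d (%.1f%%)", sum(hit[idx]),
                                   100 * mean(hit[idx]))
      tab <- table(factor(hit, c(FALSE, TRUE)), factor(g[ok], lev))
      p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value) else NA_real_
      data.frame(variable = paste0(v, "=", ref), type = "categorical",
                 n = n_avail, all = fmt(rep(TRUE, n_avail)),
                 group0 = fmt(g[ok] == lev[1]), group1 = fmt(g[ok] == lev[2]),
                 p_value = p, note = "chi-square, exploratory")
    } else {
      fmt <- function(z) sprintf("%.1f [%.1f-%.1f]", median(z),
                                 quantile(z, .25), quantile(z, .75))
      x0 <- x[ok & g == lev[1]]; x1 <- x[ok & g == lev[2]]
      p <- if (length(x0) && length(x1))
        suppressWarnings(wilcox.test(x0, x1)$p.value) else NA_real_
      data.frame(variable = v, type = "numeric", n = n_avail,
                 all = fmt(x[ok]), group0 = if (length(x0)) fmt(x0) else NA,
                 group1 = if (length(x1)) fmt(x1) else NA,
                 p_value = p, note = "Wilcoxon rank-sum, exploratory")
    }
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group0"] <- paste0(group_by, "=", lev[1])
  names(out)[names(out) == "group1"] <- paste0(group_by, "=", lev[2])
  attr(out, "exploratory") <- TRUE
  class(out) <- c("descriptive_table", "data.frame")
  out
}
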