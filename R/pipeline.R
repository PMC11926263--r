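# End-to-end orchestration: ingest -> complete-case -> fit -> thresholds ->
# Youden baseline -> evaluation -> report, driven by a single serialisable
# config with explicit seeds everywhere. Outputs are deterministic given the
# config; the only timestamp lives in the manifest.

#' Build a run configuration
#'
#' @param input path to a cohort CSV, or `NULL` to use `generator`.
#' @param generator a [generator_params()] object (used when `input` is NULL).
#' @param mapping column mapping passed to [read_cohort()].
#' @param mcmc list: chains, iter, warmup, thin, seed.
#' @param thresholds list: method ("per_draw"/"mean_probability").
#' @param bootstrap list: replicates, seed, stratified.
#' @param outdir output directory.
#' @return A validated `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, mapping = NULL,
                       mcmc = list(chains = 4L, iter = 1000L, warmup = 1000L,
                                   thin = 5L, seed = NULL),
                       thresholds = list(method = "mean_probability"),
                       bootstrap = list(replicates = 1000L, seed = NULL,
                                        stratified = TRUE),
                       outdir = "prlthresh_run") {
  if (is.null(input) && is.null(generator))
    stop("config needs an input path or generator params", call. = FALSE)
  if (is.null(mcmc$seed) || is.null(bootstrap$seed))
    stop("all seeds must be explicit in the config", call. = FALSE)
  structure(list(input = input, generator = generator, mapping = mapping,
                 mcmc = mcmc, thresholds = thresholds, bootstrap = bootstrap,
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file as written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- if (!is.null(j$generator))
    generator_params(n = j$generator$n, p_female = j$generator$p_female,
                     prl_logmu = unlist(j$generator$prl_logmu),
                     prl_logsd = unlist(j$generator$prl_logsd),
                     alpha = j$generator$alpha, u = unlist(j$generator$u),
                     beta = j$generator$beta,
                     age_dist = unlist(j$generator$age_dist),
                     bmi_dist = unlist(j$generator$bmi_dist),
                     missing_rate_prl = j$generator$missing_rate_prl,
                     seed = j$generator$seed)
  run_config(input = j$input, generator = gen, mapping = j$mapping,
             mcmc = j$mcmc, thresholds = j$thresholds,
             bootstrap = j$bootstrap, outdir = j$outdir %||% "prlthresh_run")
}

#' Write a run configuration to JSON
#'
#' Configs round-trip through serialisation unchanged.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(.config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# strip S3 classes (run_config, generator_params) for JSON serialisation
.config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$generator)) {
    g <- unclass(out$generator)
    g$prl_logmu <- as.list(g$prl_logmu)
    g$prl_logsd <- as.list(g$prl_logsd)
    g$u <- as.list(g$u)
    out$generator <- g
  }
  out
}

.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 6))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: ingest (or simulate), complete-case filter, descriptive summary,
#' posterior fit, per-stratum threshold table (Bayesian MLE/median/CrI and
#' bootstrap Youden median/CI), AUROC table, global-vs-subgroup metric
#' comparison for the gender strata, posterior-draw export, diagnostics and
#' a machine-readable manifest. Any stage failure aborts with the stage
#' name; a `_FAILED` marker file records the failed stage.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging.
#' @return (invisibly) named list of output paths.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[prlthresh] ", ...)
  stage <- "ingest"
  on_fail <- function(e) {
    writeLines(paste0("failed at stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$outdir, "_FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    cohort <- if (!is.null(config$input))
      read_cohort(config$input, config$mapping)
    else generate_cohort(config$generator)
    say(nrow(cohort), " records read")

    stage <- "complete_case"
    cc <- complete_case_filter(cohort, c("prl", "invasion"))
    say(nrow(cohort), " read -> ", nrow(cc), " complete cases")

    stage <- "descriptives"
    desc <- descriptive_table(cc, "invasion")
    .write_table(desc, file.path(config$outdir, "cohort_summary.csv"))

    stage <- "fit"
    mi <- model_input(cc)
    fit <- fit_invasion_model(mi, chains = config$mcmc$chains,
                              iter = config$mcmc$iter,
                              warmup = config$mcmc$warmup,
                              thin = config$mcmc$thin,
                              seed = config$mcmc$seed)
    export_draws(fit, file.path(config$outdir, "posterior_draws.csv"))
    diag <- convergence_report(fit)
    diag_out <- diag
    diag_out$overall_pass <- attr(diag, "pass")
    .write_table(diag_out, file.path(config$outdir, "diagnostics.csv"))
    say("fit done: max R-hat ",
        round(max(diag$r_hat, na.rm = TRUE), 4), ", min ESS ",
        round(min(diag$ess_bulk, na.rm = TRUE)))

    stage <- "thresholds"
    strata <- table2_subgroups()
    tt <- threshold_table(fit, mi, strata, method = config$thresholds$method)
    yt <- youden_table(cc, strata, replicates = config$bootstrap$replicates,
                       seed = config$bootstrap$seed,
                       stratified = config$bootstrap$stratified)
    thr <- merge(tt, yt[, c("stratum", "threshold", "j", "boot_median",
                            "ci_low", "ci_high")],
                 by = "stratum", sort = FALSE, suffixes = c("", "_youden"))
    names(thr)[names(thr) == "threshold"] <- "youden_threshold"
    names(thr)[names(thr) == "boot_median"] <- "youden_median"
    names(thr)[names(thr) == "ci_low_youden"] <- "youden_ci_low"
    names(thr)[names(thr) == "ci_high_youden"] <- "youden_ci_high"
    .write_table(thr, file.path(config$outdir, "thresholds.csv"))
    say(sum(thr$estimable), " of ", nrow(thr), " strata estimable")

    stage <- "evaluation"
    at <- auroc_table(cc, strata, replicates = config$bootstrap$replicates,
                      seed = config$bootstrap$seed + 500L)
    .write_table(at, file.path(config$outdir, "auroc.csv"))
    cmp_strata <- list(subgroup_spec("female", sex = "female"),
                       subgroup_spec("male", sex = "male"))
    cmp <- list()
    for (sp in cmp_strata) for (src in c("global", "subgroup_specific")) {
      ps <- tryCatch(posterior_metric_distribution(fit, mi, sp, src,
                                                   method = config$thresholds$method),
                     error = function(e) NULL)
      if (is.null(ps)) next
      for (m in colnames(ps$distributions))
        cmp[[length(cmp) + 1L]] <- data.frame(
          stratum = sp$name, source = src, metric = m,
          mean = unname(ps$point[m]), ci_low = ps$interval[1, m],
          ci_high = ps$interval[2, m],
          n_undefined = unname(ps$n_undefined[m]))
    }
    .write_table(do.call(rbind, cmp),
                 file.path(config$outdir, "metric_comparison.csv"))

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("prlthresh")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = .config_to_list(config),
      n_read = nrow(cohort), n_complete = nrow(cc),
      excluded_draw_totals = sum(thr$excluded_draws, na.rm = TRUE))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }, error = on_fail)
  files <- c("cohort_summary.csv", "posterior_draws.csv", "diagnostics.csv",
             "thresholds.csv", "auroc.csv", "metric_comparison.csv",
             "manifest.json")
  invisible(setNames(file.path(config$outdir, files), files))
}

#' Write the canonical test fixtures
#'
#' Writes (i) the canonical synthetic cohort: N = 149 with 18 PRL values
#' missing so the complete-case step reproduces the published 149 -> 131
#' accounting; (ii) a 12-patient worked-example cohort whose Youden cutpoint
#' is hand-checkable by exhaustive enumeration; (iii) a JSON snapshot of the
#' worked example's expected outputs.
#'
#' @param outdir writable directory.
#' @param seed seed for the canonical cohort.
#' @return (invisibly) the written paths.
#' @export
make_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  canonical <- generate_cohort(default_paper_params(seed = seed))
  p_canon <- file.path(outdir, "synthetic_cohort_n149.csv")
  write_cohort(canonical, p_canon)

  # 12 patients, perfectly enumerable: non-invasive PRL all < 400,
  # invasive all >= 400 except one overlap pair
  worked <- cohort_table(data.frame(
    patient_id = sprintf("W%02d", 1:12),
    sex = rep(c("female", "male"), 6),
    age = c(30, 55, 42, 61, 28, 49, 52, 33, 45, 58, 39, 50),
    bmi = c(22, 31, 27, 29, 24, 33, 26, 28, 35, 23, 30, 25),
    prl = c(80, 120, 150, 200, 250, 380, 400, 520, 700, 950, 300, 1200),
    invasion = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 0, 1),
    treatment = rep(c("surgery", "medical"), 6)), provenance = "worked-example")
  p_worked <- file.path(outdir, "worked_example_n12.csv")
  write_cohort(worked, p_worked)

  yj <- youden_threshold(worked$prl, worked$invasion)
  snap <- list(worked_example = list(
    youden_threshold = yj$threshold, j_statistic = yj$j_statistic,
    auroc = auroc(worked$prl, worked$invasion)),
    canonical = list(n = nrow(canonical),
                     n_complete = nrow(complete_case_filter(canonical)),
                     seed = seed))
  p_snap <- file.path(outdir, "expected_outputs.json")
  jsonlite::write_json(snap, p_snap, auto_unbox = TRUE, digits = NA)
  invisible(c(p_canon, p_worked, p_snap))
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline from a `--config` JSON), `simulate`
#' (write a synthetic cohort CSV), `fixtures` (write canonical fixtures).
#' Installed as `inst/cli/prlthresh`, runnable as
#' `Rscript -e 'prlthresh::prlthresh_cli()' <subcommand> ...`.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
prlthresh_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: prlthresh <run|simulate|fixtures> [options]",
    "  run       --config <file.json> [--outdir <dir>]",
    "  simulate  --out <file.csv> [--n <int>] [--seed <int>]",
    "  fixtures  --outdir <dir> [--seed <int>]", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (!length(i)) return(default)
    rest[i[1] + 1L]
  }
  switch(cmd,
    run = {
      cfg_path <- getopt("--config")
      if (is.null(cfg_path)) stop("run needs --config", call. = FALSE)
      cfg <- read_run_config(cfg_path)
      od <- getopt("--outdir")
      if (!is.null(od)) cfg$outdir <- od
      run_analysis(cfg)
    },
    simulate = {
      out <- getopt("--out")
      if (is.null(out)) stop("simulate needs --out", call. = FALSE)
      n <- as.integer(getopt("--n", "149"))
      seed <- as.integer(getopt("--seed", "1"))
      write_cohort(generate_cohort(default_paper_params(n = n, seed = seed)),
                   out)
    },
    fixtures = {
      od <- getopt("--outdir")
      if (is.null(od)) stop("fixtures needs --outdir", call. = FALSE)
      make_fixtures(od, seed = as.integer(getopt("--seed", "1")))
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}
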