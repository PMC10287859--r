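# End-to-end pipeline: cohort -> masks -> features -> repeatability selection
# -> nested CV -> permutation significance -> report; plus the seven named
# phase/compartment analysis combinations.

#' The seven named analysis combinations
#'
#' (a) both phases, T+TST; (b) peak, T+TST; (c) early, T+TST; (d) peak, T;
#' (e) peak, TST; (f) early, T; (g) early, TST. Each runs as an independent
#' nested CV on the matching subset of feature columns.
#' @return named list of `list(phases, compartments)`.
#' @export
analysis_combinations <- function() {
  list(
    a = list(phases = c("early", "peak"), compartments = c("T", "TST")),
    b = list(phases = "peak", compartments = c("T", "TST")),
    c = list(phases = "early", compartments = c("T", "TST")),
    d = list(phases = "peak", compartments = "T"),
    e = list(phases = "peak", compartments = "TST"),
    f = list(phases = "early", compartments = "T"),
    g = list(phases = "early", compartments = "TST")
  )
}

#' Resolve a combination selector
#'
#' Accepts a letter (`"a"`..`"g"`), `"all"`, or a `"phases/compartments"`
#' string such as `"early+peak/T+TST"` or `"peak/TST"`.
#' @param selector character selector.
#' @return named list of combinations to run.
#' @export
resolve_combination <- function(selector) {
  combos <- analysis_combinations()
  if (identical(selector, "all")) return(combos)
  if (selector %in% names(combos)) return(combos[selector])
  if (grepl("/", selector, fixed = TRUE)) {
    parts <- strsplit(selector, "/", fixed = TRUE)[[1]]
    phases <- strsplit(parts[1], "+", fixed = TRUE)[[1]]
    comps <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
    if (all(phases %in% c("early", "peak")) && all(comps %in% c("T", "TST"))) {
      # map onto a named combination when one matches
      for (nm in names(combos)) {
        cb <- combos[[nm]]
        if (setequal(cb$phases, phases) && setequal(cb$compartments, comps))
          return(combos[nm])
      }
      out <- list(list(phases = phases, compartments = comps))
      names(out) <- selector
      return(out)
    }
  }
  stop("unknown combination '", selector, "'; valid: ",
       paste(names(combos), collapse = ", "),
       ", all, or e.g. early+peak/T+TST")
}

# restrict feature columns to a combination's phases/compartments
.filter_combination_columns <- function(keys, combo) {
  info <- parse_feature_keys(keys)
  keys[info$phase %in% combo$phases & info$compartment %in% combo$compartments]
}

#' Pipeline run configuration
#'
#' @param cohort either a [cohort_config()] (synthetic cohort) or a list
#'   `list(dir = ..., labels_csv = ...)` pointing at NIfTI files on disk.
#' @param extraction an [extraction_config()].
#' @param repeatability_threshold inter-reader correlation threshold.
#' @param combination selector (see [resolve_combination()]); default `"a"`.
#' @param consensus_reader `"mean"`, `1` or `2`.
#' @param k_grid candidate PLS component counts; `NULL` = `1:min(30, n-2, p)`.
#' @param n_perm permutations for the null (default 1e5).
#' @param perm_seed seed for the permutation null.
#' @param global_zscore use cohort-wide z-scoring (source convention) instead
#'   of per-fold refitting.
#' @param score_cutoff recurrence-score cutoff defining the high-risk class.
#' @param dilate_mm,erode_mm TST ring radii.
#' @param top_fraction fraction for the beta-weight profile (default 0.05).
#' @param out_dir output directory for artifacts, or `NULL` to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       extraction = extraction_config(),
                       repeatability_threshold = 0.95,
                       combination = "a",
                       consensus_reader = "mean",
                       k_grid = NULL,
                       n_perm = 1e5,
                       perm_seed = 1,
                       global_zscore = FALSE,
                       score_cutoff = 25,
                       dilate_mm = 2, erode_mm = 2,
                       top_fraction = 0.05,
                       out_dir = NULL) {
  resolve_combination(combination)  # validates
  if (!inherits(cohort, "cohort_config")) {
    if (!is.list(cohort) || is.null(cohort$dir))
      stop("`cohort` must be a cohort_config or list(dir=, labels_csv=)")
    if (!dir.exists(cohort$dir)) stop("cohort directory not found: ", cohort$dir)
  }
  structure(list(cohort = cohort, extraction = extraction,
                 repeatability_threshold = repeatability_threshold,
                 combination = combination,
                 consensus_reader = consensus_reader, k_grid = k_grid,
                 n_perm = n_perm, perm_seed = perm_seed,
                 global_zscore = global_zscore, score_cutoff = score_cutoff,
                 dilate_mm = dilate_mm, erode_mm = erode_mm,
                 top_fraction = top_fraction, out_dir = out_dir),
            class = "run_config")
}

#' Run one analysis combination on extracted feature tables
#'
#' Repeatability-filters the combination's columns, builds the consensus
#' table, runs leave-one-out nested CV, and evaluates permutation
#' significance. The beta-weight profile comes from a final all-subject fit at
#' the modal inner-selected component count.
#'
#' @param tables list with `reader1`/`reader2` matrices (finite columns).
#' @param labels binary 0/1 outcome per subject.
#' @param combo a combination entry from [analysis_combinations()].
#' @param config a [run_config()].
#' @return list with the combination report (repeatable count, auc, z, p
#'   values, per-fold k, top-feature profile, ncv result).
#' @export
run_combination <- function(tables, labels, combo, config) {
  keys <- .filter_combination_columns(colnames(tables$reader1), combo)
  if (length(keys) == 0) stop("no feature columns match the combination")
  rep_rep <- repeatability_filter(tables$reader1[, keys, drop = FALSE],
                                  tables$reader2[, keys, drop = FALSE],
                                  config$repeatability_threshold)
  cons <- consensus_table(tables$reader1, tables$reader2, rep_rep$selected,
                          reader = config$consensus_reader)
  ncv <- loo_ncv(cons, labels, k_grid = config$k_grid,
                 global_zscore = config$global_zscore)
  auc <- roc_auc(ncv$scores, labels)
  null <- permutation_null(ncv$scores, labels, n_perm = config$n_perm,
                           seed = config$perm_seed)
  sig <- auc_significance(auc, null)
  # final all-subject fit at the modal inner-selected k for the beta profile
  k_modal <- as.integer(names(sort(table(ncv$fold_k), decreasing = TRUE))[1])
  fit <- fit_pls(suppressWarnings(zscore_columns(cons)), labels, k_modal)
  top <- top_beta_fraction(fit, config$top_fraction)
  list(n_features = length(keys),
       n_perm = null$n_perm, perm_seed = null$seed,
       n_repeatable = length(rep_rep$selected),
       repeatability = rep_rep,
       ncv = ncv,
       auc = auc, z = sig$z, p_normal = sig$p_normal,
       p_empirical = sig$p_empirical, significant = sig$significant,
       null_mean = sig$null_mean, null_sd = sig$null_sd,
       k_modal = k_modal,
       beta = fit$beta,
       top_keys = top,
       top_profile = profile_top_features(top))
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return list of class `run_report`: per-combination results plus cohort and
#'   config summaries. Artifacts (feature tables, repeatability report, fold
#'   scores, JSON report) are written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)
  say("building cohort")
  cohort <- if (inherits(config$cohort, "cohort_config")) {
    generate_cohort(config$cohort)
  } else {
    read_cohort(config$cohort$dir,
                labels_csv = config$cohort$labels_csv %||% file.path(config$cohort$dir, "cohort.csv"),
                score_cutoff = config$score_cutoff)
  }
  labels <- vapply(cohort, `[[`, 0L, "label")
  say("extracting features (", length(cohort), " subjects)")
  tables <- extract_cohort(cohort, config$extraction,
                           dilate_mm = config$dilate_mm,
                           erode_mm = config$erode_mm, verbose = verbose)
  tables <- drop_nonfinite_columns(tables)
  combos <- resolve_combination(config$combination)
  results <- list()
  for (nm in names(combos)) {
    say("combination ", nm)
    results[[nm]] <- run_combination(tables, labels, combos[[nm]], config)
  }
  report <- structure(list(
    n_subjects = length(cohort),
    n_positive = sum(labels),
    n_columns = ncol(tables$reader1),
    combinations = results,
    config = config
  ), class = "run_report")
  if (!is.null(config$out_dir)) .write_run_artifacts(report, tables, config)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_run_artifacts <- function(report, tables, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_tables(tables, file.path(config$out_dir, "features.csv"))
  for (nm in names(report$combinations)) {
    res <- report$combinations[[nm]]
    utils::write.csv(res$repeatability$report,
                     file.path(config$out_dir, paste0("repeatability_", nm, ".csv")),
                     row.names = FALSE)
    write_ncv_result(res$ncv, file.path(config$out_dir, paste0("ncv_", nm, ".csv")))
    utils::write.csv(data.frame(key = names(res$beta), beta = as.numeric(res$beta),
                                top5 = names(res$beta) %in% res$top_keys),
                     file.path(config$out_dir, paste0("beta_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report_to_list(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Convert a run report to a plain list (JSON-ready)
#' @param report a `run_report`.
#' @return nested list with per-combination metrics.
#' @export
report_to_list <- function(report) {
  list(
    n_subjects = report$n_subjects,
    n_positive = report$n_positive,
    n_feature_columns = report$n_columns,
    combinations = lapply(report$combinations, function(r) {
      list(n_features = r$n_features, n_repeatable = r$n_repeatable,
           auc = r$auc, z = r$z, p_normal = r$p_normal,
           p_empirical = r$p_empirical, significant = r$significant,
           null_mean = r$null_mean, null_sd = r$null_sd,
           n_perm = r$n_perm, perm_seed = r$perm_seed,
           k_modal = r$k_modal, fold_k = as.integer(r$ncv$fold_k),
           top_profile = r$top_profile)
    })
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$n_subjects, "subjects (", x$n_positive, "positive ),",
      x$n_columns, "feature columns\n")
  for (nm in names(x$combinations)) {
    r <- x$combinations[[nm]]
    cat(sprintf("  (%s) repeatable=%d AUC=%.3f z=%.2f p_emp=%.4g%s\n",
                nm, r$n_repeatable, r$auc, r$z, r$p_empirical,
                if (r$significant) " *" else ""))
  }
  invisible(x)
}
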