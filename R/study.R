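#' Configuration for the full threshold-revision study
#'
#' @param n_iterations,n_train,n_validation,seed Passed to [split_plan()].
#' @param navx NavX EGM settings ([navx_settings()]).
#' @param carto CARTO EGM settings ([carto_settings()]).
#' @return A `study_config` list.
#' @export
study_config <- function(n_iterations = 30, n_train = 679,
                         n_validation = 118, seed = 1,
                         navx = navx_settings(), carto = carto_settings()) {
  structure(list(n_iterations = n_iterations, n_train = n_train,
                 n_validation = n_validation, seed = seed,
                 navx = navx, carto = carto),
            class = "study_config")
}

#' Run the complete threshold-revision study on a cohort
#'
#' End-to-end pipeline: per-AEG indices for both systems, the full-cohort
#' default-threshold quadrant table and Spearman correlation, 30 resampled
#' train/validation splits, per-iteration revision of the primary (CFE-Mean,
#' ICL) and complementary (CFE-SD, ACI, SCI) thresholds on the training set,
#' and validation of the default vs revised rules on the held-out AEGs.
#' Iterations whose reference labels are single-class are flagged, excluded
#' from the summaries, and reported. Deterministic given the config seed.
#'
#' @param aegs List of `electrogram`s (the cohort), or a precomputed index
#'   table from [compute_cohort_indices()].
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, writes `thresholds.csv`,
#'   `validation_report.csv`, `quadrant_tables.csv` and `roc_summary.csv`.
#' @return A `cfae_study` list: `indices`, `default_quadrant`,
#'   `spearman_rho`, `splits`, `thresholds` (per-iteration data frame),
#'   `thresholds_mean` (a [threshold_set()] of across-iteration means),
#'   `thresholds_summary`, `validation` (per-iteration data frame),
#'   `validation_summary`, `roc_summary` (Table-2/3-shaped data frame),
#'   `kappa_test` (paired Wilcoxon of revised vs default kappa),
#'   `excluded_iterations`.
#' @export
run_full_study <- function(aegs, config = study_config(), out_dir = NULL) {
  ind <- if (is.data.frame(aegs)) aegs else
    compute_cohort_indices(aegs, config$navx, config$carto)
  default_quadrant <- quadrant_table(ind$navx_cfae, ind$carto_cfae)
  rho <- spearman_rho(ind$cfe_mean_score, ind$icl)

  plan <- split_plan(config$n_iterations, config$n_train,
                     config$n_validation, config$seed)
  splits <- make_splits(ind$id, plan)

  thr_rows <- vector("list", plan$n_iterations)
  val_rows <- vector("list", plan$n_iterations)
  excluded <- integer(0)
  for (it in seq_len(plan$n_iterations)) {
    train <- ind[match(splits[[it]]$train, ind$id), , drop = FALSE]
    valid <- ind[match(splits[[it]]$validation, ind$id), , drop = FALSE]
    res <- tryCatch({
      prim <- revise_primary_thresholds(train)
      comp <- revise_complementary_thresholds(train, prim$cfe_mean_cutoff,
                                              prim$icl_cutoff)
      ts <- threshold_set(prim$cfe_mean_cutoff, comp$cfe_sd_cutoff,
                          prim$icl_cutoff, comp$aci_cutoff, comp$sci_cutoff)
      list(thr = cbind(iteration = it, prim, comp),
           val = cbind(iteration = it,
                       validate_thresholds(valid, ts, splits[[it]]$train)))
    }, error = function(e) {
      if (grepl("degenerate-input", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(res)) {
      warning("iteration ", it, " excluded: single-class reference labels")
      excluded <- c(excluded, it)
    } else {
      thr_rows[[it]] <- res$thr
      val_rows[[it]] <- res$val
    }
  }
  thr <- do.call(rbind, thr_rows)
  val <- do.call(rbind, val_rows)
  if (is.null(thr) || nrow(thr) == 0)
    stop("degenerate-input error: every iteration had single-class labels",
         call. = FALSE)

  cut_cols <- c("cfe_mean_cutoff", "icl_cutoff", "cfe_sd_cutoff",
                "aci_cutoff", "sci_cutoff")
  thr_summary <- do.call(rbind, lapply(cut_cols, function(cc)
    data.frame(index = sub("_cutoff$", "", cc), mean = mean(thr[[cc]]),
               sd = stats::sd(thr[[cc]]))))
  ts_mean <- threshold_set(mean(thr$cfe_mean_cutoff), mean(thr$cfe_sd_cutoff),
                           mean(thr$icl_cutoff), mean(thr$aci_cutoff),
                           mean(thr$sci_cutoff))
  val_summary <- do.call(rbind, lapply(names(val)[-1], function(cc)
    data.frame(measure = cc, mean = mean(val[[cc]]), sd = stats::sd(val[[cc]]))))

  roc_summary <- roc_summary_table(thr)
  kappa_test <- if (nrow(val) >= 2 &&
                    any(val$kappa_revised != val$kappa_default)) {
    ht <- suppressWarnings(stats::wilcox.test(val$kappa_revised,
                                              val$kappa_default,
                                              paired = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else list(statistic = NA_real_, p_value = NA_real_)

  out <- structure(list(
    indices = ind, default_quadrant = default_quadrant, spearman_rho = rho,
    splits = splits, thresholds = thr, thresholds_mean = ts_mean,
    thresholds_summary = thr_summary, validation = val,
    validation_summary = val_summary, roc_summary = roc_summary,
    kappa_test = kappa_test, excluded_iterations = excluded,
    config = config), class = "cfae_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# Table 2/3 shape: classifier, sensitivity, 1-specificity, AUROC (mean +/- SD)
roc_summary_table <- function(thr) {
  row <- function(reference, classifier, s, f, a = NULL) {
    data.frame(reference = reference, classifier = classifier,
               sensitivity_mean = mean(s), sensitivity_sd = stats::sd(s),
               one_minus_specificity_mean = mean(f),
               one_minus_specificity_sd = stats::sd(f),
               auroc_mean = if (is.null(a)) NA_real_ else mean(a),
               auroc_sd = if (is.null(a)) NA_real_ else stats::sd(a))
  }
  rbind(
    row("CFE-Mean default", "ICL default", thr$icl_default_sens,
        thr$icl_default_fpr, thr$icl_auroc),
    row("CFE-Mean default", "ICL revised", thr$icl_sens, thr$icl_fpr,
        thr$icl_auroc),
    row("ICL default", "CFE-Mean default", thr$cfe_mean_default_sens,
        thr$cfe_mean_default_fpr, thr$cfe_mean_auroc),
    row("ICL default", "CFE-Mean revised", thr$cfe_mean_sens,
        thr$cfe_mean_fpr, thr$cfe_mean_auroc),
    row("primary agreement", "CFE-SD revised", thr$cfe_sd_sens,
        thr$cfe_sd_fpr, thr$cfe_sd_auroc),
    row("primary agreement", "ACI revised", thr$aci_sens, thr$aci_fpr,
        thr$aci_auroc),
    row("primary agreement", "SCI revised", thr$sci_sens, thr$sci_fpr,
        thr$sci_auroc))
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE)
  w(study$thresholds, "thresholds.csv")
  w(study$validation, "validation_report.csv")
  q <- study$default_quadrant
  w(data.frame(table = "full_cohort_default", n_both_cfae = q$n_both_cfae,
               n_navx_only = q$n_a_only, n_carto_only = q$n_b_only,
               n_neither = q$n_neither, total = q$total, kappa = q$kappa),
    "quadrant_tables.csv")
  w(study$roc_summary, "roc_summary.csv")
  invisible(out_dir)
}

#' @export
print.cfae_study <- function(x, ...) {
  cat(sprintf("<cfae_study> %d AEGs, %d iterations (%d excluded)\n",
              nrow(x$indices), x$config$n_iterations,
              length(x$excluded_iterations)))
  cat(sprintf("  default kappa (full cohort) = %.3f; Spearman rho = %.3f\n",
              x$default_quadrant$kappa, x$spearman_rho))
  tm <- x$thresholds_mean
  cat(sprintf("  revised: CFE-Mean <= %.1f ms, CFE-SD <= %.1f ms, ICL >= %.1f, ACI <= %.1f ms, SCI <= %.1f ms\n",
              tm$cfe_mean_max_ms, tm$cfe_sd_max_ms, tm$icl_min,
              tm$aci_max_ms, tm$sci_max_ms))
  cat(sprintf("  validation kappa: default %.3f +/- %.3f -> revised %.3f +/- %.3f\n",
              mean(x$validation$kappa_default), stats::sd(x$validation$kappa_default),
              mean(x$validation$kappa_revised), stats::sd(x$validation$kappa_revised)))
  invisible(x)
}

#' Window-length sweep of CFE-Mean and ICL
#'
#' Recomputes both primary indices on nested sub-windows (by default 2.5, 5
#' and 8 s from the start of each AEG). AEGs shorter than a requested window
#' are skipped for that window with a warning. Paired across-window
#' comparison is delegated to [friedman_dunn()] on the reshaped result.
#'
#' @param aegs List of `electrogram`s (>= the largest window in length).
#' @param windows_s Window lengths in seconds.
#' @param navx,carto Detector settings.
#' @return Long data frame: `id`, `window_s`, `n_marks`, `cfe_mean_ms`,
#'   `cfe_sd_ms`, `icl`, `aci_ms`, `sci_ms`, `cfe_mean_score`.
#' @export
window_sweep <- function(aegs, windows_s = c(2.5, 5, 8),
                         navx = navx_settings(), carto = carto_settings()) {
  out <- list()
  for (w in windows_s) {
    long_enough <- vapply(aegs, function(e) e$window_s >= w - 1e-9, TRUE)
    if (!all(long_enough))
      warning(sum(!long_enough), " AEG(s) shorter than ", w,
              " s skipped for that window")
    if (!any(long_enough)) next
    ind <- compute_cohort_indices(aegs[long_enough], navx, carto,
                                  window_s = w)
    out[[length(out) + 1L]] <- cbind(
      ind[, c("id", "n_marks", "cfe_mean_ms", "cfe_sd_ms", "icl",
              "aci_ms", "sci_ms", "cfe_mean_score")],
      window_s = w)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("id", "window_s", "n_marks", "cfe_mean_ms", "cfe_sd_ms", "icl",
          "aci_ms", "sci_ms", "cfe_mean_score")]
}
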