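#' Per-AEG fractionation indices for a cohort
#'
#' Runs both detectors on every AEG and assembles the per-AEG index table
#' used by the threshold-revision pipeline. Undefined indices receive
#' worst-case (least fractionated) surrogate scores so ROC input is total:
#' the window length in ms for CFE-Mean, CFE-SD, ACI and SCI (far beyond any
#' attainable value of these interval statistics, so it acts as an
#' infinity-equivalent for ranking).
#'
#' @param aegs List of `electrogram`s.
#' @param navx A [navx_settings()].
#' @param carto A [carto_settings()].
#' @param window_s Optional sub-window (seconds) to extract from each AEG
#'   before analysis; `NULL` analyses each AEG as supplied.
#' @param offset_s Offset of the sub-window (seconds).
#' @return Data frame, one row per AEG: `id`, `window_ms`, `n_marks`,
#'   `cfe_mean_ms`, `cfe_sd_ms`, `navx_defined`, `navx_cfae`, `icl`,
#'   `aci_ms`, `sci_ms`, `band`, `carto_defined`, `carto_cfae`, and the
#'   surrogate-completed scores `cfe_mean_score`, `cfe_sd_score`,
#'   `aci_score`, `sci_score`.
#' @export
compute_cohort_indices <- function(aegs, navx = navx_settings(),
                                   carto = carto_settings(),
                                   window_s = NULL, offset_s = 0) {
  rows <- lapply(seq_along(aegs), function(i) {
    egm <- aegs[[i]]
    if (!is.null(window_s)) egm <- segment_window(egm, window_s, offset_s)
    wm <- window_ms(egm)
    marks <- detect_negative_deflections(egm, navx)
    ni <- compute_navx_indices(marks, wm)
    ext <- detect_qualifying_extrema(egm, carto)
    ci <- compute_carto_indices(mark_complex_intervals(ext, carto))
    data.frame(
      id = egm$id, window_ms = wm, n_marks = ni$n_marks,
      cfe_mean_ms = ni$cfe_mean_ms, cfe_sd_ms = ni$cfe_sd_ms,
      navx_defined = ni$defined, navx_cfae = classify_navx(ni, navx),
      icl = ci$icl, aci_ms = ci$aci_ms, sci_ms = ci$sci_ms, band = ci$band,
      carto_defined = ci$defined,
      carto_cfae = ci$icl >= carto$icl_threshold,
      cfe_mean_score = if (ni$defined) ni$cfe_mean_ms else wm,
      cfe_sd_score = if (ni$defined) ni$cfe_sd_ms else wm,
      aci_score = if (ci$defined) ci$aci_ms else wm,
      sci_score = if (ci$defined) ci$sci_ms else wm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resampling plan for train/validation splits
#'
#' @param n_iterations Number of resampled splits (default 30).
#' @param n_train Training-set size (default 679; the cohort of 797 splits
#'   as 679 + 118).
#' @param n_validation Validation-set size (default 118).
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return A `split_plan` list with derived `iteration_seeds`.
#' @export
split_plan <- function(n_iterations = 30, n_train = 679, n_validation = 118,
                       seed = 1) {
  stopifnot(n_iterations >= 1, n_train >= 1, n_validation >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_train = as.integer(n_train),
                 n_validation = as.integer(n_validation), seed = seed,
                 iteration_seeds = with_seed(seed,
                   sample.int(.Machine$integer.max - 1L, n_iterations))),
            class = "split_plan")
}

#' Draw the resampled train/validation splits
#'
#' Each iteration draws `n_train` ids uniformly without replacement; the
#' remaining `n_validation` ids form the validation set. Reproducible given
#' the plan's master seed.
#'
#' @param ids Cohort AEG ids (length must equal `n_train + n_validation`).
#' @param plan A [split_plan()].
#' @return List of `n_iterations` lists with elements `train`, `validation`.
#' @export
make_splits <- function(ids, plan) {
  ids <- as.character(ids)
  if (length(ids) != plan$n_train + plan$n_validation)
    stop("parameter error: cohort size ", length(ids),
         " != n_train + n_validation = ", plan$n_train + plan$n_validation,
         call. = FALSE)
  if (anyDuplicated(ids)) stop("parameter error: duplicate ids", call. = FALSE)
  lapply(seq_len(plan$n_iterations), function(it) {
    train <- with_seed(plan$iteration_seeds[it], sample(ids, plan$n_train))
    list(train = sort(train), validation = sort(setdiff(ids, train)))
  })
}

# sensitivity and 1-specificity of a fixed binary predictor
sens_fpr <- function(pred, labels) {
  c(sens = sum(pred & labels) / sum(labels),
    fpr = sum(pred & !labels) / sum(!labels))
}

#' Revise the primary thresholds (CFE-Mean and ICL) on one training set
#'
#' Each primary index is judged against the counterpart system's
#' default-setting classification: the ICL cutoff is the closest-to-corner
#' optimum of the ROC of ICL scores against the NavX default classification
#' (CFE-Mean in 30-120 ms; high ICL is positive), and the CFE-Mean cutoff is
#' the optimum of the ROC of CFE-Mean scores against the CARTO default
#' classification (ICL >= 7; low CFE-Mean is positive). Reference labels
#' always come from the default-setting classifications; revised labels are
#' never fed back into primary training.
#'
#' @param ind Index table (rows of [compute_cohort_indices()]) for the
#'   training ids of one iteration.
#' @return One-row data frame: revised cutoffs, their operating points, the
#'   default thresholds' operating points, and both AUROCs.
#' @export
revise_primary_thresholds <- function(ind) {
  roc_icl <- roc_curve(ind$icl, ind$navx_cfae, direction = "high")
  opt_icl <- optimum_point(roc_icl)
  def_icl <- sens_fpr(ind$carto_cfae, ind$navx_cfae)
  roc_cfe <- roc_curve(ind$cfe_mean_score, ind$carto_cfae, direction = "low")
  opt_cfe <- optimum_point(roc_cfe)
  def_cfe <- sens_fpr(ind$navx_cfae, ind$carto_cfae)
  data.frame(
    icl_cutoff = opt_icl$threshold, icl_sens = opt_icl$sensitivity,
    icl_fpr = opt_icl$one_minus_specificity, icl_auroc = roc_icl$auroc,
    icl_default_sens = def_icl[["sens"]], icl_default_fpr = def_icl[["fpr"]],
    cfe_mean_cutoff = opt_cfe$threshold, cfe_mean_sens = opt_cfe$sensitivity,
    cfe_mean_fpr = opt_cfe$one_minus_specificity,
    cfe_mean_auroc = roc_cfe$auroc,
    cfe_mean_default_sens = def_cfe[["sens"]],
    cfe_mean_default_fpr = def_cfe[["fpr"]])
}

#' Revise the complementary thresholds (CFE-SD, ACI, SCI)
#'
#' The reference label is the agreement of the revised primary rules: an AEG
#' is labelled CFAE only when both CFE-Mean (<= revised cutoff) and ICL
#' (>= revised cutoff) agree. One ROC per complementary index, all
#' low-is-positive, cutoffs at the closest-to-corner optimum.
#'
#' @param ind Training index table for one iteration.
#' @param cfe_mean_cutoff,icl_cutoff Revised primary cutoffs for the same
#'   iteration.
#' @return One-row data frame: `cfe_sd_cutoff`, `aci_cutoff`, `sci_cutoff`
#'   with their sensitivities, 1-specificities, and AUROCs.
#' @export
revise_complementary_thresholds <- function(ind, cfe_mean_cutoff, icl_cutoff) {
  ref <- ind$cfe_mean_score <= cfe_mean_cutoff & ind$icl >= icl_cutoff
  one <- function(score) {
    roc <- roc_curve(score, ref, direction = "low")
    opt <- optimum_point(roc)
    c(cutoff = opt$threshold, sens = opt$sensitivity,
      fpr = opt$one_minus_specificity, auroc = roc$auroc)
  }
  sd_ <- one(ind$cfe_sd_score); aci <- one(ind$aci_score)
  sci <- one(ind$sci_score)
  data.frame(
    cfe_sd_cutoff = sd_[["cutoff"]], cfe_sd_sens = sd_[["sens"]],
    cfe_sd_fpr = sd_[["fpr"]], cfe_sd_auroc = sd_[["auroc"]],
    aci_cutoff = aci[["cutoff"]], aci_sens = aci[["sens"]],
    aci_fpr = aci[["fpr"]], aci_auroc = aci[["auroc"]],
    sci_cutoff = sci[["cutoff"]], sci_sens = sci[["sens"]],
    sci_fpr = sci[["fpr"]], sci_auroc = sci[["auroc"]])
}

#' Revised threshold set for the five indices
#'
#' @param cfe_mean_max_ms,cfe_sd_max_ms Upper cutoffs for the NavX indices.
#' @param icl_min Lower ICL cutoff (real-valued; with integer ICL a cutoff
#'   of e.g. 3.8 behaves as >= 4).
#' @param aci_max_ms,sci_max_ms Upper cutoffs for the CARTO complementary
#'   indices.
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(cfe_mean_max_ms, cfe_sd_max_ms, icl_min,
                          aci_max_ms, sci_max_ms) {
  stopifnot(cfe_mean_max_ms > 0, cfe_sd_max_ms >= 0, is.finite(icl_min),
            aci_max_ms > 0, sci_max_ms > 0)
  structure(list(cfe_mean_max_ms = cfe_mean_max_ms,
                 cfe_sd_max_ms = cfe_sd_max_ms, icl_min = icl_min,
                 aci_max_ms = aci_max_ms, sci_max_ms = sci_max_ms),
            class = "threshold_set")
}

#' Combined CFAE classification from primary + complementary indices
#'
#' NavX: CFAE when CFE-Mean <= cutoff AND CFE-SD <= cutoff. CARTO: CFAE when
#' ICL >= cutoff AND ACI <= cutoff AND SCI <= cutoff. Any undefined index
#' classifies the AEG as non-CFAE for that system.
#'
#' @param ind Index table rows.
#' @param thresholds A [threshold_set()].
#' @return Data frame: `id`, `navx_combined`, `carto_combined`.
#' @export
combined_classify <- function(ind, thresholds) {
  navx <- ind$navx_defined &
    ind$cfe_mean_ms <= thresholds$cfe_mean_max_ms &
    ind$cfe_sd_ms <= thresholds$cfe_sd_max_ms
  carto <- ind$carto_defined &
    ind$icl >= thresholds$icl_min &
    ind$aci_ms <= thresholds$aci_max_ms &
    ind$sci_ms <= thresholds$sci_max_ms
  data.frame(id = ind$id,
             navx_combined = ifelse(is.na(navx), FALSE, navx),
             carto_combined = ifelse(is.na(carto), FALSE, carto))
}

#' Validate one iteration's thresholds on its held-out AEGs
#'
#' Computes, on the validation rows only, the proportion of AEGs each system
#' classifies as CFAE and the between-system Cohen's kappa, under both the
#' default rules and the revised combined rules. Refuses to run when any
#' validation id appears in the training set (leakage).
#'
#' @param val_ind Index table rows for the validation ids.
#' @param thresholds The iteration's revised [threshold_set()].
#' @param train_ids Training ids of the same iteration (leakage audit).
#' @return One-row data frame: proportions and kappas, default and revised.
#' @export
validate_thresholds <- function(val_ind, thresholds, train_ids = character(0)) {
  if (length(intersect(val_ind$id, train_ids)) > 0)
    stop("contract violation: validation ids overlap the training set (leakage)",
         call. = FALSE)
  comb <- combined_classify(val_ind, thresholds)
  kap_def <- quadrant_table(val_ind$navx_cfae, val_ind$carto_cfae)
  kap_rev <- quadrant_table(comb$navx_combined, comb$carto_combined)
  data.frame(prop_navx_default = mean(val_ind$navx_cfae),
             prop_carto_default = mean(val_ind$carto_cfae),
             kappa_default = kap_def$kappa,
             prop_navx_revised = mean(comb$navx_combined),
             prop_carto_revised = mean(comb$carto_combined),
             kappa_revised = kap_rev$kappa)
}
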