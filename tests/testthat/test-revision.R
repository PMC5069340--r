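make_ind <- function(cfe, sd_, icl, aci, sci, wm = 2500) {
  n <- length(cfe)
  data.frame(
    id = sprintf("a%03d", seq_len(n)), window_ms = wm, n_marks = 10,
    cfe_mean_ms = cfe, cfe_sd_ms = sd_, navx_defined = !is.na(cfe),
    navx_cfae = !is.na(cfe) & cfe >= 30 & cfe <= 120,
    icl = icl, aci_ms = aci, sci_ms = sci, band = icl_band(icl),
    carto_defined = icl > 0, carto_cfae = icl >= 7,
    cfe_mean_score = ifelse(is.na(cfe), wm, cfe),
    cfe_sd_score = ifelse(is.na(sd_), wm, sd_),
    aci_score = ifelse(icl > 0, aci, wm),
    sci_score = ifelse(icl > 0, sci, wm))
}

test_that("splits are reproducible, disjoint, exhaustive and distinct", {
  ids <- sprintf("aeg%04d", 1:797)
  plan <- split_plan(seed = 99)
  s1 <- make_splits(ids, plan)
  s2 <- make_splits(ids, plan)
  expect_identical(s1, s2)
  expect_length(s1, 30)
  for (sp in s1) {
    expect_length(sp$train, 679)
    expect_length(sp$validation, 118)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), ids)
  }
  expect_gt(length(unique(vapply(s1, function(s)
    paste(s$train, collapse = ""), ""))), 1)
  expect_error(make_splits(ids[1:100], plan), "cohort size")
})

test_that("perfectly concordant indices reproduce the default partition", {
  # CFAE items: low CFE-Mean and high ICL; organized: the reverse
  cfae <- rep(c(TRUE, FALSE), c(30, 30))
  ind <- make_ind(cfe = ifelse(cfae, 70, 150), sd_ = ifelse(cfae, 10, 40),
                  icl = ifelse(cfae, 12, 1),
                  aci = ifelse(cfae, 70, 100), sci = ifelse(cfae, 55, 95))
  prim <- revise_primary_thresholds(ind)
  expect_equal(prim$icl_auroc, 1)
  expect_equal(prim$cfe_mean_auroc, 1)
  # revised cutoffs reproduce the default boundaries' partition
  expect_identical(ind$cfe_mean_score <= prim$cfe_mean_cutoff, cfae)
  expect_identical(ind$icl >= prim$icl_cutoff, cfae)
  kq <- quadrant_table(ind$cfe_mean_score <= prim$cfe_mean_cutoff,
                       ind$icl >= prim$icl_cutoff)
  expect_equal(kq$kappa, 1)
})

test_that("complementary revision uses the primary-agreement label", {
  cfae <- rep(c(TRUE, FALSE), c(25, 35))
  ind <- make_ind(cfe = ifelse(cfae, 60, 160), sd_ = ifelse(cfae, 8, 45),
                  icl = ifelse(cfae, 15, 0),
                  aci = ifelse(cfae, 65, NA), sci = ifelse(cfae, 52, NA))
  comp <- revise_complementary_thresholds(ind, cfe_mean_cutoff = 100,
                                          icl_cutoff = 5)
  expect_equal(comp$cfe_sd_auroc, 1)
  expect_equal(comp$aci_auroc, 1)
  expect_equal(comp$sci_auroc, 1)
  expect_lte(comp$sci_cutoff, comp$aci_cutoff)
  # an index independent of the labels has chance-level AUROC
  set.seed(11)
  aurocs <- replicate(40, {
    roc_curve(rnorm(60), sample(cfae), "low")$auroc
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.03)
})

test_that("combined classification applies all cutoffs conjunctively", {
  ts <- threshold_set(cfe_mean_max_ms = 84.1, cfe_sd_max_ms = 46.6,
                      icl_min = 4, aci_max_ms = 82, sci_max_ms = 58)
  ind <- make_ind(cfe = c(80, 80, 90, NA, 70),
                  sd_ = c(40, 50, 40, NA, 30),
                  icl = c(5, 5, 5, 8, 0),
                  aci = c(90, 70, 70, 75, NA),
                  sci = c(50, 50, 50, 50, NA))
  got <- combined_classify(ind, ts)
  expect_equal(got$navx_combined, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # ACI fails the first row; undefined ACI/SCI fail the last
  expect_equal(got$carto_combined, c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("validation refuses leakage and reports both rule sets", {
  ind <- make_ind(cfe = c(70, 150, 80, 140), sd_ = c(10, 40, 12, 35),
                  icl = c(10, 1, 9, 2), aci = c(70, 100, 72, 95),
                  sci = c(55, 90, 57, 88))
  ts <- threshold_set(100, 20, 5, 80, 60)
  expect_error(validate_thresholds(ind, ts, train_ids = ind$id[1]),
               "leakage")
  rep_ <- validate_thresholds(ind, ts, train_ids = character(0))
  expect_equal(rep_$prop_navx_default, 0.5)
  expect_equal(rep_$prop_carto_default, 0.5)
  expect_equal(rep_$kappa_default, 1)
  expect_equal(rep_$kappa_revised, 1)
})

test_that("the full study is deterministic and structurally sound", {
  coh <- generate_cohort(separated_cohort_spec(seed = 21, n_total = 120))
  cfg <- study_config(n_iterations = 4, n_train = 90, n_validation = 30,
                      seed = 13)
  st1 <- run_full_study(coh$aegs, cfg)
  st2 <- run_full_study(coh$aegs, cfg)
  expect_identical(st1$thresholds, st2$thresholds)
  expect_identical(st1$validation, st2$validation)
  expect_equal(nrow(st1$validation), 4)
  expect_equal(nrow(st1$thresholds), 4)
  # no leakage by construction, asserted structurally
  for (sp in st1$splits)
    expect_length(intersect(sp$train, sp$validation), 0)
  # across-iteration spread of the continuous cutoffs is nonzero
  expect_gt(stats::sd(st1$thresholds$cfe_mean_cutoff), 0)
  # written outputs are byte-identical across runs with one seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_full_study(coh$aegs, cfg, out_dir = d1)
  run_full_study(coh$aegs, cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("window sweep recomputes both indices per window", {
  spec <- cohort_spec(n_total = 12, window_s = 8, seed = 31)
  coh <- generate_cohort(spec)
  sw <- window_sweep(coh$aegs, windows_s = c(2.5, 5, 8))
  expect_equal(nrow(sw), 36)
  expect_setequal(unique(sw$window_s), c(2.5, 5, 8))

  # window 2.5 on the leading 2.5 s equals direct computation
  direct <- compute_cohort_indices(lapply(coh$aegs, segment_window, 2.5))
  sub <- sw[sw$window_s == 2.5, ]
  expect_equal(sub$cfe_mean_ms, direct$cfe_mean_ms)
  expect_equal(sub$icl, direct$icl)

  # stationary trains: CFE-Mean stable across windows (Friedman-ready shape)
  wide <- reshape(sw[, c("id", "window_s", "cfe_mean_score")],
                  idvar = "id", timevar = "window_s", direction = "wide")
  expect_equal(dim(wide), c(12, 4))
  fr <- friedman_dunn(as.matrix(wide[, -1]))
  expect_true(fr$p_value >= 0 && fr$p_value <= 1)

  # short signals are skipped with a warning
  mixed <- c(coh$aegs[1:2], list(short = segment_window(coh$aegs[[3]], 2.5)))
  expect_warning(sw2 <- window_sweep(mixed, windows_s = c(2.5, 8)),
                 "skipped")
  expect_equal(sum(sw2$window_s == 8), 2)
})
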