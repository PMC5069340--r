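test_that("activation trains honour the renewal contract", {
  # zero-jitter limit: exactly periodic from 0
  tr <- generate_activation_train(
    aeg_profile(mean_interval_ms = 100, seed = 1), window_s = 2.5)
  expect_equal(tr$t_ms, seq(0, 2400, by = 100), ignore_attr = TRUE)
  expect_equal(nrow(tr), 25)

  # determinism under the seed
  pf <- aeg_profile(mean_interval_ms = 80, interval_jitter_ms = 12, seed = 42)
  expect_identical(generate_activation_train(pf, 2.5),
                   generate_activation_train(pf, 2.5))

  # Monte-Carlo: empirical interval mean within 1 ms of the profile mean
  ivs <- unlist(lapply(1:300, function(s) {
    diff(generate_activation_train(
      aeg_profile(mean_interval_ms = 100, interval_jitter_ms = 10,
                  seed = 1000 + s), 2.5)$t_ms)
  }))
  expect_lt(abs(mean(ivs) - 100), 1)
  expect_lt(abs(stats::sd(ivs) - 10), 1)

  # infeasible profile: truncation floor above the reachable range
  expect_error(aeg_profile(mean_interval_ms = 30, interval_jitter_ms = 4,
                           deflections_per_complex = 3L,
                           subdeflection_spacing_ms = 20),
               "infeasible")
})

test_that("noiseless rendering closes the loop with both detectors", {
  # NavX closure: every planted deflection recovered, CFE-Mean = interval
  g <- generate_aeg(aeg_profile(mean_interval_ms = 100, pp_amplitude_mv = 0.2,
                                seed = 6))
  marks <- detect_negative_deflections(g$egm)
  expect_equal(nrow(marks), nrow(g$truth))
  expect_equal(marks$t_ms, g$truth$t_ms, tolerance = 1,
               ignore_attr = TRUE)            # within one sample (0.83 ms)
  ni <- compute_navx_indices(marks, window_ms(g$egm))
  expect_equal(ni$cfe_mean_ms, 100, tolerance = 0.01)
  expect_equal(ni$cfe_sd_ms, 0, tolerance = 0.01)

  # CARTO closure: fixed 0.1 mV deflections every 80 ms
  g2 <- generate_aeg(aeg_profile(mean_interval_ms = 80, pp_amplitude_mv = 0.1,
                                 seed = 6))
  ci <- compute_carto_indices(mark_complex_intervals(
    detect_qualifying_extrema(g2$egm)))
  expect_equal(ci$icl, nrow(g2$truth) - 1)    # one interval per gap
  expect_equal(ci$aci_ms, 80, tolerance = 0.5)
})

test_that("detection recall stays high under baseline noise", {
  hits <- total <- 0
  for (s in 1:25) {
    g <- generate_aeg(aeg_profile(mean_interval_ms = 100,
                                  interval_jitter_ms = 10,
                                  pp_amplitude_mv = 0.2,
                                  noise_rms_mv = 0.01, seed = 3000 + s))
    marks <- detect_negative_deflections(g$egm)
    total <- total + nrow(g$truth)
    hits <- hits + sum(vapply(g$truth$t_ms, function(t)
      any(abs(marks$t_ms - t) <= 5), TRUE))
  }
  expect_gte(hits / total, 0.95)
})

test_that("cohort generation is reproducible and archetypes separate", {
  spec <- cohort_spec(n_total = 120, seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$aegs, `[[`, "samples"),
                   lapply(c2$aegs, `[[`, "samples"))
  expect_equal(nrow(c1$truth), 120)
  expect_true(all(c1$truth$archetype %in% names(archetype_profiles())))

  ind <- compute_cohort_indices(c1$aegs)
  ind$archetype <- c1$truth$archetype
  cc <- ind[ind$archetype == "concordant_cfae", ]
  expect_gte(mean(cc$navx_cfae & cc$carto_cfae), 0.9)
  org <- ind[ind$archetype == "concordant_organized", ]
  expect_gte(mean(!org$navx_cfae & !org$carto_cfae), 0.9)
  nav <- ind[ind$archetype == "navx_only", ]
  expect_gte(mean(nav$navx_cfae & !nav$carto_cfae), 0.9)
})

test_that("a CFAE-only cohort classifies CFAE by both systems", {
  spec <- cohort_spec(n_total = 40,
                      weights = c(concordant_cfae = 1,
                                  concordant_organized = 0,
                                  navx_only = 0, carto_only = 0),
                      seed = 5)
  coh <- generate_cohort(spec)
  ind <- compute_cohort_indices(coh$aegs)
  expect_gte(mean(ind$navx_cfae), 0.95)
  expect_gte(mean(ind$carto_cfae), 0.95)
})

test_that("archetype CFE-Mean tracks the planted interval process", {
  # statistical fidelity of the effective FI mean for single-deflection
  # archetypes at negligible noise
  cfe <- vapply(1:120, function(s) {
    g <- generate_aeg(aeg_profile(mean_interval_ms = 112,
                                  interval_jitter_ms = 12,
                                  pp_amplitude_mv = 0.30,
                                  amplitude_jitter_mv = 0.04,
                                  neg_fraction = 0.85, seed = 5000 + s))
    compute_navx_indices(detect_negative_deflections(g$egm),
                         2500)$cfe_mean_ms
  }, 0)
  expect_lt(abs(mean(cfe) - 112), 2)
})
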