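test_that("ROC construction matches hand-counted examples", {
  r1 <- roc_curve(c(40, 60, 70, 80, 130, 150), c(T, T, T, F, F, F), "low")
  expect_equal(r1$auroc, 1.0)
  o1 <- optimum_point(r1)
  expect_equal(o1$distance_to_corner, 0)
  expect_equal(o1$sensitivity, 1)
  expect_equal(o1$one_minus_specificity, 0)

  sc <- c(40, 60, 90, 70, 100, 130, 150)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r2 <- roc_curve(sc, lb, "low")
  expect_equal(r2$auroc, 11 / 12)           # exhaustive pair counting
  o2 <- optimum_point(r2)
  expect_equal(o2$sensitivity, 1)
  expect_equal(o2$one_minus_specificity, 0.25)
  expect_gt(o2$threshold, 90); expect_lt(o2$threshold, 100)

  # curve is monotone nondecreasing in both coordinates with sentinels
  expect_true(all(diff(r2$points$sensitivity) >= 0))
  expect_true(all(diff(r2$points$one_minus_specificity) >= 0))
  expect_equal(range(r2$points$sensitivity), c(0, 1))

  expect_error(roc_curve(1:5, rep(TRUE, 5), "low"), "degenerate")
})

test_that("trapezoid and rank AUROC agree, and match an independent library", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    scores <- if (i %% 2) rnorm(n) else sample(0:12, n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    dir <- if (i %% 3) "low" else "high"
    a1 <- roc_curve(scores, labels, dir)$auroc
    a2 <- auroc_rank(scores, labels, dir)
    expect_equal(a1, a2, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(TRUE, FALSE), each = 40)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_curve(scores, labels, "high")$auroc, ref,
               tolerance = 1e-10)
})

test_that("random labels give chance-level AUROC", {
  set.seed(123)
  scores <- rnorm(1e4)
  labels <- sample(rep(c(TRUE, FALSE), 5e3))
  expect_lt(abs(roc_curve(scores, labels, "low")$auroc - 0.5), 0.02)
})

test_that("optimum point ties break toward higher sensitivity", {
  # scores equal within class: all achievable points lie on the diagonal
  r <- roc_curve(c(1, 1, 2, 2), c(TRUE, FALSE, TRUE, FALSE), "low")
  o <- optimum_point(r)
  d <- sqrt((1 - r$points$sensitivity)^2 + r$points$one_minus_specificity^2)
  expect_true(all(o$distance_to_corner <= d + 1e-12))
  ties <- which(abs(d - o$distance_to_corner) < 1e-12)
  expect_equal(o$sensitivity, max(r$points$sensitivity[ties]))
})

test_that("Cohen's kappa reproduces the quadrant-table and edge cases", {
  k <- cohen_kappa(273, 282, 12, 230)
  expect_equal(round(k$kappa, 2), 0.34)
  expect_equal(k$band, "marginal")

  expect_equal(cohen_kappa(50, 0, 0, 50)$kappa, 1)
  expect_equal(cohen_kappa(50, 0, 0, 50)$band, "excellent")
  # rater A all-positive, rater B positive on half: po == pe
  expect_equal(cohen_kappa(50, 50, 0, 0)$kappa, 0)
  # kappa = 1 iff off-diagonals are zero
  expect_lt(cohen_kappa(50, 1, 0, 49)$kappa, 1)
  # invariant under relabeling both raters simultaneously
  expect_equal(cohen_kappa(273, 282, 12, 230)$kappa,
               cohen_kappa(230, 12, 282, 273)$kappa)
  expect_error(cohen_kappa(0, 0, 0, 0), "empty")
})

test_that("quadrant_table cross-tabulates and is symmetric off-diagonal", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  b <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  q <- quadrant_table(a, b)
  expect_equal(q$n_both_cfae, 2); expect_equal(q$n_a_only, 1)
  expect_equal(q$n_b_only, 1); expect_equal(q$n_neither, 1)
  expect_equal(q$total, 5)
  expect_equal(q$observed_agreement, 3 / 5)

  qt <- quadrant_table(b, a)
  expect_equal(qt$n_a_only, q$n_b_only)
  expect_equal(qt$n_b_only, q$n_a_only)

  q2 <- quadrant_table(a, a)
  expect_equal(q2$n_a_only + q2$n_b_only, 0)
  expect_error(quadrant_table(a, b, ids = 1:5, ids_b = c(1:4, 9)),
               "alignment")
})

test_that("Spearman, Yates chi-square and Mann-Whitney behave as published", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_rho(1:5, rep(2, 5)), "constant")

  same <- yates_chi_square(matrix(c(30, 70, 30, 70), 2, byrow = TRUE))
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.99)
  big <- yates_chi_square(matrix(c(555, 242, 285, 512), 2, byrow = TRUE))
  expect_lt(big$p_value, 1e-4)
  # continuity correction only shrinks the statistic
  un <- suppressWarnings(stats::chisq.test(
    matrix(c(12, 5, 7, 9), 2), correct = FALSE))
  expect_lte(yates_chi_square(matrix(c(12, 5, 7, 9), 2))$statistic,
             unname(un$statistic))
  expect_error(yates_chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "degenerate")

  ident <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p_value, 0.99)
  sep <- mann_whitney_u(1:10, 21:30)
  expect_true(sep$exact)
  expect_equal(sep$U, 0, ignore_attr = TRUE)
  expect_lt(sep$p_value, 0.001)
  # U_x + U_y = n_x * n_y
  set.seed(3)
  x <- rnorm(12); y <- rnorm(9)
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 12 * 9,
               ignore_attr = TRUE)
  # exact and approximate agree for moderate n
  x <- rnorm(15); y <- rnorm(15, 0.5)
  p_ex <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(mann_whitney_u(x, y)$p_value - p_ex), 0.01)
})

test_that("Friedman statistic matches base R and Dunn output is sane", {
  m <- matrix(c(1.2, 2.3, 3.1,
                2.2, 1.1, 3.4,
                1.5, 2.8, 3.0,
                1.1, 2.0, 2.9,
                1.9, 2.5, 3.3), ncol = 3, byrow = TRUE)
  got <- friedman_dunn(m)
  ref <- stats::friedman.test(m)   # tie-free: statistics coincide
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(nrow(got$pairwise), 3)
  expect_true(all(got$pairwise$p_adj >= got$pairwise$p_raw - 1e-15))
  expect_true(all(got$pairwise$p_adj <= 1))

  expect_equal(friedman_dunn(matrix(1, 4, 3))$statistic, 0)
  expect_error(friedman_dunn(matrix(1:5, ncol = 1)), "2 groups")

  # the exhaustive within-block permutation null is invariant to permuting
  # group labels within every block of the data
  set.seed(5)
  m2 <- matrix(rnorm(12), ncol = 3)               # 4 blocks x 3 groups
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  null_dist <- function(m) {
    grid <- expand.grid(rep(list(1:6), nrow(m)))
    apply(grid, 1, function(g) {
      pm <- t(vapply(seq_len(nrow(m)),
                     function(i) m[i, perms[[g[i]]]], numeric(3)))
      friedman_dunn(pm)$statistic
    })
  }
  m3 <- t(vapply(1:4, function(i) m2[i, perms[[c(2, 5, 3, 6)[i]]]],
                 numeric(3)))
  expect_equal(sort(null_dist(m2)), sort(null_dist(m3)), tolerance = 1e-12)
})

test_that("all reported p-values live in the unit interval", {
  set.seed(8)
  ps <- c(
    yates_chi_square(matrix(c(8, 3, 4, 9), 2))$p_value,
    mann_whitney_u(rnorm(25), rnorm(30))$p_value,
    friedman_dunn(matrix(rnorm(12), 4, 3))$p_value)
  expect_true(all(ps >= 0 & ps <= 1))
})
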