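#' ROC curve with midpoint thresholds
#'
#' Builds a receiver operating characteristic curve for a score against a
#' binary reference label. Thresholds are placed at the midpoints between
#' consecutive distinct scores plus two infinite sentinels, so every
#' achievable confusion matrix is represented (integer scores such as ICL
#' naturally yield stepped curves). `direction = "low"` means a low score
#' indicates CFAE (CFE-Mean, CFE-SD, ACI, SCI: an item is called positive
#' when `score <= threshold`); `direction = "high"` means a high score does
#' (ICL: positive when `score >= threshold`).
#'
#' AUROC is computed by the trapezoidal rule; it equals the rank statistic
#' P(positive ranks above negative) + 0.5 P(tie) (see [auroc_rank()]).
#'
#' @param scores Finite numeric scores (surrogate scores for undefined
#'   indices are allowed and expected).
#' @param labels Logical (or 0/1) reference CFAE flags.
#' @param direction `"low"` or `"high"` (which score direction is positive).
#' @return A `roc_curve` object: `points` (data frame `threshold`,
#'   `sensitivity`, `one_minus_specificity`, sorted so both coordinates are
#'   nondecreasing), `auroc`, `direction`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate-input error: need at least one positive and one negative label",
         call. = FALSE)
  x <- if (direction == "low") -scores else scores
  ux <- sort(unique(x))
  # thresholds on the x scale, descending: +Inf (call nothing) down to -Inf
  cuts <- rev(c(-Inf, if (length(ux) > 1) (ux[-1] + ux[-length(ux)]) / 2, Inf))
  # cumulative counts above each cut
  tp <- vapply(cuts, function(ct) sum(x >= ct & labels), 0)
  fp <- vapply(cuts, function(ct) sum(x >= ct & !labels), 0)
  sens <- tp / n_pos
  fpr <- fp / n_neg
  thr <- if (direction == "low") -cuts else cuts
  pts <- data.frame(threshold = thr, sensitivity = sens,
                    one_minus_specificity = fpr)
  auroc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(points = pts, auroc = auroc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Rank-statistic AUROC
#'
#' The Mann-Whitney form of the area under the ROC curve: the probability
#' that a randomly chosen positive item out-ranks a randomly chosen negative
#' one, counting ties as one half. Matches the trapezoidal AUROC of
#' [roc_curve()] exactly.
#'
#' @inheritParams roc_curve
#' @return AUROC in \[0, 1\].
#' @export
auroc_rank <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  x <- if (direction == "low") -scores else scores
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate-input error: need both classes", call. = FALSE)
  r <- rank(x)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Optimum ROC point (closest to the top-left corner)
#'
#' Selects the curve point minimising the Euclidean distance to the ideal
#' classifier at (0, 1) in (1-specificity, sensitivity) space. Ties are
#' broken toward higher sensitivity (the clinical context favours not
#' missing CFAE), then toward higher specificity, then deterministically by
#' threshold order.
#'
#' @param roc A [roc_curve()] object.
#' @return List: `threshold` (score units, applied with the curve's
#'   direction), `sensitivity`, `one_minus_specificity`, `distance_to_corner`.
#' @export
optimum_point <- function(roc) {
  p <- roc$points
  d <- sqrt((1 - p$sensitivity)^2 + p$one_minus_specificity^2)
  ord <- order(d, -p$sensitivity, p$one_minus_specificity)
  i <- ord[1]
  list(threshold = p$threshold[i], sensitivity = p$sensitivity[i],
       one_minus_specificity = p$one_minus_specificity[i],
       distance_to_corner = d[i])
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUROC = %.4f (direction: %s-is-positive, %d+/%d-)\n",
              nrow(x$points), x$auroc, x$direction, x$n_pos, x$n_neg))
  invisible(x)
}

#' Cross-tabulate two per-AEG CFAE classifications
#'
#' Builds the 2x2 agreement table between two binary classifications of the
#' same AEGs (the four quadrants of the index-vs-index scatter), with derived
#' proportions, observed agreement, and Cohen's kappa.
#'
#' @param flags_a,flags_b Logical CFAE flags, aligned by AEG.
#' @param ids Optional AEG ids for both vectors; when given for both sides
#'   they must match exactly (alignment check).
#' @param ids_b Optional ids of `flags_b` to check against `ids`.
#' @return An `agreement_table`: counts `n_both_cfae`, `n_a_only`,
#'   `n_b_only`, `n_neither`, plus `total`, `proportion_a`, `proportion_b`,
#'   `observed_agreement`, `kappa`.
#' @export
quadrant_table <- function(flags_a, flags_b, ids = NULL, ids_b = NULL) {
  if (!is.null(ids) && !is.null(ids_b) && !identical(as.character(ids),
                                                     as.character(ids_b)))
    stop("alignment error: AEG ids of the two classifications differ",
         call. = FALSE)
  flags_a <- as.logical(flags_a); flags_b <- as.logical(flags_b)
  if (length(flags_a) != length(flags_b))
    stop("alignment error: classifications have different lengths", call. = FALSE)
  agreement_table(n_both_cfae = sum(flags_a & flags_b),
                  n_a_only = sum(flags_a & !flags_b),
                  n_b_only = sum(!flags_a & flags_b),
                  n_neither = sum(!flags_a & !flags_b))
}

#' Construct a 2x2 agreement table from its four counts
#'
#' @param n_both_cfae,n_a_only,n_b_only,n_neither Nonnegative counts: both
#'   systems CFAE, system A only, system B only, neither.
#' @return An `agreement_table` (see [quadrant_table()]).
#' @export
agreement_table <- function(n_both_cfae, n_a_only, n_b_only, n_neither) {
  cells <- c(n_both_cfae, n_a_only, n_b_only, n_neither)
  stopifnot(all(cells >= 0))
  total <- sum(cells)
  structure(list(n_both_cfae = n_both_cfae, n_a_only = n_a_only,
                 n_b_only = n_b_only, n_neither = n_neither, total = total,
                 proportion_a = (n_both_cfae + n_a_only) / total,
                 proportion_b = (n_both_cfae + n_b_only) / total,
                 observed_agreement = (n_both_cfae + n_neither) / total,
                 kappa = cohen_kappa(n_both_cfae, n_a_only, n_b_only,
                                     n_neither)$kappa),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf(paste0("<agreement_table> n = %d\n",
                     "  both CFAE %d | A only %d | B only %d | neither %d\n",
                     "  P(A) = %.3f, P(B) = %.3f, observed agreement = %.3f, kappa = %.3f\n"),
              x$total, x$n_both_cfae, x$n_a_only, x$n_b_only, x$n_neither,
              x$proportion_a, x$proportion_b, x$observed_agreement, x$kappa))
  invisible(x)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement kappa = (po - pe) / (1 - pe) with standard 2x2
#' marginals. When pe = 1 (both raters constant and equal, i.e. no marginal
#' variance) kappa is defined as 0. Band labels follow the convention
#' 0 <= kappa < 0.4 marginal, 0.4 <= kappa <= 0.75 good, kappa > 0.75
#' excellent agreement.
#'
#' @param x Either an `agreement_table`, a length-4 numeric vector
#'   (both, a-only, b-only, neither), a 2x2 matrix, or the `n_both_cfae`
#'   count with the remaining three counts in the other arguments.
#' @param n_a_only,n_b_only,n_neither Remaining counts when `x` is scalar.
#' @return List: `kappa`, `po` (observed agreement), `pe` (chance
#'   agreement), `band`.
#' @export
cohen_kappa <- function(x, n_a_only = NULL, n_b_only = NULL, n_neither = NULL) {
  if (inherits(x, "agreement_table")) {
    cells <- c(x$n_both_cfae, x$n_a_only, x$n_b_only, x$n_neither)
  } else if (is.matrix(x)) {
    stopifnot(all(dim(x) == 2L))
    cells <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  } else if (length(x) == 4L) {
    cells <- as.numeric(x)
  } else {
    cells <- c(x, n_a_only, n_b_only, n_neither)
  }
  stopifnot(length(cells) == 4L, all(cells >= 0))
  n <- sum(cells)
  if (n == 0) stop("empty-input error: agreement table has no observations",
                   call. = FALSE)
  po <- (cells[1] + cells[4]) / n
  pa <- (cells[1] + cells[2]) / n    # rater A positive
  pb <- (cells[1] + cells[3]) / n    # rater B positive
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) 0 else (po - pe) / (1 - pe)
  list(kappa = kappa, po = po, pe = pe, band = kappa_band(kappa))
}

kappa_band <- function(kappa) {
  ifelse(kappa > 0.75, "excellent", ifelse(kappa >= 0.4, "good", "marginal"))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware).
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant input vector", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Two-sided continuity-corrected chi-square with 1 degree of freedom.
#'
#' @param tab 2x2 matrix of counts (or length-4 vector, filled by row).
#' @return List: `statistic`, `p_value`, `df`.
#' @export
yates_chi_square <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate-input error: zero marginal in 2x2 table", call. = FALSE)
  ht <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Mann-Whitney U test
#'
#' Exact enumeration for small tie-free samples (both n <= 20), otherwise the
#' tie-corrected normal approximation, via [stats::wilcox.test()]. The
#' reported `U` is the U statistic of `x` (so `U_x + U_y = n_x * n_y`).
#'
#' @param x,y Numeric samples.
#' @return List: `U`, `p_value`, `exact` (whether the exact distribution was
#'   used).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(length(x), length(y)) <= 20L
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Friedman test with Dunn's pairwise correction
#'
#' Nonparametric test for k related samples measured over n blocks. The
#' statistic is the tie-corrected Friedman rank statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (\sum_{ij} r_{ij}^2 - nk(k+1)^2/4)}
#' referred to a chi-square with k-1 df. Pairwise follow-up uses Dunn's
#' z-tests on mean ranks, z = (Rbar_i - Rbar_j) / sqrt(k(k+1)/(6n)), with
#' Bonferroni scaling over all k(k-1)/2 comparisons.
#'
#' @param blocks n x k numeric matrix (rows = blocks, columns = groups).
#' @return List: `statistic`, `df`, `p_value`, `mean_ranks`, `pairwise`
#'   (data frame `group_i`, `group_j`, `z`, `p_raw`, `p_adj`).
#' @export
friedman_dunn <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks); k <- ncol(blocks)
  if (k < 2L) stop("parameter error: need at least 2 groups", call. = FALSE)
  if (n < 2L) stop("parameter error: need at least 2 blocks", call. = FALSE)
  r <- t(apply(blocks, 1, rank))
  Rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  stat <- if (denom <= 0) 0 else num / denom   # all blocks fully tied -> 0
  df <- k - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  rbar <- Rj / n
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  m <- ncol(pairs)
  cn <- colnames(blocks)
  if (is.null(cn)) cn <- as.character(seq_len(k))
  pairwise <- data.frame(group_i = cn[pairs[1, ]], group_j = cn[pairs[2, ]],
                         z = z, p_raw = p_raw, p_adj = pmin(1, p_raw * m))
  list(statistic = stat, df = df, p_value = p,
       mean_ranks = stats::setNames(rbar, cn), pairwise = pairwise)
}
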