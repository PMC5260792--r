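# Rank-based comparators: QPSP hit-rate profiles, SNET/FSNET class-weighted
# complex scores, and PFSNET paired deltas.

#' Two-sample t statistic (pooled or Welch)
#'
#' The pooled-variance form is the statistic QPSP applies to hit-rate
#' vectors; the Welch form (Satterthwaite df) is used by the SNET family.
#' Degenerate inputs follow fixed conventions: zero pooled variance with
#' equal means gives t = 0, p = 1; zero variance with unequal means gives
#' the smallest representable positive p.
#'
#' @param xs,ys Numeric vectors, each of length >= 2.
#' @param pooled Pooled-variance t (`TRUE`) or Welch (`FALSE`).
#' @param alternative `"two.sided"` (default) or `"greater"` (upper tail of
#'   `mean(xs) - mean(ys)`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(xs, ys, pooled = TRUE, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(xs) < 2L || length(ys) < 2L) stop("need at least 2 observations per group")
  r <- .row_t(rbind(c(xs, ys)), seq_along(xs), length(xs) + seq_along(ys), pooled = pooled)
  p <- if (alternative == "two.sided") r$p_two_sided else r$p_greater
  list(statistic = unname(r$t), df = unname(r$df), p_value = unname(p))
}

#' QPSP hit-rate profiles
#'
#' For each sample S and complex C, the hit-rate is the weight-modulated
#' overlap `H(S, C) = sum_{g in C, measured} w(g, S) / |C measured|`, using
#' fractional fuzzy weights. The per-sample vector of hit-rates over all
#' complexes is the sample's complex-based signature profile.
#'
#' @param weights Weight matrix from the `fuzzy_fractional` scheme
#'   ([compute_weights()]).
#' @param complexes Named list of complexes (pre-filtered).
#' @return Matrix of hit-rates, complexes x samples.
#' @export
qpsp_hit_rates <- function(weights, complexes) {
  scheme <- attr(weights, "scheme")
  if (is.null(scheme) || scheme$name != "fuzzy_fractional")
    stop("QPSP hit-rates require fuzzy_fractional weights")
  ind <- .complex_indicator(complexes, rownames(weights))
  sizes <- rowSums(ind)
  if (any(sizes == 0)) stop("complex with no measured member")
  (ind %*% weights) / sizes
}

#' QPSP complex test
#'
#' Per complex, the hit-rates of class-1 samples are compared against those
#' of class-2 samples with the pooled-variance two-sample t statistic;
#' two-sided p below `alpha` selects the complex.
#'
#' @inheritParams he_test
#' @param alpha1,alpha2,n_bins Weight-scheme parameters (see
#'   [weight_scheme()]).
#' @return Data frame in the common result layout; `statistic` is the t
#'   score (class 1 minus class 2); `direction` reports the sign for
#'   selected complexes.
#' @export
qpsp_test <- function(matrix, classes, complexes, alpha = 0.05,
                      alpha1 = 0.10, alpha2 = 0.20, n_bins = 4L) {
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix), min_per_class = 2L)
  .check_complex_coverage(complexes, matrix)
  W <- compute_weights(matrix, weight_scheme("fuzzy_fractional", alpha1, alpha2, n_bins))
  H <- qpsp_hit_rates(W, complexes)
  i1 <- which(cl$labels == cl$class1)
  i2 <- which(cl$labels == cl$class2)
  tt <- .row_t(H, i1, i2, pooled = TRUE)
  selected <- tt$p_two_sided < alpha
  data.frame(complex_id = names(complexes), method = "qpsp",
             statistic = unname(tt$t), p_value = unname(tt$p_two_sided),
             direction = ifelse(selected,
                                ifelse(tt$t > 0, "up_in_class1", "up_in_class2"),
                                "none"),
             selected = selected, row.names = NULL, stringsAsFactors = FALSE)
}

#' Class-conditional top-rank proportions (beta table)
#'
#' `beta(g, C) = sum_{p in C} fs(g, p) / |C|`: with binary weights this is
#' the proportion of class-C samples having protein g among their top-alpha
#' ranks; with fuzzy weights it is the mean fuzzy membership.
#'
#' @param weights Weight matrix (binary for SNET, fuzzy_fractional for
#'   FSNET/PFSNET).
#' @param classes Named character vector of class labels.
#' @return Matrix proteins x classes of beta values in [0, 1] (for
#'   fractional/binary schemes).
#' @export
snet_beta <- function(weights, classes) {
  cl <- .check_classes(classes, colnames(weights))
  vapply(c(cl$class1, cl$class2), function(lv) {
    rowMeans(weights[, cl$labels == lv, drop = FALSE])
  }, numeric(nrow(weights)))
}

#' SNET complex score for one sample
#'
#' `score(S, p, C) = sum_{g in S, measured} fs(g, p) * beta(g, C)`: the
#' complex's weight in sample p, attenuated by how consistently each member
#' sits in the top ranks of the weighting class C.
#'
#' @param complex Character vector of member protein ids.
#' @param sample Sample id (column of `weights`).
#' @param weights Weight matrix.
#' @param beta Beta table from [snet_beta()].
#' @param weighting_class Class label choosing the beta column.
#' @return Single numeric score.
#' @export
snet_score <- function(complex, sample, weights, beta, weighting_class) {
  members <- intersect(complex, rownames(weights))
  sum(weights[members, sample] * beta[members, weighting_class])
}

# Complex-by-sample score matrix for one weighting class (vectorised
# equivalent of snet_score over all complexes and samples).
.snet_scores <- function(ind, weights, beta_col) {
  ind %*% (weights * beta_col)
}

#' SNET / FSNET complex test
#'
#' For each direction (weighting class X, other class Y), per-complex scores
#' of X samples are compared against those of Y samples (both scored with
#' X's beta table) by a one-sided Welch t-test in the upper 5% tail
#' (Welch-Satterthwaite df). The selected set is the union over both
#' directions. `variant = "snet"` uses binary top-alpha1 weights,
#' `"fsnet"` fractional fuzzy weights.
#'
#' @inheritParams qpsp_test
#' @param variant `"snet"` or `"fsnet"`.
#' @return Data frame in the common result layout plus per-direction columns
#'   `p_up_class1` and `p_up_class2`; `p_value` is the smaller of the two
#'   one-sided p-values and `statistic` the corresponding t.
#' @export
snet_family_test <- function(matrix, classes, complexes, variant = c("snet", "fsnet"),
                             alpha = 0.05, alpha1 = 0.10, alpha2 = 0.20, n_bins = 4L) {
  variant <- match.arg(variant)
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix), min_per_class = 2L)
  .check_complex_coverage(complexes, matrix)
  scheme <- if (variant == "snet") weight_scheme("binary", alpha1, alpha2, n_bins)
            else weight_scheme("fuzzy_fractional", alpha1, alpha2, n_bins)
  W <- compute_weights(matrix, scheme)
  beta <- snet_beta(W, cl$labels)
  ind <- .complex_indicator(complexes, rownames(matrix))
  i1 <- which(cl$labels == cl$class1)
  i2 <- which(cl$labels == cl$class2)
  s1 <- .snet_scores(ind, W, beta[, cl$class1])
  s2 <- .snet_scores(ind, W, beta[, cl$class2])
  t1 <- .row_t(s1, i1, i2, pooled = FALSE)   # X = class1, weighted by class1
  t2 <- .row_t(s2, i2, i1, pooled = FALSE)   # X = class2, weighted by class2
  .two_direction_result(names(complexes), variant, t1$t, t1$p_greater,
                        t2$t, t2$p_greater, alpha)
}

#' PFSNET paired-delta complex test
#'
#' For every sample p in either class, `delta(S, p) = score(S, p, X) -
#' score(S, p, Y)`; if the complex is irrelevant to the class contrast the
#' deltas centre on zero. A one-sample t statistic (mean/se over all samples,
#' df = n - 1) is tested in the upper 5% tail for each direction; the
#' selected set is the union. Fractional fuzzy weights are used throughout.
#'
#' @inheritParams qpsp_test
#' @return Data frame as in [snet_family_test()].
#' @export
pfsnet_test <- function(matrix, classes, complexes, alpha = 0.05,
                        alpha1 = 0.10, alpha2 = 0.20, n_bins = 4L) {
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix), min_per_class = 1L)
  if (ncol(matrix) < 3L) stop("PFSNET needs at least 3 samples in total")
  .check_complex_coverage(complexes, matrix)
  W <- compute_weights(matrix, weight_scheme("fuzzy_fractional", alpha1, alpha2, n_bins))
  beta <- snet_beta(W, cl$labels)
  ind <- .complex_indicator(complexes, rownames(matrix))
  delta <- .snet_scores(ind, W, beta[, cl$class1]) -
           .snet_scores(ind, W, beta[, cl$class2])
  n <- ncol(delta)
  m <- rowMeans(delta)
  se <- sqrt(rowSums((delta - m)^2) / (n - 1L) / n)
  t <- m / se
  zero <- se == 0
  t[zero & m == 0] <- 0
  t[zero & m > 0] <- Inf
  t[zero & m < 0] <- -Inf
  p1 <- stats::pt(t, n - 1L, lower.tail = FALSE)
  p2 <- stats::pt(-t, n - 1L, lower.tail = FALSE)
  p1[zero & m > 0] <- .Machine$double.xmin
  p2[zero & m < 0] <- .Machine$double.xmin
  p1[zero & m < 0] <- 1
  p2[zero & m > 0] <- 1
  p1[zero & m == 0] <- 1
  p2[zero & m == 0] <- 1
  .two_direction_result(names(complexes), "pfsnet", t, p1, -t, p2, alpha)
}

# Fold two one-sided direction tests into the common result layout.
.two_direction_result <- function(ids, method, t1, p1, t2, p2, alpha) {
  sel1 <- p1 < alpha
  sel2 <- p2 < alpha
  selected <- sel1 | sel2
  use1 <- p1 <= p2
  data.frame(complex_id = ids, method = method,
             statistic = ifelse(use1, t1, t2),
             p_value = pmin(p1, p2),
             direction = ifelse(!selected, "none",
                                ifelse(use1, "up_in_class1", "up_in_class2")),
             selected = selected,
             p_up_class1 = unname(p1), p_up_class2 = unname(p2),
             row.names = NULL, stringsAsFactors = FALSE)
}
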