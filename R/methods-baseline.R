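# Classical comparators: hypergeometric enrichment (t-test pre-selection +
# hypergeometric upper tail) and the direct-group two-sample KS gene-set test.

#' Hypergeometric upper-tail probability
#'
#' Given `N` proteins of which `B` belong to a complex, and a differential
#' list of size `n` overlapping the complex in `b` proteins, returns the
#' exact probability of an overlap of `b` or more by chance:
#' \deqn{P(X \ge b) = \sum_{i=b}^{\min(n,B)} \binom{n}{i}\binom{N-n}{B-i} / \binom{N}{B}}
#' Terms are accumulated in log space (via `lchoose`), so large universes do
#' not overflow.
#'
#' @param N Total number of proteins in the universe.
#' @param B Complex size within the universe.
#' @param n Differential-list size.
#' @param b Observed overlap.
#' @return A p-value in (0, 1].
#' @export
hypergeom_tail <- function(N, B, n, b) {
  if (B > N || n > N) stop("B and n must not exceed N")
  if (b < 0 || b > min(n, B)) stop("b out of range: need 0 <= b <= min(n, B)")
  if (b == 0L) return(1)
  i <- b:min(n, B)
  lp <- lchoose(n, i) + lchoose(N - n, B - i) - lchoose(N, B)
  min(1, exp(.logsumexp(lp)))
}

#' Hypergeometric enrichment test (HE)
#'
#' The two-stage classical procedure: (1) per-protein two-sample t-tests
#' between classes; proteins with p below `t_alpha` form the differential
#' list; (2) per complex, a hypergeometric upper-tail test of the overlap
#' between the differential list and the complex membership, over the
#' universe of all matrix proteins.
#'
#' @param matrix Expression matrix (proteins x samples).
#' @param classes Named character vector of class labels (two classes, at
#'   least 2 samples each).
#' @param complexes Named list of complexes (ideally pre-filtered with
#'   [filter_complexes()]).
#' @param t_alpha Stage-1 per-protein significance cutoff (default 0.05).
#' @param alpha Stage-2 complex-level cutoff (default 0.05).
#' @param pooled_t Use the pooled-variance t in stage 1 instead of Welch
#'   (default `FALSE`, i.e. Welch).
#' @param adjust P-value adjustment method for the complex-level p-values
#'   (see [stats::p.adjust()]); default `"none"`, matching the uncorrected
#'   0.05 convention of the method family.
#' @return Data frame with columns `complex_id`, `method`, `statistic`
#'   (the overlap `b`), `p_value`, `direction` (always `"none"`: HE is
#'   undirected), `selected`.
#' @export
he_test <- function(matrix, classes, complexes, t_alpha = 0.05, alpha = 0.05,
                    pooled_t = FALSE, adjust = "none") {
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix), min_per_class = 2L)
  .check_complex_coverage(complexes, matrix)
  i1 <- which(cl$labels == cl$class1)
  i2 <- which(cl$labels == cl$class2)
  tt <- .row_t(matrix, i1, i2, pooled = pooled_t)
  diff_ids <- rownames(matrix)[tt$p_two_sided < t_alpha]
  N <- nrow(matrix)
  n <- length(diff_ids)
  ids <- rownames(matrix)
  res <- lapply(names(complexes), function(nm) {
    members <- intersect(complexes[[nm]], ids)
    B <- length(members)
    b <- length(intersect(members, diff_ids))
    p <- if (n == 0L) 1 else hypergeom_tail(N, B, n, b)
    data.frame(complex_id = nm, method = "he", statistic = b, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$direction <- "none"
  out$selected <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

# Asymptotic two-sample Kolmogorov survival function Q(lambda).
.kolmogorov_q <- function(lambda) {
  vapply(lambda, function(l) {
    if (l <= 0) return(1)
    k <- 1:100
    q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * l^2))
    min(1, max(0, q))
  }, numeric(1L))
}

# Critical multiplier c(alpha): the printed constant 1.36 at alpha = 0.05,
# otherwise inverted numerically from the asymptotic distribution.
.ks_critical <- function(alpha) {
  if (isTRUE(all.equal(alpha, 0.05))) return(1.36)
  stats::uniroot(function(l) .kolmogorov_q(l) - alpha, c(1e-4, 5))$root
}

#' Two-sample Kolmogorov-Smirnov statistic on ranks
#'
#' Computes `ks = max_x |F_D(x) - F_D'(x)|` where `F_D` and `F_D'` are the
#' empirical distribution functions of the in-set and out-of-set rank
#' samples, and the rejection threshold
#' `c(alpha) * sqrt((|D| + |D'|) / (|D| * |D'|))` with `c(0.05) = 1.36`.
#'
#' @param in_set_values Numeric ranks (or any scores) of the in-complex set D.
#' @param out_set_values Ranks of the out-of-complex set D'.
#' @param alpha Significance level (default 0.05).
#' @return List of class `"ks_result"`: `ks`, `threshold`, `significant`,
#'   `p_value` (asymptotic), `n_in`, `n_out`.
#' @export
ks_statistic <- function(in_set_values, out_set_values, alpha = 0.05) {
  m <- length(in_set_values); n <- length(out_set_values)
  if (m < 1L || n < 1L) stop("both sets must be non-empty")
  x <- sort(unique(c(in_set_values, out_set_values)))
  Fd <- findInterval(x, sort(in_set_values)) / m
  Fo <- findInterval(x, sort(out_set_values)) / n
  ks <- max(abs(Fd - Fo))
  threshold <- .ks_critical(alpha) * sqrt((m + n) / (m * n))
  structure(list(ks = ks, threshold = threshold,
                 significant = ks >= threshold,
                 p_value = .kolmogorov_q(sqrt(m * n / (m + n)) * ks),
                 n_in = m, n_out = n),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f (threshold %.4f, |D| = %d, |D'| = %d) %s\n",
              x$ks, x$threshold, x$n_in, x$n_out,
              if (x$significant) "*" else ""))
  invisible(x)
}

#' Direct-group KS gene-set enrichment test (GSEA variant)
#'
#' Per protein, a signed class-contrast score (the Welch t statistic,
#' class 1 minus class 2) is computed and all proteins are ranked by it. Per
#' complex, the ranks of member proteins (D) are compared against the ranks
#' of all other proteins (D') with the two-sample KS statistic; the complex
#' is selected when `ks` reaches the critical threshold (see
#' [ks_statistic()]). No t-test pre-selection is involved.
#'
#' @inheritParams he_test
#' @param alpha Complex-level significance level (default 0.05).
#' @return Data frame in the common result layout; `statistic` is the KS
#'   statistic, `p_value` the asymptotic KS p-value, `direction` `"none"`.
#' @export
gsea_test <- function(matrix, classes, complexes, alpha = 0.05) {
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix), min_per_class = 2L)
  .check_complex_coverage(complexes, matrix)
  i1 <- which(cl$labels == cl$class1)
  i2 <- which(cl$labels == cl$class2)
  contrast <- .row_t(matrix, i1, i2, pooled = FALSE)$t
  contrast[!is.finite(contrast)] <- sign(contrast[!is.finite(contrast)]) * .Machine$double.xmax
  rks <- rank(contrast, ties.method = "average")
  ids <- rownames(matrix)
  crit <- .ks_critical(alpha)
  res <- lapply(names(complexes), function(nm) {
    inset <- ids %in% complexes[[nm]]
    if (all(inset)) stop("complex '", nm, "' covers every matrix protein (D' empty)")
    m <- sum(inset); n <- sum(!inset)
    ksr <- ks_statistic(rks[inset], rks[!inset], alpha = alpha)
    data.frame(complex_id = nm, method = "gsea", statistic = ksr$ks,
               p_value = ksr$p_value, direction = "none",
               selected = ksr$ks >= crit * sqrt((m + n) / (m * n)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Every complex must have at least one measured member; empty complexes are
# a sign that filter_complexes() was skipped.
.check_complex_coverage <- function(complexes, matrix) {
  if (!length(complexes)) stop("empty complex set")
  if (is.null(names(complexes)) || any(!nzchar(names(complexes))))
    stop("complexes must be a named list")
  ids <- rownames(matrix)
  bad <- names(complexes)[vapply(complexes, function(m) !any(m %in% ids), logical(1L))]
  if (length(bad))
    stop("complexes with no measured member (run filter_complexes first): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}
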