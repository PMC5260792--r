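#' Construct a rank-weighting scheme
#'
#' The three weighting schemes used by the complex-based methods all derive
#' from per-sample abundance percentile ranks:
#' \describe{
#'   \item{`binary`}{1 for proteins in the top `alpha1` fraction of a sample,
#'     0 otherwise (SNET, and the unweighted FishNET variant).}
#'   \item{`fuzzy_fractional`}{1 in the top `alpha1`; the band
#'     `(alpha1, alpha2]` is split into `n_bins` equal-width bins carrying
#'     descending weights 0.8, 0.6, 0.4, 0.2 (defaults); 0 below
#'     (QPSP, FSNET, PFSNET).}
#'   \item{`fuzzy_integer`}{5 in the top `alpha1`; bin weights 4, 3, 2, 1;
#'     0 below (Fuzzy-FishNET). Equals the fractional scheme times 5 at the
#'     defaults.}
#' }
#'
#' @param name One of `"binary"`, `"fuzzy_fractional"`, `"fuzzy_integer"`.
#' @param alpha1 Top-rank fraction receiving the full weight (default 0.10).
#' @param alpha2 Extended fraction; ranks in `(alpha1, alpha2]` receive
#'   binned weights (default 0.20). Ignored by the binary scheme.
#' @param n_bins Number of equal-width bins between `alpha1` and `alpha2`
#'   (default 4).
#' @return An object of class `"weight_scheme"`.
#' @export
weight_scheme <- function(name = c("fuzzy_integer", "fuzzy_fractional", "binary"),
                          alpha1 = 0.10, alpha2 = 0.20, n_bins = 4L) {
  name <- match.arg(name)
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 <= 1))
    stop("need 0 < alpha1 < alpha2 <= 1")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  structure(list(name = name, alpha1 = alpha1, alpha2 = alpha2,
                 n_bins = as.integer(n_bins)),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight scheme:", x$name,
      sprintf("(alpha1 = %g, alpha2 = %g, bins = %d)\n", x$alpha1, x$alpha2, x$n_bins))
  invisible(x)
}

#' Per-sample abundance percentile ranks
#'
#' Within each sample, proteins with positive abundance are ranked from the
#' most abundant down; the percentile of a protein is (ordinal rank) /
#' (number of positive proteins in that sample), so "top 10%" means
#' percentile <= 0.10. Proteins with zero abundance (not observed) are
#' assigned percentile 1 and never compete for top ranks. Ties are broken by
#' protein id in radix (byte) order, making ranks deterministic across runs
#' and platforms.
#'
#' @param matrix Non-negative expression matrix (proteins x samples).
#' @return Matrix of percentiles in (0, 1], same dimensions and dimnames as
#'   the input, with a logical `"zero"` attribute marking unobserved cells.
#' @export
percentile_ranks <- function(matrix) {
  .check_matrix(matrix)
  ids <- rownames(matrix)
  pct <- matrix
  pct[] <- 1
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    pos <- which(v > 0)
    if (!length(pos)) stop("sample '", colnames(matrix)[j], "' has no positive values")
    ord <- pos[order(-v[pos], ids[pos], method = "radix")]
    pct[ord, j] <- seq_along(ord) / length(ord)
  }
  attr(pct, "zero") <- matrix == 0
  pct
}

#' Assign rank-based weights under a scheme
#'
#' Maps percentile ranks (from [percentile_ranks()]) to weights. The top
#' region is `[0, alpha1]`; bins over `(alpha1, alpha2]` are half-open
#' `(alpha1 + (k-1) w, alpha1 + k w]` with `w = (alpha2 - alpha1) / n_bins`,
#' so the weight levels partition the percentile axis. Unobserved (zero
#' abundance) proteins always weigh 0.
#'
#' @param ranks Percentile matrix from [percentile_ranks()].
#' @param scheme A [weight_scheme()].
#' @return Weight matrix (same shape) with the scheme stored in the
#'   `"scheme"` attribute.
#' @export
assign_weights <- function(ranks, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  eps <- 1e-9
  top_w <- if (scheme$name == "fuzzy_integer") scheme$n_bins + 1 else 1
  w <- ranks
  w[] <- 0
  top <- ranks <= scheme$alpha1 + eps
  w[top] <- top_w
  if (scheme$name != "binary") {
    mid <- !top & ranks <= scheme$alpha2 + eps
    if (any(mid)) {
      bw <- (scheme$alpha2 - scheme$alpha1) / scheme$n_bins
      k <- ceiling((ranks[mid] - scheme$alpha1) / bw - eps)
      k <- pmin(pmax(k, 1), scheme$n_bins)
      wt <- scheme$n_bins + 1 - k
      if (scheme$name == "fuzzy_fractional") wt <- wt / (scheme$n_bins + 1)
      w[mid] <- wt
    }
  }
  zero <- attr(ranks, "zero")
  if (!is.null(zero)) w[zero] <- 0
  attr(w, "zero") <- NULL
  attr(w, "scheme") <- scheme
  w
}

#' Compute rank weights for an expression matrix
#'
#' Convenience wrapper: `assign_weights(percentile_ranks(matrix), scheme)`.
#'
#' @inheritParams percentile_ranks
#' @inheritParams assign_weights
#' @return Weight matrix with `"scheme"` attribute.
#' @export
compute_weights <- function(matrix, scheme = weight_scheme()) {
  assign_weights(percentile_ranks(matrix), scheme)
}
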