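# Ground-truth-bearing synthetic data: multiplicative spike-in of
# differential proteins, pseudo-class construction from a single-condition
# matrix, expression-correlated pseudo-complexes at controlled purity, and
# label shuffling for null experiments.

#' Simulation parameters
#'
#' Defaults follow the benchmark protocol the package implements: 20% of
#' proteins are differential, with multiplicative effect sizes drawn
#' uniformly from {0.2, 0.5, 0.8, 1.0, 2.0} and applied in one class only.
#'
#' @param diff_fraction Fraction of proteins made differential (default 0.20).
#' @param effect_sizes Candidate effect sizes `p`; a spiked value becomes
#'   `SC * (1 + p)` (default `c(0.2, 0.5, 0.8, 1.0, 2.0)`).
#' @param n_replicate_datasets Number of replicate datasets a full benchmark
#'   generates (default 100; benchmark drivers may scale this down).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return Object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(diff_fraction = 0.20,
                            effect_sizes = c(0.2, 0.5, 0.8, 1.0, 2.0),
                            n_replicate_datasets = 100L, seed = NULL) {
  if (!(diff_fraction > 0 && diff_fraction < 1)) stop("diff_fraction must be in (0, 1)")
  if (any(effect_sizes <= 0)) stop("effect sizes must be positive")
  structure(list(diff_fraction = diff_fraction, effect_sizes = effect_sizes,
                 n_replicate_datasets = as.integer(n_replicate_datasets),
                 seed = seed),
            class = "simulation_spec")
}

#' Pseudo-complex parameters
#'
#' @param n_diff_complexes Number of differential pseudo-complexes (an equal
#'   number of non-differential ones is always built).
#' @param purity Fraction of each differential pseudo-complex that is truly
#'   differential, in (0, 1]; the protocol's levels are 1.0, 0.75 and 0.5.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return Object of class `"pseudo_complex_spec"`.
#' @export
pseudo_complex_spec <- function(n_diff_complexes, purity = 1.0, seed = NULL) {
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  if (n_diff_complexes < 1L) stop("need at least one differential pseudo-complex")
  structure(list(n_diff_complexes = as.integer(n_diff_complexes),
                 purity = purity, seed = seed),
            class = "pseudo_complex_spec")
}

#' Generate a base spectral-count-like matrix
#'
#' Synthesises a single-condition count matrix for use as spike-in
#' substrate: each protein draws a log-normal mean abundance and each cell
#' is Poisson around it, giving the right-skewed, zero-inflated-at-the-
#' low-end shape of spectral counts. The parameters are artifact choices
#' for a plausible screen, not estimates of any particular instrument.
#'
#' @param n_proteins,n_samples Matrix dimensions.
#' @param meanlog,sdlog Log-normal parameters of the per-protein mean
#'   (defaults `log(10)` and 1.2).
#' @param seed Integer seed.
#' @return Expression matrix with zero-padded protein ids (`P0001`, ...)
#'   and sample ids (`S01`, ...).
#' @export
simulate_base_matrix <- function(n_proteins = 1000L, n_samples = 12L,
                                 meanlog = log(10), sdlog = 1.2, seed = NULL) {
  .with_seed(seed, {
    lambda <- stats::rlnorm(n_proteins, meanlog = meanlog, sdlog = sdlog)
    m <- matrix(stats::rpois(n_proteins * n_samples, rep(lambda, n_samples)),
                nrow = n_proteins, ncol = n_samples)
    wp <- max(4L, nchar(as.character(n_proteins)))
    ws <- max(2L, nchar(as.character(n_samples)))
    dimnames(m) <- list(sprintf(paste0("P%0", wp, "d"), seq_len(n_proteins)),
                        sprintf(paste0("S%0", ws, "d"), seq_len(n_samples)))
    storage.mode(m) <- "double"
    m
  })
}

#' Spike differential proteins into one class
#'
#' Selects `round(diff_fraction * P)` proteins uniformly without
#' replacement; each gets an effect size `p` drawn uniformly from
#' `effect_sizes` and its counts in `which_class` samples are multiplied by
#' `(1 + p)`. All other cells are untouched (bitwise).
#'
#' @param base Expression matrix.
#' @param classes Named character vector of class labels covering the
#'   samples of `base`.
#' @param spec A [simulation_spec()] (its `seed` drives the draw).
#' @param which_class Label of the class receiving the effects.
#' @return Object of class `"simulated_dataset"`: list with `matrix`,
#'   `classes`, `truth_proteins`, `effects` (named effect sizes) and
#'   `spiked_class`.
#' @export
spike_in <- function(base, classes, spec = simulation_spec(), which_class) {
  .check_matrix(base)
  cl <- .check_classes(classes, colnames(base))
  if (!which_class %in% c(cl$class1, cl$class2)) stop("unknown class: ", which_class)
  P <- nrow(base)
  n_diff <- round(spec$diff_fraction * P)
  if (n_diff < 1L) stop("diff_fraction * proteins < 1")
  .with_seed(spec$seed, {
    truth <- sort(sample(rownames(base), n_diff))
    eff <- stats::setNames(sample(spec$effect_sizes, n_diff, replace = TRUE), truth)
    m <- base
    spiked_cols <- names(cl$labels)[cl$labels == which_class]
    m[truth, spiked_cols] <- m[truth, spiked_cols] * (1 + eff)
    structure(list(matrix = m, classes = cl$labels, truth_proteins = truth,
                   effects = eff, spiked_class = which_class),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset: %d proteins x %d samples, %d differential (spiked in '%s')\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth_proteins), x$spiked_class))
  invisible(x)
}

#' Build a pseudo-class dataset from single-condition samples
#'
#' Randomly halves an even set of same-condition samples into a pseudo
#' control and pseudo test class, then spikes differential proteins into
#' the test half ([spike_in()]). With 12 input samples this yields the
#' 6 control + 6 artificial test layout of the benchmark protocol.
#'
#' @param controls Expression matrix of same-condition samples (even count,
#'   at least 4).
#' @param spec A [simulation_spec()].
#' @param labels Length-2 character vector naming the pseudo classes
#'   (default `c("control", "test")`; effects go into the second).
#' @return A `"simulated_dataset"`.
#' @export
make_pseudo_class_dataset <- function(controls, spec = simulation_spec(),
                                      labels = c("control", "test")) {
  .check_matrix(controls)
  ns <- ncol(controls)
  if (ns %% 2L != 0L) stop("even number of samples required, got ", ns)
  if (ns < 4L) stop("need at least 4 samples")
  .with_seed(spec$seed, {
    test_half <- sample(colnames(controls), ns %/% 2L)
    cls <- stats::setNames(ifelse(colnames(controls) %in% test_half,
                                  labels[2L], labels[1L]),
                           colnames(controls))
    inner <- spec
    inner$seed <- if (is.null(spec$seed)) NULL else
      (spec$seed * 69069L + 1L) %% .Machine$integer.max
    spike_in(controls, cls, inner, which_class = labels[2L])
  })
}

# Order proteins by Ward-linkage leaf order on Euclidean distances across
# all samples, then split into k contiguous near-equal chunks.
.cluster_chunks <- function(mat, ids, k) {
  if (length(ids) > 2L) {
    hc <- stats::hclust(stats::dist(mat[ids, , drop = FALSE]), method = "ward.D2")
    ids <- ids[hc$order]
  }
  n <- length(ids)
  base_sz <- n %/% k
  extra <- n %% k
  sizes <- rep(base_sz, k) + c(rep(1L, extra), rep(0L, k - extra))
  split(ids, rep(seq_len(k), times = sizes))
}

#' Build expression-correlated pseudo-complexes with ground truth
#'
#' Differential (truth) proteins are ordered by the leaf order of Ward
#' hierarchical clustering on pairwise Euclidean distances over all
#' samples, so co-expressed proteins are adjacent, then split into
#' contiguous near-equal chunks: the differential pseudo-complexes. An
#' equal number of non-differential proteins are sampled, ordered and split
#' the same way: the non-differential pseudo-complexes. At `purity < 1`,
#' `round((1 - purity) * size)` members of each differential pseudo-complex
#' are replaced by unused non-differential proteins (never ones already
#' placed in non-differential pseudo-complexes, so truth cannot leak).
#'
#' @param dataset A `"simulated_dataset"`, or any list with `matrix` and
#'   `truth_proteins` (a null dataset may designate truth proteins without
#'   spiking effects).
#' @param spec A [pseudo_complex_spec()].
#' @return Named complex list (`DC...` differential, `NC...`
#'   non-differential) with a `"truth"` attribute mapping complex id to
#'   `"differential"` / `"non_differential"`.
#' @export
build_pseudo_complexes <- function(dataset, spec) {
  stopifnot(inherits(spec, "pseudo_complex_spec"))
  mat <- dataset$matrix
  truth <- dataset$truth_proteins
  k <- spec$n_diff_complexes
  if (length(truth) < 3L * k)
    stop("need at least 3 truth proteins per differential pseudo-complex")
  nondiff_pool <- setdiff(rownames(mat), truth)
  if (length(nondiff_pool) < length(truth))
    stop("not enough non-differential proteins to mirror the differential set")
  .with_seed(spec$seed, {
    diff_chunks <- .cluster_chunks(mat, sort(truth), k)
    nd_sel <- sample(nondiff_pool, length(truth))
    nd_chunks <- .cluster_chunks(mat, sort(nd_sel), k)
    unused <- setdiff(nondiff_pool, nd_sel)
    if (spec$purity < 1) {
      for (i in seq_len(k)) {
        sz <- length(diff_chunks[[i]])
        n_repl <- round((1 - spec$purity) * sz)
        if (n_repl > 0L) {
          if (n_repl > length(unused))
            stop("not enough unused non-differential proteins for purity dilution")
          out_idx <- sample(sz, n_repl)
          repl <- sample(unused, n_repl)
          unused <- setdiff(unused, repl)
          diff_chunks[[i]][out_idx] <- repl
        }
      }
    }
    wd <- max(2L, nchar(as.character(k)))
    out <- c(diff_chunks, nd_chunks)
    names(out) <- c(sprintf(paste0("DC%0", wd, "d"), seq_len(k)),
                    sprintf(paste0("NC%0", wd, "d"), seq_len(k)))
    attr(out, "truth") <- stats::setNames(
      rep(c("differential", "non_differential"), each = k), names(out))
    out
  })
}

#' Shuffle class labels
#'
#' Permutes the label multiset over the same samples (class sizes are
#' conserved); the device behind null cross-validation and pseudo-class
#' false-positive experiments.
#'
#' @param classes Named character vector of class labels.
#' @param seed Integer seed.
#' @return Named character vector over the same sample ids.
#' @export
shuffle_labels <- function(classes, seed = NULL) {
  .with_seed(seed, stats::setNames(sample(unname(classes)), names(classes)))
}
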