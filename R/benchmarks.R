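# Evaluation machinery: precision/recall against pseudo-complex truth,
# selection-overlap metrics, resampling stability matrices, deterministic
# naive Bayes cross-validation, and pseudo-class false-positive rates.

#' Precision, recall and F-score against complex truth labels
#'
#' `TP` are selected differential complexes, `FP` selected non-differential
#' ones, `FN` differential complexes not selected. `Precision = TP/(TP+FP)`,
#' `Recall = TP/(TP+FN)`, `F = 2PR/(P+R)` (0 when `P + R = 0`; an undefined
#' precision or recall with empty denominator is reported as 0).
#'
#' @param selected Character vector of selected complex ids.
#' @param truth Named character vector mapping complex id to
#'   `"differential"` / `"non_differential"` (e.g. the `"truth"` attribute
#'   of [build_pseudo_complexes()] output).
#' @return List of class `"pr_summary"`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_score`.
#' @export
precision_recall_f <- function(selected, truth) {
  selected <- unique(selected)
  unknown <- setdiff(selected, names(truth))
  if (length(unknown))
    stop("selected ids without truth label: ", paste(unknown, collapse = ", "))
  is_diff <- truth[selected] == "differential"
  tp <- sum(is_diff)
  fp <- sum(!is_diff)
  fn <- sum(truth == "differential") - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_score = f),
            class = "pr_summary")
}

#' @export
print.pr_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.3f  recall %.3f  F %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Overlap between two selection sets
#'
#' `jaccard` is `|A ∩ B| / |A ∪ B|`; `min_normalized` is
#' `|A ∩ B| / min(|A|, |B|)`, the laxer overlap used for robustness
#' comparisons across alpha settings. Two empty sets overlap perfectly by
#' convention (1); one empty set gives 0.
#'
#' @param T1,T2 Character vectors (treated as sets).
#' @param mode `"jaccard"` or `"min_normalized"`.
#' @return Overlap in [0, 1].
#' @export
set_overlap <- function(T1, T2, mode = c("jaccard", "min_normalized")) {
  mode <- match.arg(mode)
  T1 <- unique(T1); T2 <- unique(T2)
  if (length(T1) == 0L && length(T2) == 0L) return(1)
  inter <- length(intersect(T1, T2))
  if (mode == "jaccard") inter / length(union(T1, T2))
  else {
    mn <- min(length(T1), length(T2))
    if (mn == 0L) 0 else inter / mn
  }
}

# Mean pairwise Jaccard over the rows of a binary selection matrix,
# computed with one cross-product (rounds can number in the thousands).
.mean_pairwise_jaccard <- function(B) {
  r <- nrow(B)
  if (r < 2L) return(NA_real_)
  inter <- tcrossprod(B)
  sz <- rowSums(B)
  uni <- outer(sz, sz, "+") - inter
  J <- ifelse(uni == 0, 1, inter / uni)
  mean(J[upper.tri(J)])
}

# Resolve a method argument: a method id string or a function
# (matrix, classes, complexes, alpha, ...) -> result data frame.
.resolve_method <- function(method) {
  if (is.function(method)) return(method)
  switch(method,
    he = function(matrix, classes, complexes, alpha = 0.05, ...)
      he_test(matrix, classes, complexes, alpha = alpha, ...),
    gsea = function(matrix, classes, complexes, alpha = 0.05, ...)
      gsea_test(matrix, classes, complexes, alpha = alpha),
    qpsp = qpsp_test,
    snet = function(matrix, classes, complexes, alpha = 0.05, ...)
      snet_family_test(matrix, classes, complexes, variant = "snet", alpha = alpha, ...),
    fsnet = function(matrix, classes, complexes, alpha = 0.05, ...)
      snet_family_test(matrix, classes, complexes, variant = "fsnet", alpha = alpha, ...),
    pfsnet = pfsnet_test,
    ffishnet = function(matrix, classes, complexes, alpha = 0.05, ...)
      fishnet_test(matrix, classes, complexes, fuzzy = TRUE, alpha = alpha, ...),
    fishnet = function(matrix, classes, complexes, alpha = 0.05, ...)
      fishnet_test(matrix, classes, complexes, fuzzy = FALSE, alpha = alpha, ...),
    stop("unknown method: ", method)
  )
}

#' Available method identifiers
#' @return Character vector of the eight method ids.
#' @export
method_ids <- function() {
  c("ffishnet", "fishnet", "he", "gsea", "qpsp", "snet", "fsnet", "pfsnet")
}

#' Resampling stability of complex selection
#'
#' For each resampling size `s`, draws `s` samples per class without
#' replacement `reps` times, reruns the method, and records the binary
#' selection vector over complexes. Row sums count selections per round,
#' column sums give per-complex selection frequencies, and the headline
#' scalar is the mean pairwise Jaccard of the per-round selection sets.
#'
#' @param matrix,classes,complexes The dataset and complex list.
#' @param method Method id (see [method_ids()]) or a function with the
#'   `*_test` signature.
#' @param sizes Per-class resampling sizes (default `c(4, 6, 8)`).
#' @param reps Rounds per size (default 1000).
#' @param seed Integer seed.
#' @param alpha Selection level passed to the method.
#' @param ... Further arguments for the method.
#' @return List of class `"stability_result"`: per size, a list with the
#'   binary `matrix` (rounds x complexes), `row_counts`, `col_counts`,
#'   `col_freq`, and `mean_jaccard`.
#' @export
stability_resampling <- function(matrix, classes, complexes, method,
                                 sizes = c(4L, 6L, 8L), reps = 1000L,
                                 seed = NULL, alpha = 0.05, ...) {
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix))
  fn <- .resolve_method(method)
  s1 <- names(cl$labels)[cl$labels == cl$class1]
  s2 <- names(cl$labels)[cl$labels == cl$class2]
  if (any(sizes > min(length(s1), length(s2))))
    stop("resampling size exceeds class size")
  .with_seed(seed, {
    out <- lapply(sizes, function(sz) {
      B <- matrix(0L, nrow = reps, ncol = length(complexes),
                  dimnames = list(NULL, names(complexes)))
      for (r in seq_len(reps)) {
        cols <- c(sample(s1, sz), sample(s2, sz))
        res <- fn(matrix[, cols, drop = FALSE], cl$labels[cols], complexes,
                  alpha = alpha, ...)
        B[r, res$complex_id[res$selected]] <- 1L
      }
      list(matrix = B,
           row_counts = rowSums(B),
           col_counts = colSums(B),
           col_freq = colSums(B) / reps,
           mean_jaccard = .mean_pairwise_jaccard(B))
    })
    names(out) <- paste0("size_", sizes)
    structure(out, class = "stability_result",
              method = if (is.character(method)) method else "custom",
              reps = reps, seed = seed)
  })
}

#' @export
print.stability_result <- function(x, ...) {
  cat("resampling stability (", attr(x, "reps"), " rounds):\n", sep = "")
  for (nm in names(x)) {
    cat(sprintf("  %s: mean selections/round %.1f, mean pairwise Jaccard %.3f\n",
                nm, mean(x[[nm]]$row_counts), x[[nm]]$mean_jaccard))
  }
  invisible(x)
}

#' Deterministic Gaussian naive Bayes
#'
#' Gaussian class-conditional densities with per-class per-feature means
#' and variances; variances are floored at `1e-9 * (global feature variance
#' + 1)` so single-sample classes and near-constant features stay finite.
#' Features constant across the whole training set are skipped. Prediction
#' is the argmax of log-prior plus summed log-likelihood, with ties broken
#' toward the lexicographically smaller class label, so repeated runs are
#' bit-identical.
#'
#' @param train_features Numeric matrix, samples x features.
#' @param train_labels Character vector of class labels (length =
#'   `nrow(train_features)`).
#' @param test_features Numeric matrix with the same feature columns.
#' @return Character vector of predicted labels.
#' @export
naive_bayes_fit_predict <- function(train_features, train_labels, test_features) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  if (nrow(train_features) != length(train_labels))
    stop("one label per training sample required")
  if (ncol(train_features) != ncol(test_features))
    stop("train and test feature sets differ")
  labels <- sort(unique(train_labels), method = "radix")
  gv <- apply(train_features, 2L, stats::var)
  gv[is.na(gv)] <- 0
  keep <- gv > 0
  floor_v <- 1e-9 * (gv + 1)
  scores <- vapply(labels, function(lv) {
    idx <- train_labels == lv
    X <- train_features[idx, , drop = FALSE]
    mu <- colMeans(X)
    v <- if (nrow(X) > 1L) apply(X, 2L, stats::var) else rep(0, ncol(X))
    v <- pmax(v, floor_v)
    lp <- log(sum(idx) / length(train_labels))
    if (!any(keep)) return(rep(lp, nrow(test_features)))
    ll <- vapply(which(keep), function(j) {
      stats::dnorm(test_features[, j], mu[j], sqrt(v[j]), log = TRUE)
    }, numeric(nrow(test_features)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(test_features))
    lp + rowSums(ll)
  }, numeric(nrow(test_features)))
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = length(labels),
                                             dimnames = list(NULL, labels))
  labels[max.col(scores, ties.method = "first")]
}

#' Cross-validation of complex-based feature selection
#'
#' Per repetition: optionally shuffle the labels; stratified random
#' partition of each class into one half for feature selection and a
#' quarter each for training and validation; run the method on the
#' selection half; represent each sample by the expressions of all proteins
#' belonging to at least one selected complex; fit the deterministic naive
#' Bayes on the training quarter and score accuracy on the validation
#' quarter. When nothing is selected, the majority training class is
#' predicted (recorded in `fallback`).
#'
#' @inheritParams stability_resampling
#' @param reps Repetitions (default 1000).
#' @param scenario `"real"` or `"shuffled"` labels.
#' @return Data frame of class `"cv_result"`: `rep`, `scenario`,
#'   `accuracy`, `n_selected_complexes`, `n_features`, `fallback`.
#' @export
cross_validate <- function(matrix, classes, complexes, method, reps = 1000L,
                           seed = NULL, scenario = c("real", "shuffled"),
                           alpha = 0.05, ...) {
  scenario <- match.arg(scenario)
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix), min_per_class = 4L)
  fn <- .resolve_method(method)
  .with_seed(seed, {
    recs <- vector("list", reps)
    for (r in seq_len(reps)) {
      lab <- if (scenario == "shuffled") shuffle_labels(cl$labels) else cl$labels
      sel_cols <- train_cols <- val_cols <- character(0)
      for (lv in c(cl$class1, cl$class2)) {
        s <- sample(names(lab)[lab == lv])      # random stratified order
        n <- length(s)
        n_sel <- n %/% 2L
        n_train <- ceiling((n - n_sel) / 2)
        sel_cols <- c(sel_cols, s[seq_len(n_sel)])
        train_cols <- c(train_cols, s[n_sel + seq_len(n_train)])
        val_cols <- c(val_cols, s[(n_sel + n_train + 1L):n])
      }
      res <- fn(matrix[, sel_cols, drop = FALSE], lab[sel_cols], complexes,
                alpha = alpha, ...)
      sel_complexes <- res$complex_id[res$selected]
      feats <- unique(unlist(complexes[sel_complexes], use.names = FALSE))
      feats <- intersect(feats, rownames(matrix))
      truth_val <- lab[val_cols]
      if (length(feats) == 0L) {
        tab <- table(lab[train_cols])
        maj <- names(tab)[which(tab == max(tab))]
        pred <- rep(sort(maj, method = "radix")[1L], length(val_cols))
        fallback <- TRUE
      } else {
        pred <- naive_bayes_fit_predict(t(matrix[feats, train_cols, drop = FALSE]),
                                        lab[train_cols],
                                        t(matrix[feats, val_cols, drop = FALSE]))
        fallback <- FALSE
      }
      recs[[r]] <- data.frame(rep = r, scenario = scenario,
                              accuracy = mean(pred == truth_val),
                              n_selected_complexes = length(sel_complexes),
                              n_features = length(feats),
                              fallback = fallback, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs)
    class(out) <- c("cv_result", "data.frame")
    out
  })
}

#' Pseudo-class false-positive evaluation
#'
#' Samples of a single condition are repeatedly halved at random into two
#' pseudo-classes and the method is rerun; any selection is a false
#' positive. With an odd sample count the largest even subset is used.
#'
#' @param matrix Expression matrix of same-condition samples (>= 4).
#' @param complexes Complex list.
#' @inheritParams stability_resampling
#' @param reps Rounds (default 100).
#' @param labels Length-2 pseudo-class names.
#' @return Data frame: per round the number and fraction of complexes
#'   selected.
#' @export
false_positive_eval <- function(matrix, complexes, method, reps = 100L,
                                seed = NULL, alpha = 0.05,
                                labels = c("pseudoA", "pseudoB"), ...) {
  .check_matrix(matrix)
  fn <- .resolve_method(method)
  ns <- ncol(matrix)
  if (ns < 4L) stop("need at least 4 samples")
  use <- ns - ns %% 2L
  .with_seed(seed, {
    rates <- integer(reps)
    for (r in seq_len(reps)) {
      cols <- sample(colnames(matrix), use)
      lab <- stats::setNames(rep(labels, each = use %/% 2L), cols)
      res <- fn(matrix[, cols, drop = FALSE], lab, complexes, alpha = alpha, ...)
      rates[r] <- sum(res$selected)
    }
    data.frame(round = seq_len(reps), n_selected = rates,
               rate = rates / length(complexes))
  })
}

#' Null-calibration experiment
#'
#' Generates fresh null datasets (no spiked effects; truth proteins are
#' designated but untouched, so pseudo-complexes have the protocol's
#' expression-correlated structure) and records, per round and method, the
#' fraction of one-sided direction tests falling below `alpha` (for the
#' undirected methods, the fraction of complexes selected).
#'
#' @param methods Method ids to evaluate each round.
#' @param n_proteins,samples_per_class,n_diff_complexes Null dataset shape
#'   (defaults 1000, 6, 30 -- i.e. 60 pseudo-complexes in total).
#' @param rounds Number of independent null datasets.
#' @param seed Integer seed.
#' @param alpha Nominal level (default 0.05).
#' @return Matrix rounds x methods of per-round selection rates.
#' @export
null_calibration <- function(methods = c("ffishnet", "snet", "fsnet", "pfsnet",
                                         "qpsp", "gsea"),
                             n_proteins = 1000L, samples_per_class = 6L,
                             n_diff_complexes = 30L, rounds = 100L,
                             seed = 1L, alpha = 0.05) {
  .with_seed(seed, {
    out <- matrix(NA_real_, nrow = rounds, ncol = length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(rounds)) {
      base <- simulate_base_matrix(n_proteins, 2L * samples_per_class)
      cl <- stats::setNames(rep(c("A", "B"), each = samples_per_class),
                            colnames(base))
      truth <- sort(sample(rownames(base), round(0.2 * n_proteins)))
      cplx <- build_pseudo_complexes(list(matrix = base, truth_proteins = truth),
                                     pseudo_complex_spec(n_diff_complexes))
      cplx <- filter_complexes(cplx, base)
      for (m in methods) {
        res <- .resolve_method(m)(base, cl, cplx, alpha = alpha)
        out[r, m] <- if (all(c("p_up_class1", "p_up_class2") %in% names(res)))
          mean(c(res$p_up_class1, res$p_up_class2) < alpha)
        else mean(res$selected)
      }
    }
    out
  })
}

#' Precision-recall benchmark over replicate spiked datasets
#'
#' The simulated benchmark protocol: per replicate, spike 20% differential
#' proteins into a pseudo-test class, build pseudo-complexes at the given
#' purity, run each method, and score F against the complex truth labels.
#'
#' @param methods Method ids.
#' @param n_datasets Replicate datasets (the full protocol uses 100;
#'   scaled-down runs are fine since each replicate is independent).
#' @param n_proteins,samples_per_class,n_diff_complexes Dataset shape.
#' @param purity Pseudo-complex purity in (0, 1].
#' @param spec A [simulation_spec()] for the spike-in.
#' @param seed Integer seed.
#' @param alpha Selection level.
#' @return Matrix n_datasets x methods of F-scores.
#' @export
pr_benchmark <- function(methods = c("ffishnet", "he", "gsea"),
                         n_datasets = 20L, n_proteins = 1000L,
                         samples_per_class = 6L, n_diff_complexes = 62L,
                         purity = 0.5, spec = simulation_spec(), seed = 1L,
                         alpha = 0.05) {
  .with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_datasets, ncol = length(methods),
                  dimnames = list(NULL, methods))
    for (i in seq_len(n_datasets)) {
      base <- simulate_base_matrix(n_proteins, 2L * samples_per_class)
      ds <- make_pseudo_class_dataset(base, spec)
      cplx <- build_pseudo_complexes(ds, pseudo_complex_spec(n_diff_complexes,
                                                             purity = purity))
      cplx <- filter_complexes(cplx, ds$matrix)
      truth <- attr(cplx, "truth")
      for (m in methods) {
        res <- .resolve_method(m)(ds$matrix, ds$classes, cplx, alpha = alpha)
        out[i, m] <- precision_recall_f(res$complex_id[res$selected], truth)$f_score
      }
    }
    out
  })
}
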