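#' Complex-based feature selection
#'
#' The front door of the package: runs one of the eight complex-based
#' feature-selection methods on an expression matrix, a two-class labelling
#' and a complex collection, after applying the standard coverage filter
#' (at least `min_identified` measured members per complex).
#'
#' Methods: `"ffishnet"` (Fuzzy-FishNET, the integer-fuzzy Fisher exact
#' test), `"fishnet"` (its unweighted ablation), `"he"` (hypergeometric
#' enrichment), `"gsea"` (direct-group KS), `"qpsp"`, `"snet"`, `"fsnet"`,
#' `"pfsnet"`.
#'
#' @param matrix Expression matrix (proteins x samples), e.g. from
#'   [read_expression_matrix()].
#' @param classes Named character vector of class labels, e.g. from
#'   [read_class_labels()].
#' @param complexes Named list of complexes, e.g. from
#'   [read_complexes_gmt()].
#' @param method Method id (see [method_ids()]).
#' @param alpha Complex-level significance level (default 0.05).
#' @param alpha1,alpha2,n_bins Rank-weighting parameters for the rank-based
#'   methods (defaults 0.10, 0.20, 4); ignored by `"he"` and `"gsea"`.
#' @param min_identified Complex coverage filter (default 3).
#' @param ... Further method-specific arguments (e.g. `t_alpha` for HE).
#' @return Object of class `"complex_select"`: a list with `results` (the
#'   per-complex result table), `method`, `alpha`, `params`,
#'   `n_complexes_tested`, `classes` and the matched call.
#' @examples
#' ds <- make_pseudo_class_dataset(simulate_base_matrix(300, 12, seed = 1),
#'                                 simulation_spec(seed = 2))
#' cplx <- build_pseudo_complexes(ds, pseudo_complex_spec(10, purity = 1, seed = 3))
#' fit <- complex_select(ds$matrix, ds$classes, cplx, method = "ffishnet")
#' summary(fit)
#' @export
complex_select <- function(matrix, classes, complexes,
                           method = c("ffishnet", "fishnet", "he", "gsea",
                                      "qpsp", "snet", "fsnet", "pfsnet"),
                           alpha = 0.05, alpha1 = 0.10, alpha2 = 0.20,
                           n_bins = 4L, min_identified = 3L, ...) {
  method <- match.arg(method)
  .check_matrix(matrix)
  cl <- .check_classes(classes, colnames(matrix))
  filtered <- filter_complexes(complexes, matrix, min_identified)
  if (!length(filtered)) stop("no complex passes the coverage filter")
  fn <- .resolve_method(method)
  extra <- if (method %in% c("he", "gsea")) list(...)
           else c(list(alpha1 = alpha1, alpha2 = alpha2, n_bins = n_bins), list(...))
  results <- do.call(fn, c(list(matrix, cl$labels, filtered, alpha = alpha), extra))
  structure(list(results = results, method = method, alpha = alpha,
                 params = list(alpha1 = alpha1, alpha2 = alpha2, n_bins = n_bins,
                               min_identified = min_identified),
                 n_complexes_tested = length(filtered),
                 classes = c(class1 = cl$class1, class2 = cl$class2),
                 call = match.call()),
            class = "complex_select")
}

#' @export
print.complex_select <- function(x, ...) {
  cat("complex-based feature selection\n")
  cat("  method:  ", x$method, "\n", sep = "")
  cat("  classes: ", x$classes[["class1"]], " vs ", x$classes[["class2"]], "\n", sep = "")
  cat("  tested:  ", x$n_complexes_tested, " complexes at alpha = ", x$alpha, "\n", sep = "")
  cat("  selected:", sum(x$results$selected), "\n")
  invisible(x)
}

#' @export
summary.complex_select <- function(object, n = 10L, ...) {
  res <- object$results
  sel <- res[res$selected, , drop = FALSE]
  sel <- sel[order(sel$p_value, sel$complex_id), , drop = FALSE]
  print(object)
  if (nrow(sel)) {
    cat("  by direction:",
        paste(names(table(sel$direction)), table(sel$direction),
              sep = " = ", collapse = ", "), "\n")
    cat("\ntop selected complexes:\n")
    print(utils::head(sel[c("complex_id", "statistic", "p_value", "direction")], n),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.complex_select <- function(x, ...) x$results

#' Extract selected complex ids
#' @param x A `"complex_select"` object.
#' @return Character vector of selected complex ids.
#' @export
selected_complexes <- function(x) {
  stopifnot(inherits(x, "complex_select"))
  x$results$complex_id[x$results$selected]
}

#' @export
plot.complex_select <- function(x, ...) {
  p <- x$results$p_value
  graphics::hist(p, breaks = seq(0, 1, by = 0.05),
                 main = paste0(x$method, ": complex p-values"),
                 xlab = "p-value", col = "grey85", border = "white", ...)
  graphics::abline(v = x$alpha, col = "firebrick", lty = 2)
  invisible(x)
}
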