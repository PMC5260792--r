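#' Read a protein-by-sample expression matrix
#'
#' Reads a tab-separated quantification table (spectral counts or any
#' non-negative abundance). The header row holds sample ids and the first
#' column holds protein ids; input row and column order is preserved.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with protein ids as row names and sample ids as
#'   column names.
#' @details Validation errors name the offending ids or cell coordinates:
#'   duplicate protein/sample ids, non-numeric cells, and negative values all
#'   abort with a message locating the problem.
#' @seealso [write_expression_matrix()], [read_class_labels()]
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 3L) stop("expected protein id column plus at least 2 samples in ", path)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate protein ids in ", path, ": ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup)) stop("duplicate sample ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value at protein '", ids[bad[1L, 1L]], "', sample '",
         samples[bad[1L, 2L]], "' in ", path)
  }
  bad <- which(vals < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative value at protein '", ids[bad[1L, 1L]], "', sample '",
         samples[bad[1L, 2L]], "' in ", path)
  }
  dimnames(vals) <- list(ids, samples)
  .check_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; `read(write(x))` is the identity.
#'
#' @param x Numeric matrix with protein row names and sample column names.
#' @param path Output file path.
#' @param id_column Name for the protein id column (first header field).
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path, id_column = "protein_id") {
  .check_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-class table
#'
#' @param path TSV with columns `sample_id` and `class` (header optional but
#'   recommended; the first two columns are used).
#' @return Named character vector mapping sample id to class label.
#' @export
read_class_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("class-label file needs two columns (sample_id, class): ", path)
  labels <- stats::setNames(df[[2L]], df[[1L]])
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup)) stop("duplicate sample ids in ", path, ": ", paste(dup, collapse = ", "))
  .check_classes(labels)$labels
}

#' Write a sample-class table
#' @param classes Named character vector (names = sample ids).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_class_labels <- function(classes, path) {
  df <- data.frame(sample_id = names(classes), class = unname(classes),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein complexes from a GMT file
#'
#' One set per line: `name <tab> description <tab> member1 <tab> member2 ...`.
#' Members are deduplicated with original order preserved. This is the
#' interchange format for curated complex collections such as CORUM exports.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per complex). Descriptions
#'   are kept in the `"descriptions"` attribute.
#' @export
read_complexes_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("GMT line ", i, ": expected name, description and at least one member")
    nms[i] <- fields[1L]
    desc[i] <- fields[2L]
    out[[i]] <- unique(fields[-(1:2)])
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("duplicate complex ids: ", paste(dup, collapse = ", "))
  names(out) <- nms
  attr(out, "descriptions") <- stats::setNames(desc, nms)
  out
}

#' Write protein complexes to a GMT file
#' @param complexes Named list of character vectors.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_complexes_gmt <- function(complexes, path) {
  desc <- attr(complexes, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(complexes)), names(complexes))
  lines <- vapply(names(complexes), function(nm) {
    paste(c(nm, desc[[nm]], complexes[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Retain complexes sufficiently covered by the measured proteome
#'
#' Keeps complexes with at least `min_identified` members present as rows of
#' the expression matrix. Presence as a matrix row is the operative notion of
#' "identified and measured"; zero counts in individual samples do not
#' disqualify a protein. Complex-level truth annotations (see
#' [build_pseudo_complexes()]) are carried through.
#'
#' @param complexes Named list of character vectors.
#' @param matrix Expression matrix (only row names are used).
#' @param min_identified Minimum number of measured members (default 3).
#' @return Filtered complex list (possibly empty), truth attribute subset
#'   accordingly.
#' @export
filter_complexes <- function(complexes, matrix, min_identified = 3L) {
  stopifnot(min_identified >= 1L)
  ids <- rownames(matrix)
  keep <- vapply(complexes, function(m) sum(m %in% ids) >= min_identified, logical(1L))
  out <- complexes[keep]
  truth <- attr(complexes, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth[names(out)]
  desc <- attr(complexes, "descriptions")
  if (!is.null(desc)) attr(out, "descriptions") <- desc[names(out)]
  out
}

#' Write a complex-test result table
#'
#' Serialises the universal result record shared by all methods: one row per
#' complex with `complex_id`, `method`, `statistic`, `p_value`, `direction`
#' and `selected`.
#'
#' @param results Data frame as returned by the `*_test` functions.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  cols <- c("complex_id", "method", "statistic", "p_value", "direction", "selected")
  missing <- setdiff(cols, colnames(results))
  if (length(missing)) stop("result table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.table(results[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
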