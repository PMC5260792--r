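# Internal helpers shared across modules.

# log(sum(exp(x))) without overflow; x may contain -Inf.
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Validate and normalise a two-class label assignment.
# `classes` is a named character vector (names = sample ids) or a factor.
# Returns list(labels = named chr, class1, class2) with class1 the
# lexicographically smaller label (ordering is locale-independent).
.check_classes <- function(classes, sample_ids = NULL, min_per_class = 1L) {
  if (is.factor(classes)) classes <- stats::setNames(as.character(classes), names(classes))
  if (is.null(names(classes)) || anyNA(names(classes)) || any(names(classes) == ""))
    stop("class labels must be a named vector (names = sample ids)")
  lv <- sort(unique(unname(classes)), method = "radix")
  if (length(lv) != 2L)
    stop("exactly two distinct class labels required, got: ",
         paste(lv, collapse = ", "))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(classes))
    if (length(missing))
      stop("samples without a class label: ", paste(missing, collapse = ", "))
    classes <- classes[sample_ids]
  }
  n1 <- sum(classes == lv[1L]); n2 <- sum(classes == lv[2L])
  if (n1 < min_per_class || n2 < min_per_class)
    stop("each class needs at least ", min_per_class, " samples (",
         lv[1L], ": ", n1, ", ", lv[2L], ": ", n2, ")")
  list(labels = classes, class1 = lv[1L], class2 = lv[2L])
}

# Validate an expression matrix (numeric, non-negative, unique dimnames).
.check_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs protein row names and sample column names")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (any(x < 0)) stop("expression matrix contains negative values")
  if (ncol(x) < 2L) stop("at least 2 samples required")
  invisible(x)
}

# Complex membership indicator (complexes x proteins), restricted to
# proteins present in `protein_ids`. Missing members contribute nothing.
.complex_indicator <- function(complexes, protein_ids) {
  k <- length(complexes)
  ind <- matrix(0, nrow = k, ncol = length(protein_ids),
                dimnames = list(names(complexes), protein_ids))
  for (i in seq_len(k)) {
    hit <- intersect(complexes[[i]], protein_ids)
    if (length(hit)) ind[i, hit] <- 1
  }
  ind
}

# Per-row two-sample t statistics between column groups i1 and i2 of M.
# pooled = TRUE gives the equal-variance form (df = n1 + n2 - 2), otherwise
# Welch with Satterthwaite df. Degenerate rows (zero standard error):
# equal means -> t = 0, p = 1; unequal means -> p = smallest positive double.
# Returns list(t, df, p_greater, p_two_sided): p_greater is P(T > t).
.row_t <- function(M, i1, i2, pooled = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  X1 <- M[, i1, drop = FALSE]; X2 <- M[, i2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1L)
  d <- m1 - m2
  if (pooled) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, length(d))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1L) + b^2 / (n2 - 1L))
  }
  t <- d / se
  zero <- se == 0
  if (any(zero)) {
    t[zero & d == 0] <- 0
    t[zero & d > 0] <- Inf
    t[zero & d < 0] <- -Inf
    df[zero] <- n1 + n2 - 2L
  }
  pg <- stats::pt(t, df, lower.tail = FALSE)
  p2 <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # zero-se rows: exact conventions
  if (any(zero)) {
    pg[zero & d == 0] <- 0.5
    p2[zero & d == 0] <- 1
    pg[zero & d > 0] <- .Machine$double.xmin
    pg[zero & d < 0] <- 1
    p2[zero & d != 0] <- .Machine$double.xmin
  }
  p2 <- pmin(p2, 1)
  list(t = t, df = df, p_greater = pg, p_two_sided = p2)
}

# Restore RNG state on exit so seeded helpers do not perturb the caller.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
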