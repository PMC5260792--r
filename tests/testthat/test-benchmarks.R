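test_that("precision/recall/F follow the printed formulas and conventions", {
  truth <- stats::setNames(rep(c("differential", "non_differential"), each = 10),
                           sprintf("C%02d", 1:20))
  # TP = FP = FN = 5 -> P = R = F = 0.5
  sel <- c(sprintf("C%02d", 1:5), sprintf("C%02d", 11:15))
  pr <- precision_recall_f(sel, truth)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.5)
  expect_equal(pr$f_score, 0.5)
  # perfect selection
  pr1 <- precision_recall_f(sprintf("C%02d", 1:10), truth)
  expect_equal(pr1$f_score, 1)
  # nothing selected -> F = 0 by convention
  expect_equal(precision_recall_f(character(0), truth)$f_score, 0)
  # TP = 0 with selections -> F = 0
  expect_equal(precision_recall_f("C11", truth)$f_score, 0)
  expect_error(precision_recall_f("Cxx", truth), "without truth label")
})

test_that("F <= min(2P, 2R) and F = P when P = R over random selections", {
  truth <- stats::setNames(rep(c("differential", "non_differential"), each = 15),
                           sprintf("C%02d", 1:30))
  set.seed(41)
  for (i in 1:20) {
    sel <- sample(names(truth), sample(0:30, 1))
    pr <- precision_recall_f(sel, truth)
    expect_lte(pr$f_score, min(2 * pr$precision, 2 * pr$recall) + 1e-12)
    if (pr$precision == pr$recall) expect_equal(pr$f_score, pr$precision)
  }
})

test_that("set overlap modes follow their formulas with Jaccard <= min-normalised", {
  expect_equal(set_overlap(letters[1:4], letters[1:4]), 1)
  expect_equal(set_overlap(letters[1:4], letters[1:4], "min_normalized"), 1)
  expect_equal(set_overlap(letters[1:3], letters[4:6]), 0)
  expect_equal(set_overlap(letters[1:4], letters[2:5]), 3 / 5)
  expect_equal(set_overlap(letters[1:4], letters[2:5], "min_normalized"), 3 / 4)
  expect_equal(set_overlap(character(0), character(0)), 1)
  expect_equal(set_overlap(character(0), letters[1:3], "min_normalized"), 0)
  set.seed(42)
  for (i in 1:20) {
    a <- sample(letters, sample(1:20, 1)); b <- sample(letters, sample(1:20, 1))
    expect_lte(set_overlap(a, b), set_overlap(a, b, "min_normalized") + 1e-12)
  }
})

test_that("stability harness: constant selector gives Jaccard 1, full binary bookkeeping", {
  ds <- separable_dataset(n_proteins = 100, seed = 43)
  cplx <- build_pseudo_complexes(ds, pseudo_complex_spec(5, purity = 1, seed = 44))
  fixed <- function(matrix, classes, complexes, alpha = 0.05, ...) {
    data.frame(complex_id = names(complexes), method = "fixed", statistic = 0,
               p_value = ifelse(seq_along(complexes) <= 3, 0.01, 0.5),
               direction = "none", selected = seq_along(complexes) <= 3,
               stringsAsFactors = FALSE)
  }
  st <- stability_resampling(ds$matrix, ds$classes, cplx, fixed,
                             sizes = 4, reps = 8, seed = 45)
  s <- st$size_4
  expect_equal(s$mean_jaccard, 1)
  expect_true(all(s$col_counts %in% c(0L, 8L)))
  expect_equal(unname(s$row_counts), rep(3, 8))
  # reps = 1: degenerate but well-formed
  st1 <- stability_resampling(ds$matrix, ds$classes, cplx, fixed,
                              sizes = 4, reps = 1, seed = 46)
  expect_true(is.na(st1$size_4$mean_jaccard))
  expect_error(stability_resampling(ds$matrix, ds$classes, cplx, fixed,
                                    sizes = 10, reps = 2), "exceeds class size")
})

test_that("random k-set selector matches the expected pairwise Jaccard", {
  ds <- separable_dataset(n_proteins = 100, seed = 47)
  cplx <- build_pseudo_complexes(ds, pseudo_complex_spec(5, purity = 1, seed = 48))
  k <- 2; C <- length(cplx)
  rnd <- function(matrix, classes, complexes, alpha = 0.05, ...) {
    sel <- sample(length(complexes), k)
    data.frame(complex_id = names(complexes), method = "rnd", statistic = 0,
               p_value = 0.5, direction = "none",
               selected = seq_along(complexes) %in% sel, stringsAsFactors = FALSE)
  }
  st <- stability_resampling(ds$matrix, ds$classes, cplx, rnd,
                             sizes = 4, reps = 300, seed = 49)
  # E[J] for two independent k-subsets of C complexes (enumeration oracle)
  overlap_probs <- vapply(0:k, function(o) {
    choose(k, o) * choose(C - k, k - o) / choose(C, k)
  }, numeric(1))
  expected <- sum((0:k) / (2 * k - (0:k)) * overlap_probs)
  expect_lt(abs(st$size_4$mean_jaccard - expected), 0.05)
})

test_that("naive Bayes is deterministic with documented tie-breaks", {
  train <- matrix(c(-10, -9, 10, 9), ncol = 1)
  labels <- c("low", "low", "high", "high")
  expect_identical(naive_bayes_fit_predict(train, labels, matrix(9, ncol = 1)), "high")
  expect_identical(naive_bayes_fit_predict(train, labels, matrix(-9, ncol = 1)), "low")
  # exactly equidistant point with equal priors: lexicographically smaller label
  expect_identical(naive_bayes_fit_predict(train, labels, matrix(0, ncol = 1)), "high")
  # training points classify to their own class on a separable fixture
  set.seed(50)
  X <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(20, 6), ncol = 2))
  y <- rep(c("a", "b"), each = 10)
  expect_identical(naive_bayes_fit_predict(X, y, X), y)
  # constant features are skipped without breaking prediction
  Xc <- cbind(X, 1)
  expect_identical(naive_bayes_fit_predict(Xc, y, Xc), y)
})

test_that("naive Bayes agrees with e1071 on a separable fixture", {
  set.seed(51)
  X <- rbind(matrix(rnorm(40, 0), ncol = 4), matrix(rnorm(40, 3), ncol = 4))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("a", "b"), each = 10)
  Xt <- rbind(matrix(rnorm(20, 0), ncol = 4), matrix(rnorm(20, 3), ncol = 4))
  colnames(Xt) <- paste0("f", 1:4)
  ref <- as.character(predict(e1071::naiveBayes(X, factor(y)), Xt))
  expect_identical(naive_bayes_fit_predict(X, y, Xt), ref)
})

test_that("cross-validation separates real labels from shuffled ones", {
  # 16 samples per class so each CV quarter holds 4 per class: enough for the
  # Gaussian class-conditional variances to be estimable
  base <- simulate_base_matrix(200, 32, seed = 52)
  ds <- make_pseudo_class_dataset(base, simulation_spec(effect_sizes = 2, seed = 53))
  cplx <- build_pseudo_complexes(ds, pseudo_complex_spec(8, purity = 1, seed = 54))
  cv_real <- cross_validate(ds$matrix, ds$classes, cplx, "ffishnet",
                            reps = 30, seed = 55, scenario = "real")
  cv_shuf <- cross_validate(ds$matrix, ds$classes, cplx, "ffishnet",
                            reps = 30, seed = 55, scenario = "shuffled")
  expect_gt(mean(cv_real$accuracy), 0.8)
  expect_lt(mean(cv_shuf$accuracy), 0.75)
  expect_gt(mean(cv_real$accuracy), mean(cv_shuf$accuracy))
  # records are well-formed
  expect_true(all(cv_real$accuracy >= 0 & cv_real$accuracy <= 1))
  expect_identical(nrow(cv_real), 30L)
})

test_that("false-positive harness: select-everything method reports rate 1", {
  ds <- separable_dataset(n_proteins = 100, seed = 56)
  cplx <- build_pseudo_complexes(ds, pseudo_complex_spec(5, purity = 1, seed = 57))
  all_in <- function(matrix, classes, complexes, alpha = 0.05, ...) {
    data.frame(complex_id = names(complexes), method = "all", statistic = 0,
               p_value = 0, direction = "none", selected = TRUE,
               stringsAsFactors = FALSE)
  }
  fp <- false_positive_eval(ds$matrix, cplx, all_in, reps = 5, seed = 58)
  expect_true(all(fp$rate == 1))
  fp2 <- false_positive_eval(ds$matrix, cplx, all_in, reps = 5, seed = 58)
  expect_identical(fp, fp2)
})
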