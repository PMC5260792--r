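test_that("two-sample t matches stats::t.test in both variance modes", {
  set.seed(6)
  for (i in 1:10) {
    xs <- rnorm(5, 1); ys <- rnorm(7)
    pooled <- two_sample_t(xs, ys, pooled = TRUE)
    ref <- t.test(xs, ys, var.equal = TRUE)
    expect_equal(pooled$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pooled$p_value, ref$p.value, tolerance = 1e-12)
    welch <- two_sample_t(xs, ys, pooled = FALSE)
    refw <- t.test(xs, ys)
    expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-12)
    expect_equal(welch$p_value, refw$p.value, tolerance = 1e-12)
    refg <- t.test(xs, ys, alternative = "greater")
    expect_equal(two_sample_t(xs, ys, pooled = FALSE, alternative = "greater")$p_value,
                 refg$p.value, tolerance = 1e-12)
  }
})

test_that("two-sample t degenerate conventions and antisymmetry hold", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(two_sample_t(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_lt(two_sample_t(c(5, 5, 5), c(1, 1, 1))$p_value, 1e-300)
  a <- two_sample_t(c(1, 3, 5), c(2, 4, 9))
  b <- two_sample_t(c(2, 4, 9), c(1, 3, 5))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("QPSP hit-rates are weight-modulated overlaps over measured size", {
  w <- matrix(c(1, 0.8, 0, 1, 1, 1, 0, 0, 0), nrow = 3,
              dimnames = list(c("P1", "P2", "P3"), c("S1", "S2", "S3")))
  attr(w, "scheme") <- weight_scheme("fuzzy_fractional")
  h <- qpsp_hit_rates(w, list(C = c("P1", "P2", "P3")))
  expect_equal(unname(h[1, ]), c(1.8 / 3, 1, 0))
  # missing members contribute nothing; measured size is the denominator
  h2 <- qpsp_hit_rates(w, list(C = c("P1", "P2", "Pabsent")))
  expect_equal(h2[1, "S1"], 1.8 / 2)
  expect_error(qpsp_hit_rates(w, list(C = "Pabsent")), "no measured member")
})

test_that("QPSP selects nothing when the two classes are identical copies", {
  m <- tiny_matrix()[, 1:3]
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("S%d", 1:6)
  res <- qpsp_test(dup, tiny_classes(dup), tiny_complexes())
  expect_false(any(res$selected))
  expect_true(all(res$p_value == 1))
})

test_that("beta is the class proportion (or mean fuzzy membership) of top ranks", {
  w <- matrix(c(1, 1, 1, 1,   1, 1, 1, 0,   0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), sprintf("S%d", 1:4)))
  cl <- stats::setNames(rep("A", 4), colnames(w))
  cl2 <- c(cl[1:2], stats::setNames(rep("B", 2), c("S3", "S4")))
  beta <- snet_beta(w, cl2)
  expect_equal(unname(beta["P1", ]), c(1, 1))
  expect_equal(unname(beta["P2", ]), c(1, 0.5))
  expect_equal(unname(beta["P3", ]), c(0, 0))
})

test_that("snet_score is the fs x beta sum over measured members", {
  w <- matrix(c(1, 1, 0.8), ncol = 1, dimnames = list(c("P1", "P2", "P3"), "S1"))
  beta <- matrix(c(1, 0.5, 1), ncol = 1, dimnames = list(c("P1", "P2", "P3"), "A"))
  expect_equal(snet_score(c("P1", "P2", "P3"), "S1", w, beta, "A"), 2.3)
  expect_equal(snet_score(c("P1", "P2", "P3", "Pmissing"), "S1", w, beta, "A"), 2.3)
  expect_equal(snet_score("P3", "S1", w * 0, beta, "A"), 0)
})

test_that("SNET/FSNET select a class-1-only complex with the right direction", {
  # complex members dominate the top ranks of class A samples only
  set.seed(8)
  m <- matrix(runif(40 * 8, 1, 100), nrow = 40,
              dimnames = list(sprintf("P%02d", 1:40), sprintf("S%d", 1:8)))
  cl <- stats::setNames(rep(c("A", "B"), each = 4), colnames(m))
  m[1:4, cl == "A"] <- 1000 + m[1:4, cl == "A"]
  cplx <- list(HOT = sprintf("P%02d", 1:4), COLD = sprintf("P%02d", 21:24))
  for (v in c("snet", "fsnet")) {
    res <- snet_family_test(m, cl, cplx, variant = v)
    expect_true(res$selected[res$complex_id == "HOT"])
    expect_identical(res$direction[res$complex_id == "HOT"], "up_in_class1")
    # swapped labels flip the direction with identical p-values
    swapped <- stats::setNames(ifelse(cl == "A", "B", "A"), names(cl))
    res2 <- snet_family_test(m, swapped, cplx, variant = v)
    expect_identical(res2$direction[res2$complex_id == "HOT"], "up_in_class2")
    expect_equal(res2$p_up_class2, res$p_up_class1, tolerance = 1e-12)
    expect_equal(res2$p_up_class1, res$p_up_class2, tolerance = 1e-12)
  }
})

test_that("SNET equals FSNET when the fuzzy region collapses", {
  m <- tiny_matrix()
  cl <- tiny_classes(m)
  cplx <- tiny_complexes()
  a <- snet_family_test(m, cl, cplx, variant = "snet",
                        alpha1 = 0.3, alpha2 = 0.3 + 1e-9)
  b <- snet_family_test(m, cl, cplx, variant = "fsnet",
                        alpha1 = 0.3, alpha2 = 0.3 + 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
})

test_that("rank-based tests are invariant to per-sample monotone transforms", {
  m <- tiny_matrix()
  cl <- tiny_classes(m)
  cplx <- tiny_complexes()
  m2 <- m
  m2[, 1:3] <- log1p(m2[, 1:3]) * 3        # different monotone map per sample block
  m2[, 4:6] <- sqrt(m2[, 4:6])
  for (meth in c("qpsp", "snet", "fsnet", "pfsnet", "ffishnet")) {
    f1 <- complex_select(m, cl, cplx, method = meth)
    f2 <- complex_select(m2, cl, cplx, method = meth)
    expect_equal(f1$results$p_value, f2$results$p_value, tolerance = 1e-12,
                 label = meth)
  }
})

test_that("PFSNET deltas vanish when both beta tables coincide", {
  m <- tiny_matrix()[, 1:3]
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("S%d", 1:6)
  res <- pfsnet_test(dup, tiny_classes(dup), tiny_complexes())
  expect_false(any(res$selected))
  expect_true(all(res$statistic == 0))
})

test_that("PFSNET closed-form delta on a fully polarised fixture", {
  # every class-A sample has all 3 members in its top 10%; class B never does
  set.seed(10)
  m <- matrix(runif(30 * 6, 10, 20), nrow = 30,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("S%d", 1:6)))
  cl <- stats::setNames(rep(c("A", "B"), each = 3), colnames(m))
  m[1:3, cl == "A"] <- 1e4 + m[1:3, cl == "A"]
  m[1:3, cl == "B"] <- 1        # well below every other protein in class B
  cplx <- list(POL = c("P01", "P02", "P03"))
  res <- pfsnet_test(m, cl, cplx)
  expect_true(res$selected)
  expect_identical(res$direction, "up_in_class1")
  # delta for class-A samples is |S| (fs = 1, betaA = 1, betaB = 0)
  W <- compute_weights(m, weight_scheme("fuzzy_fractional"))
  beta <- snet_beta(W, cl)
  dA <- sum(W[1:3, "S1"] * beta[1:3, "A"]) - sum(W[1:3, "S1"] * beta[1:3, "B"])
  expect_equal(dA, 3)
})
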