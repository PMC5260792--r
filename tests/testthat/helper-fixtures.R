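# Shared fixtures and independent oracles for the test suite.

# Small deterministic matrix: 10 proteins x 6 samples, distinct positive
# values except where noted.
tiny_matrix <- function() {
  set.seed(42)
  m <- matrix(sample(1:600, 60), nrow = 10,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("S%d", 1:6)))
  storage.mode(m) <- "double"
  m
}

tiny_classes <- function(m = tiny_matrix()) {
  stats::setNames(rep(c("A", "B"), each = ncol(m) / 2), colnames(m))
}

tiny_complexes <- function() {
  list(C1 = c("P01", "P02", "P03"),
       C2 = c("P04", "P05", "P06", "P07"),
       C3 = c("P08", "P09", "P10"))
}

# Independent Fisher tail oracle: enumerate every table with the observed
# marginals, computing point probabilities directly from factorials
# (valid for n <= 40), and sum those with first cell >= a.
enum_fisher_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  pts <- vapply(lo:hi, function(x) {
    bb <- r1 - x; cc <- c1 - x; dd <- n - r1 - cc
    factorial(r1) * factorial(n - r1) * factorial(c1) * factorial(n - c1) /
      (factorial(x) * factorial(bb) * factorial(cc) * factorial(dd) * factorial(n))
  }, numeric(1))
  sum(pts[(lo:hi) >= a])
}

# Independent hypergeometric tail oracle: enumerate all possible
# differential sets of size n out of N (complex = first B ids) and count
# the fraction overlapping in >= b members. Feasible for N <= 12.
enum_hypergeom_tail <- function(N, B, n, b) {
  complex <- seq_len(B)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(s) sum(s %in% complex))
  mean(hits >= b)
}

# Brute-force two-sample KS statistic via direct ECDF evaluation.
enum_ks <- function(x, y) {
  g <- c(x, y)
  max(vapply(g, function(v) abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}

# A strongly separable spiked dataset for end-to-end checks.
separable_dataset <- function(n_proteins = 300, spc = 6, seed = 7,
                              effect_sizes = c(1, 2)) {
  base <- simulate_base_matrix(n_proteins, 2 * spc, seed = seed)
  make_pseudo_class_dataset(base, simulation_spec(effect_sizes = effect_sizes,
                                                  seed = seed + 1))
}
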