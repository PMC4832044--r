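mk_counts <- function(m, times = c(0, 8, 16), reps = 1) {
  d <- ts_design(times = times, n_replicates = reps)
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))), d$sample_id)
  count_matrix(m, assay = "RNA", feature = "CDS", design = d)
}

test_that("upper-quartile factors: symmetry, depth cancellation, hand oracle", {
  # identical samples -> factors all 1
  m <- mk_counts(matrix(rep(c(0L, 5L, 10L, 20L, 100L), 3), ncol = 3))
  f <- upper_quartile_factors(m)
  expect_equal(f$uq_factor, rep(1, 3))
  expect_equal(exp(mean(log(f$uq_factor))), 1, tolerance = 1e-9)

  # doubling a sample's counts doubles its library size too: q/lib cancels
  m2 <- mk_counts(cbind(c(0L, 5L, 10L, 20L, 100L),
                        2L * c(0L, 5L, 10L, 20L, 100L)), times = c(0, 12))
  f2 <- upper_quartile_factors(m2)
  expect_equal(f2$uq_factor, rep(1, 2))

  # hand-computed 3-sample oracle on positive-total genes
  raw <- cbind(c(10L, 20L, 30L, 40L, 0L),
               c(10L, 10L, 10L, 10L, 0L),
               c(5L, 10L, 100L, 1L, 0L))
  m3 <- mk_counts(raw)
  q <- apply(raw[1:4, ], 2, quantile, probs = 0.75, type = 7)
  qn <- q / colSums(raw)
  expect_equal(upper_quartile_factors(m3)$uq_factor,
               unname(qn / exp(mean(log(qn)))))
  expect_equal(upper_quartile_factors(m3)$effective_size,
               unname(colSums(raw) * qn / exp(mean(log(qn)))))

  # all-zero sample and too-sparse samples are explicit errors
  expect_error(upper_quartile_factors(
    mk_counts(cbind(c(1L, 0L, 0L, 0L, 0L), c(9L, 9L, 9L, 9L, 9L)),
              times = c(0, 12))), "upper quartile is zero")
})

test_that("upper-quartile factors agree with edgeR's upperquartile method", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  raw <- matrix(rnbinom(5 * 200, mu = 60, size = 10), ncol = 5)
  raw <- rbind(raw, matrix(0L, 3, 5))
  m <- mk_counts(raw, times = c(0, 5, 10, 15, 20))
  ours <- upper_quartile_factors(m)$uq_factor
  theirs <- edgeR::calcNormFactors(unclass(m), method = "upperquartile",
                                   p = 0.75)
  expect_equal(ours, unname(theirs), tolerance = 1e-10)
})

test_that("RPKM follows the direct formula and its invariances", {
  # counts 10, length 1000 nt, N forced to 1e6 -> RPKM 10
  m <- mk_counts(matrix(c(10L, 10L, 10L,
                          rep(333323L, 3),
                          rep(666667L, 3)), ncol = 3, byrow = TRUE))
  f <- upper_quartile_factors(m)
  # equal samples: factors 1, N = library size = 1e6
  expect_equal(exp(mean(log(f$effective_size))), 1e6)
  r <- rpkm(m, f, setNames(c(1000, 500, 2000), rownames(m)))
  expect_equal(unname(r["g01", ]), rep(10, 3))

  # zero count -> RPKM exactly 0; zero length -> gene dropped with warning
  m0 <- mk_counts(matrix(c(0L, 4L, 8L, rep(50L, 6)), ncol = 3, byrow = TRUE))
  f0 <- upper_quartile_factors(m0)
  expect_warning(r0 <- rpkm(m0, f0, setNames(c(1000, 1000, 0), rownames(m0))),
                 "length 0")
  expect_equal(nrow(r0), 2)
  expect_identical(r0["g01", 1][[1]], 0)

  # uniform rescaling of every count leaves RPKM unchanged
  set.seed(4)
  raw <- matrix(rpois(60, 40) + 1L, ncol = 3)
  lens <- setNames(runif(20, 300, 3000), sprintf("g%02d", 1:20))
  mA <- mk_counts(raw); mB <- mk_counts(raw * 3L)
  rA <- rpkm(mA, upper_quartile_factors(mA), lens)
  rB <- rpkm(mB, upper_quartile_factors(mB), lens)
  expect_equal(rA, rB, tolerance = 1e-12)
})

test_that("translation efficiency is a guarded RPF/RNA ratio", {
  rpf <- matrix(c(4, 0, 6), ncol = 1,
                dimnames = list(c("a", "b", "c"), "ZT00_r1"))
  rna <- matrix(c(2, 5, 0), ncol = 1,
                dimnames = list(c("a", "b", "c"), "ZT00_r1"))
  te <- translation_efficiency(rpf, rna)
  expect_equal(te["a", 1][[1]], 2)       # definition
  expect_equal(te["b", 1][[1]], 0)       # zero numerator
  expect_true(is.na(te["c", 1]))         # zero denominator: undefined, not Inf
  expect_error(translation_efficiency(
    rpf, matrix(1, 1, 1, dimnames = list("z", "ZT00_r1"))), "disjoint gene")
})

test_that("proportional RPF/RNA counts give constant TE on noiseless data", {
  # RPF counts exactly 2x RNA counts with equal library sizes -> TE = 2
  # everywhere (the doubled footprint density is genuine signal, not depth,
  # so the library sizes are held equal rather than recomputed from sums)
  set.seed(8)
  d <- ts_design()
  raw <- matrix(rpois(50 * 24, 80) + 1L, ncol = 24,
                dimnames = list(sprintf("g%02d", 1:50), d$sample_id))
  rna <- count_matrix(raw, "RNA", "CDS", d)
  rpf <- count_matrix(raw * 2L, "RPF", "CDS", d)
  lens <- setNames(rep(1000, 50), rownames(raw))
  lib <- rep(1e5, 24)
  te <- translation_efficiency(
    rpkm(rpf, upper_quartile_factors(rpf, lib_size = lib), lens),
    rpkm(rna, upper_quartile_factors(rna, lib_size = lib), lens))
  expect_equal(unname(as.vector(te)), rep(2, length(te)), tolerance = 1e-6)

  # recomputing library sizes from the doubled matrix absorbs the global
  # factor instead: TE is then constant at 1 (per-matrix normalization)
  te1 <- translation_efficiency(
    rpkm(rpf, upper_quartile_factors(rpf), lens),
    rpkm(rna, upper_quartile_factors(rna), lens))
  expect_equal(unname(as.vector(te1)), rep(1, length(te1)), tolerance = 1e-6)
})
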