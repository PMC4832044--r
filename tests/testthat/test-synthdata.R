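test_that("default design is 12 time points x 2 replicates over 24 h", {
  d <- ts_design()
  expect_equal(nrow(d), 24)
  expect_equal(sort(unique(d$time)), seq(0, 22, by = 2))
  expect_equal(unname(table(d$time)), rep(2L, 12), ignore_attr = TRUE)
  expect_equal(design_period(d), 24)
  expect_error(ts_design(times = c(0, 6, 12, 24)), "\\[0, period\\)")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- sim_params(n_genes = 40, seed = 11)
  s1 <- simulate_counts(params = p)
  s2 <- simulate_counts(params = p)
  expect_identical(unclass(s1$rna), unclass(s2$rna))
  expect_identical(unclass(s1$rpf), unclass(s2$rpf))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(params = sim_params(n_genes = 40, seed = 12))
  expect_false(identical(unclass(s1$rna), unclass(s3$rna)))
})

test_that("truth classes follow the requested fractions and carry amplitudes", {
  p <- sim_params(n_genes = 200, fraction_rna_rhythmic = 0.2,
                  fraction_te_rhythmic = 0.1, fraction_both = 0.05, seed = 3)
  tr <- simulate_counts(params = p)$truth
  expect_equal(sum(tr$true_class == "rna_only"), 40)
  expect_equal(sum(tr$true_class == "translation_only"), 20)
  expect_equal(sum(tr$true_class == "both"), 10)
  expect_true(all(tr$true_amplitude_rna[tr$true_class == "rna_only"] > 1))
  expect_true(all(tr$true_amplitude_rna[tr$true_class == "arrhythmic"] == 1))
  expect_true(all(is.na(tr$true_phase_rna[tr$true_class == "arrhythmic"])))
  expect_true(all(tr$true_phase_te[tr$true_class == "translation_only"] >= 0 &
                    tr$true_phase_te[tr$true_class == "translation_only"] < 24))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(n_genes = 0), "positive")
  expect_error(sim_params(fraction_rna_rhythmic = 0.6, fraction_both = 0.6),
               "sum")
  expect_error(sim_params(fold_amplitude_range = c(0.5, 2)), "> 1")
  expect_error(sim_params(dispersion = -1), ">= 0")
  expect_error(simulate_counts(ts_design(times = c(0, 8, 16)),
                               sim_params(n_genes = 10)), "4 distinct")
})

test_that("arrhythmic genes have time-independent means and a planted fold-4
           gene peaks at 4x its trough in the noiseless limit", {
  # pure-null simulation: per-time mean counts show no trend in time
  p <- sim_params(n_genes = 400, fraction_rna_rhythmic = 0,
                  fraction_te_rhythmic = 0, fraction_both = 0,
                  dispersion = 0, library_size_range = c(1, 1), seed = 5)
  d <- ts_design()
  s <- simulate_counts(d, p)
  rel <- sweep(unclass(s$rna), 1, rowMeans(unclass(s$rna)), `/`)
  per_time <- tapply(colMeans(rel), d$time, mean)
  slope <- stats::coef(stats::lm(per_time ~ as.numeric(names(per_time))))[2]
  expect_lt(abs(slope), 0.005)  # fraction of the mean per hour

  # noiseless limit: Poisson at huge counts, fold amplitude exactly 4
  p4 <- sim_params(n_genes = 30, fraction_rna_rhythmic = 1,
                   fraction_te_rhythmic = 0, fraction_both = 0,
                   fold_amplitude_range = c(4, 4 + 1e-12), dispersion = 0,
                   log2_mesor_range = c(14, 14.0001),
                   library_size_range = c(1, 1), seed = 6)
  s4 <- simulate_counts(d, p4)
  tr <- s4$truth
  m <- unclass(s4$rna)
  for (i in seq_len(5)) {
    prof <- tapply(m[i, ], d$time, mean)
    # expected peak/trough of the mean curve; sampling on the 2-h grid sees
    # >= cos(2*pi*1/24) of the true peak, so allow a few percent
    expect_equal(max(prof) / min(prof), 4, tolerance = 0.06)
  }
})

test_that("zero dispersion yields Poisson-scale variance", {
  p <- sim_params(n_genes = 2000, fraction_rna_rhythmic = 0,
                  fraction_te_rhythmic = 0, fraction_both = 0,
                  dispersion = 0, log2_mesor_range = c(8, 8.0001),
                  library_size_range = c(1, 1), seed = 9)
  m <- unclass(simulate_counts(params = p)$rna)
  v <- apply(m, 1, var)
  mu <- rowMeans(m)
  # Poisson: var/mean ~ 1; the NB alternative at dispersion 0.05 would give
  # var/mean ~ 1 + 0.05*256 ~ 13.8
  expect_equal(median(v / mu), 1, tolerance = 0.15)
})

test_that("synthetic FASTQ manifest records origins and insert lengths", {
  one_class <- simulate_fastq(n_clean = 0, n_contaminant = c(mt_tRNA = 5),
                              seed = 2)
  expect_equal(nrow(one_class$manifest), 5)
  expect_true(all(one_class$manifest$origin == "mt_tRNA"))

  fixed_len <- simulate_fastq(n_clean = 10, n_contaminant = c(tRNA = 3),
                              length_distribution = c("30" = 1), seed = 2)
  expect_true(all(fixed_len$manifest$insert_length == 30))
  reads <- read_fastq(fixed_len$fastq)
  expect_equal(nrow(reads), 13)
  expect_true(all(nchar(reads$sequence) == 50))

  expect_error(simulate_fastq(length_distribution = c("80" = 1),
                              read_length = 50), "budget")
  expect_error(simulate_fastq(n_contaminant = c(nonsense = 2)),
               "unknown contaminant")
})
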