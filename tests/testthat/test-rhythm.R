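grid <- rep(seq(0, 22, by = 2), 2)

test_that("cosinor recovers a noiseless sinusoid exactly", {
  y <- 3 + cos(2 * pi * grid / 24)
  f <- fit_sinusoid(y, grid)
  expect_equal(f$mesor, 3, tolerance = 1e-10)
  expect_equal(f$a, 1, tolerance = 1e-10)
  expect_equal(f$b, 0, tolerance = 1e-10)
  expect_equal(f$fold_amplitude, 4, tolerance = 1e-10)
  expect_equal(circ_diff(f$phase, 0), 0, tolerance = 1e-8)
  expect_equal(f$rss, 0, tolerance = 1e-20)

  flat <- fit_sinusoid(rep(5, 24), grid)
  expect_equal(flat$fold_amplitude, 1, tolerance = 1e-12)

  expect_error(fit_sinusoid(1:4, rep(c(0, 12), 2)), "rank-deficient")
})

test_that("closed-form cosinor matches lm() and a brute-force grid oracle", {
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(24, sd = 2) + runif(1, 4, 8) +
      runif(1, 0, 2) * cos(2 * pi * (grid - runif(1, 0, 24)) / 24)
    f <- fit_sinusoid(y, grid)
    co <- coef(lm(y ~ cos(2 * pi * grid / 24) + sin(2 * pi * grid / 24)))
    expect_equal(unname(c(f$mesor, f$a, f$b)), unname(co), tolerance = 1e-10)
  }
  # brute force over (m, a, b) on one series, to grid resolution
  set.seed(32)
  y <- 5 + 0.8 * cos(2 * pi * (grid - 7) / 24) + rnorm(24, sd = 0.3)
  f <- fit_sinusoid(y, grid)
  gr <- expand.grid(m = seq(4, 6, 0.05), a = seq(-1.5, 1.5, 0.05),
                    b = seq(-1.5, 1.5, 0.05))
  X <- cbind(1, cos(2 * pi * grid / 24), sin(2 * pi * grid / 24))
  rss <- colSums((y - X %*% t(as.matrix(gr)))^2)
  best <- gr[which.min(rss), ]
  expect_lt(abs(f$mesor - best$m), 0.05)
  expect_lt(abs(f$a - best$a), 0.05)
  expect_lt(abs(f$b - best$b), 0.05)
})

test_that("amplitude ignores level shifts; phase tracks time shifts", {
  set.seed(33)
  y <- 2 + 1.2 * cos(2 * pi * (grid - 9) / 24) + rnorm(24, 0, 0.2)
  f1 <- fit_sinusoid(y, grid)
  f2 <- fit_sinusoid(y + 7, grid)
  expect_equal(f1$fold_amplitude, f2$fold_amplitude, tolerance = 1e-12)
  f3 <- fit_sinusoid(y, (grid + 5) %% 24)
  expect_equal(circ_diff(f3$phase, (f1$phase + 5) %% 24), 0,
               tolerance = 1e-8)
})

test_that("sigmoid fit recovers a noiseless step profile", {
  y <- ifelse(grid %in% seq(12, 22, 2), 4, 2)
  f <- fit_sigmoid(y, grid)
  expect_equal(f$low, 2, tolerance = 1e-3)
  expect_equal(f$high, 4, tolerance = 1e-3)
  expect_equal(f$fold_amplitude, 4, tolerance = 1e-2)
  expect_lt(f$rss, 1e-6)

  flat <- fit_sigmoid(rep(3, 24), grid)
  expect_equal(flat$low, flat$high, tolerance = 1e-9)
  expect_equal(flat$fold_amplitude, 1, tolerance = 1e-8)
})

test_that("sinusoid-generated data selects the sinusoid model", {
  # exact: a noiseless sinusoid is interpolated by the cosinor (rss 0), so
  # the sigmoid can never fit it strictly better
  y0 <- 5 + cos(2 * pi * (grid - 7) / 24)
  expect_lte(fit_sinusoid(y0, grid)$rss, fit_sigmoid(y0, grid)$rss)

  # noisy: BIC prefers the sinusoid for the large majority of genes (the
  # 4-parameter sigmoid can out-fit raw rss, but not after its BIC penalty)
  set.seed(34)
  chosen <- replicate(100, {
    y <- 5 + cos(2 * pi * (grid - runif(1, 0, 24)) / 24) + rnorm(24, 0, 0.3)
    select_model(y, grid)$model
  })
  expect_gte(mean(chosen == "sinusoid"), 0.8)
})

test_that("model selection guards degrees of freedom and scores the null", {
  # n = 4 observations at 4 distinct times: sigmoid (4 params) excluded
  y4 <- c(1, 2, 1.5, 1.2); t4 <- c(0, 6, 12, 18)
  sm <- select_model(y4, t4)
  expect_named(sm$fits, "sinusoid")

  # strong sinusoid: selected with a tiny p-value
  y <- 6 + 2 * cos(2 * pi * (grid - 4) / 24) + rnorm(24, 0, 0.05)
  sm2 <- select_model(y, grid)
  expect_equal(sm2$model, "sinusoid")
  expect_lt(sm2$p_value, 1e-12)

  # constant series: flat, amplitude exactly 1, p = 1
  sm3 <- select_model(rep(5, 24), grid)
  expect_equal(sm3$model, "flat")
  expect_equal(sm3$fold_amplitude, 1)
  expect_equal(sm3$p_value, 1)

  # under the null the selected-model p-value is approximately uniform
  # (model selection makes it mildly anti-conservative; the downstream
  # calling rule adds an amplitude gate and FDR correction on top)
  set.seed(35)
  p <- replicate(300, select_model(rnorm(24), grid)$p_value)
  expect_lt(abs(mean(p < 0.2) - 0.2), 0.1)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.1)
})

test_that("BH q-values match the hand step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  hand_bh <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(36)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_fdr(p), hand_bh(p), tolerance = 1e-12)
  }
})

test_that("rhythmic calls require both amplitude and FDR thresholds", {
  fits <- data.frame(gene_id = c("a", "b", "c", "d"),
                     fold_amplitude = c(2.0, 1.4, 3.0, 1.2),
                     p_value = c(0.001, 0.0005, 0.03, 0.5),
                     q_value = c(0.01, 0.001, 0.06, 0.6))
  calls <- call_rhythmic(fits)
  expect_equal(calls$rhythmic, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$reason, c(NA, "amplitude", "fdr", "amplitude,fdr"))
})

test_that("fit_rhythms drops undefined cells and skips sparse genes", {
  d <- ts_design()
  set.seed(37)
  mat <- matrix(2^(5 + rnorm(3 * 24, 0, 0.1)), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), d$sample_id))
  mat["g2", 1:20] <- NA        # only 4 defined samples: skipped
  mat["g3", 1:4] <- 0          # zeros dropped, 20 left: fitted
  fits <- fit_rhythms(mat, d, layer = "TE")
  expect_true(is.na(fits$p_value[fits$gene_id == "g2"]))
  expect_equal(fits$n_used[fits$gene_id == "g3"], 20)
  expect_false(is.na(fits$p_value[fits$gene_id == "g3"]))
  calls <- call_rhythmic(fits)
  expect_false(calls$rhythmic[calls$gene_id == "g2"])
  expect_equal(calls$reason[calls$gene_id == "g2"], "insufficient_data")
})
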