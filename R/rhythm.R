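#' Closed-form fixed-period cosinor fit
#'
#' Ordinary least squares of `y = m + a*cos(2*pi*t/period) +
#' b*sin(2*pi*t/period)` solved through the normal equations. On log2-scale
#' measurements the fitted curve's peak/trough ratio on the linear scale is
#' `fold_amplitude = 2^(2*sqrt(a^2+b^2))` and the peak time is
#' `phase = (period/(2*pi)) * atan2(b, a) mod period`.
#'
#' @param values numeric measurements (log2 scale for multiplicative
#'   amplitudes); non-finite values must be removed by the caller.
#' @param times sampling times in hours, same length as `values`; at least 3
#'   distinct times are needed for a full-rank fit (>= 4 recommended).
#' @param period rhythm period in hours.
#' @return list with `mesor` (m), `a`, `b`, `fold_amplitude`, `phase`,
#'   `rss`, `n`, `k = 3` parameters.
#' @examples
#' t <- rep(seq(0, 22, 2), 2)
#' f <- fit_sinusoid(3 + cos(2 * pi * t / 24), t)
#' c(f$mesor, f$fold_amplitude, f$phase)  # 3, 4, 0
#' @export
fit_sinusoid <- function(values, times, period = 24) {
  stopifnot(length(values) == length(times), all(is.finite(values)))
  if (length(unique(times)) < 3)
    stop("rank-deficient design: need >= 3 distinct times")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  beta <- solve(crossprod(X), crossprod(X, values))
  resid <- values - X %*% beta
  a <- beta[2]; b <- beta[3]
  R <- sqrt(a^2 + b^2)
  list(mesor = beta[1], a = a, b = b,
       fold_amplitude = 2^(2 * R),
       phase = (atan2(b, a) * period / (2 * pi)) %% period,
       rss = sum(resid^2), n = length(values), k = 3L)
}

# plateau profile of the circularized sigmoid: level rises from low to high
# at t0 and falls back half a period later, with logistic transitions of the
# given steepness (per hour). g(t) in (0,1); linear coefficients solved by
# least squares.
sigmoid_profile <- function(times, t0, steepness, period = 24) {
  h <- period / 4
  tc <- t0 + h                          # center of the high plateau
  d <- abs((times - tc) %% period)
  d <- pmin(d, period - d)              # circular distance
  stats::plogis(steepness * (h - d))
}

sigmoid_rss <- function(values, times, t0, steepness, period) {
  X <- cbind(1, sigmoid_profile(times, t0, steepness, period))
  fit <- stats::.lm.fit(X, values)
  sum(fit$residuals^2)
}

#' Circularized sigmoid (square-wave) rhythm fit
#'
#' Least-squares fit of a two-transition logistic profile on the circle: the
#' level switches from `low` to `high` at transition time `t0` and back half
#' a period later, with symmetric logistic transitions of the given
#' steepness. For fixed `(t0, steepness)` the levels enter linearly and are
#' profiled out; the nonlinear pair is found by a deterministic multi-start
#' search (t0 starts every 2 h, 1-D optimization of log-steepness at each,
#' then a local refinement of t0) — no random starts, so the fit is
#' reproducible without a seed.
#'
#' @inheritParams fit_sinusoid
#' @return list with `low`, `high` (log2 units, `high >= low`), `t0`
#'   (hours, the low-to-high transition), `steepness` (per hour),
#'   `fold_amplitude` (peak/trough of the fitted curve on the linear scale),
#'   `rss`, `n`, `k = 4` parameters.
#' @export
fit_sigmoid <- function(values, times, period = 24) {
  stopifnot(length(values) == length(times), all(is.finite(values)))
  if (length(unique(times)) < 4)
    stop("rank-deficient design: need >= 4 distinct times")
  ls_bounds <- log(c(0.05, 60))
  best_s <- function(t0, tol = 1e-4) {
    o <- stats::optimize(function(ls) sigmoid_rss(values, times, t0,
                                                  exp(ls), period),
                         interval = ls_bounds, tol = tol)
    c(o$minimum, o$objective)
  }
  starts <- seq(0, period - 2, by = 2)
  coarse <- vapply(starts, best_s, numeric(2), tol = 0.05)
  i <- which.min(coarse[2, ])
  t0 <- starts[i]; ls <- coarse[1, i]
  # local refinement: t0 within +/- 2 h of the best start, then steepness
  t0 <- stats::optimize(function(t) sigmoid_rss(values, times, t %% period,
                                                exp(ls), period),
                        interval = c(t0 - 2, t0 + 2), tol = 1e-4)$minimum %% period
  ls <- best_s(t0)[1]
  s <- exp(ls)
  X <- cbind(1, sigmoid_profile(times, t0, s, period))
  fit <- stats::.lm.fit(X, values)
  beta <- fit$coefficients
  if (beta[2] < 0) {                     # high plateau on the other half
    t0 <- (t0 + period / 2) %% period
    X <- cbind(1, sigmoid_profile(times, t0, s, period))
    fit <- stats::.lm.fit(X, values)
    beta <- fit$coefficients
  }
  h <- period / 4
  g_range <- stats::plogis(s * h) - stats::plogis(-s * h)
  span <- abs(beta[2]) * g_range        # curve max - min over the cycle
  low <- beta[1] + min(beta[2], 0) + abs(beta[2]) * stats::plogis(-s * h)
  list(low = low, high = low + span, t0 = t0, steepness = s,
       fold_amplitude = 2^span, rss = sum(fit$residuals^2),
       n = length(values), k = 4L)
}

#' Compare rhythm models against a flat baseline
#'
#' Fits flat, sinusoid and (sample size permitting) sigmoid models to one
#' series, selects among the non-flat candidates by BIC, and reports the
#' selected model together with an F-test p-value of the best candidate
#' against the flat model (numerator df = candidate parameters - 1). The
#' reported `model` is "flat" when the flat model's BIC beats both
#' candidates; the p-value is always the best candidate's, so it remains
#' uniform under the null and usable for FDR control. A candidate is
#' considered only when `n` exceeds its parameter count.
#'
#' @inheritParams fit_sinusoid
#' @return list with `model` ("flat", "sinusoid" or "sigmoid"), `p_value`,
#'   `mesor`, `fold_amplitude` (1 when flat), `phase` (sinusoid only),
#'   `fits` (the underlying model fits).
#' @export
select_model <- function(values, times, period = 24) {
  n <- length(values)
  flat_rss <- sum((values - mean(values))^2)
  bic <- function(rss, k) n * log(max(rss, 0) / n) + k * log(n)
  cand <- list()
  if (n > 3) cand$sinusoid <- fit_sinusoid(values, times, period)
  if (n > 4 && length(unique(times)) >= 4)
    cand$sigmoid <- fit_sigmoid(values, times, period)
  if (!length(cand)) stop("too few observations for any rhythm model")

  bics <- vapply(cand, function(f) bic(f$rss, f$k), numeric(1))
  # ties go to the sinusoid (listed first)
  best <- names(cand)[which.min(bics)]
  bf <- cand[[best]]
  df1 <- bf$k - 1L
  df2 <- n - bf$k
  gain <- max(flat_rss - bf$rss, 0)
  p <- if (gain == 0) 1
  else if (bf$rss == 0) 0
  else stats::pf((gain / df1) / (bf$rss / df2), df1, df2, lower.tail = FALSE)

  model <- if (bic(flat_rss, 1L) <= min(bics)) "flat" else best
  if (model == "flat") {
    list(model = "flat", p_value = p, mesor = mean(values),
         fold_amplitude = 1, phase = NA_real_, fits = cand)
  } else {
    list(model = model, p_value = p, mesor = bf$mesor %||% mean(values),
         fold_amplitude = bf$fold_amplitude,
         phase = if (model == "sinusoid") bf$phase else NA_real_,
         fits = cand)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) p_(j) * n / j`, capped at 1
#' and mapped back to input order. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric p-values in \[0, 1\] (NA allowed, propagated).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit rhythm models to every gene of an expression matrix
#'
#' Per-gene rhythmicity scan of an RPKM or TE matrix: values are
#' log2-transformed (cells that are 0 or undefined are dropped from that
#' gene's fit, no pseudocount), genes with fewer than `min_defined` usable
#' samples or fewer than 4 distinct times are skipped, each remaining gene is
#' run through [select_model()], and q-values are computed by
#' Benjamini-Hochberg within the layer.
#'
#' @param mat gene x sample matrix of RPKM or TE values (linear scale).
#' @param design a [ts_design()] matching the columns.
#' @param layer label recorded in the output ("RNA", "RPF" or "TE").
#' @param min_defined minimum usable samples per gene (default 8).
#' @return data.frame with one row per input gene: `gene_id`, `layer`,
#'   `n_used`, `model`, `mesor`, `fold_amplitude`, `phase`, `p_value`,
#'   `q_value`. Skipped genes carry NA fit fields.
#' @export
fit_rhythms <- function(mat, design, layer = c("RNA", "RPF", "TE"),
                        min_defined = 8L) {
  layer <- match.arg(layer)
  validate_design(design)
  stopifnot(identical(colnames(mat), design$sample_id))
  period <- design_period(design)
  genes <- rownames(mat)
  out <- data.frame(gene_id = genes, layer = layer, n_used = 0L,
                    model = NA_character_, mesor = NA_real_,
                    fold_amplitude = NA_real_, phase = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    v <- mat[i, ]
    ok <- is.finite(v) & v > 0
    out$n_used[i] <- sum(ok)
    if (sum(ok) < min_defined ||
        length(unique(design$time[ok])) < 4) next
    sm <- select_model(log2(v[ok]), design$time[ok], period)
    out$model[i] <- sm$model
    out$mesor[i] <- sm$mesor
    out$fold_amplitude[i] <- sm$fold_amplitude
    out$phase[i] <- sm$phase
    out$p_value[i] <- sm$p_value
  }
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Call rhythmic genes by amplitude and FDR
#'
#' A gene is rhythmic when its fitted peak-to-trough fold amplitude exceeds
#' `amp_threshold` AND its within-layer BH q-value is below `fdr_threshold`
#' (conventional thresholds: amplitude > 1.5, FDR < 0.05). For non-rhythmic
#' genes the failing criteria are recorded.
#'
#' @param fits result of [fit_rhythms()] (q-values present).
#' @param amp_threshold peak/trough fold amplitude threshold (exclusive).
#' @param fdr_threshold FDR threshold (exclusive).
#' @return `fits` with added `rhythmic` (logical; FALSE for skipped genes)
#'   and `reason` ("amplitude", "fdr", "amplitude,fdr", "insufficient_data",
#'   or NA when rhythmic).
#' @export
call_rhythmic <- function(fits, amp_threshold = 1.5, fdr_threshold = 0.05) {
  fitted <- !is.na(fits$p_value)
  amp_ok <- fitted & fits$fold_amplitude > amp_threshold
  fdr_ok <- fitted & fits$q_value < fdr_threshold
  fits$rhythmic <- amp_ok & fdr_ok
  reason <- rep(NA_character_, nrow(fits))
  reason[!fits$rhythmic] <- paste0(
    ifelse(!amp_ok[!fits$rhythmic], "amplitude", ""),
    ifelse(!amp_ok[!fits$rhythmic] & !fdr_ok[!fits$rhythmic], ",", ""),
    ifelse(!fdr_ok[!fits$rhythmic], "fdr", ""))
  reason[!fitted] <- "insufficient_data"
  fits$reason <- reason
  fits
}
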