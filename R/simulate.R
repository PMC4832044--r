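#' Parameters of the synthetic paired RPF/RNA time-course generator
#'
#' The generator plants multiplicative 24-h rhythms in mRNA abundance and/or
#' translation efficiency (TE) on a negative-binomial count background. A
#' gene's class is drawn from \{both, rna_only, translation_only,
#' arrhythmic\}: `fraction_rna_rhythmic` genes carry an mRNA rhythm only,
#' `fraction_te_rhythmic` a TE rhythm only, `fraction_both` both layers; the
#' remainder is arrhythmic.
#'
#' Amplitudes are "fold amplitudes": the peak/trough ratio of the noiseless
#' mean curve, so a planted fold of 4 means the peak mean is 4x the trough
#' mean. On the log2 scale the half-amplitude is `log2(fold)/2`. Planted
#' folds are drawn uniformly on `fold_amplitude_range` (defaults 2-4, chosen
#' so planted rhythms clear the field's conventional >1.5-fold calling
#' threshold), phases uniformly on [0, 24), and log2 mesors uniformly on
#' `log2_mesor_range` (default 2^5-2^9 expected counts, a realistic bulk
#' dynamic range at moderate depth).
#'
#' @param n_genes number of genes to simulate.
#' @param fraction_rna_rhythmic,fraction_te_rhythmic,fraction_both class
#'   proportions; their sum must be <= 1.
#' @param log2_mesor_range range of per-gene log2 baseline expected counts.
#' @param fold_amplitude_range range of planted peak/trough fold amplitudes
#'   (all > 1).
#' @param dispersion negative-binomial dispersion shared by all genes
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param library_size_range range of relative per-sample sequencing depths;
#'   depths are drawn uniformly and applied as multiplicative factors
#'   relative to their geometric mean.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return a `sim_params` list.
#' @seealso [simulate_counts()]
#' @export
sim_params <- function(n_genes = 1000,
                       fraction_rna_rhythmic = 0.1,
                       fraction_te_rhythmic = 0.1,
                       fraction_both = 0.1,
                       log2_mesor_range = c(5, 9),
                       fold_amplitude_range = c(2, 4),
                       dispersion = 0.05,
                       library_size_range = c(0.8, 1.25),
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            fraction_rna_rhythmic = fraction_rna_rhythmic,
            fraction_te_rhythmic = fraction_te_rhythmic,
            fraction_both = fraction_both,
            log2_mesor_range = log2_mesor_range,
            fold_amplitude_range = fold_amplitude_range,
            dispersion = dispersion,
            library_size_range = library_size_range,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (p$n_genes <= 0) stop("n_genes must be positive")
  fr <- c(p$fraction_rna_rhythmic, p$fraction_te_rhythmic, p$fraction_both)
  if (any(fr < 0) || sum(fr) > 1)
    stop("rhythmic fractions must be >= 0 and sum to <= 1")
  if (any(p$fold_amplitude_range <= 1))
    stop("planted fold amplitudes must be > 1")
  if (p$dispersion < 0) stop("dispersion must be >= 0")
  if (any(p$library_size_range <= 0)) stop("library sizes must be positive")
  invisible(p)
}

# NB draw parameterized by mean and dispersion; dispersion 0 degrades to
# Poisson (size = 1/dispersion -> Inf).
rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion == 0) return(stats::rpois(n, lambda = mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate paired RPF and RNA count matrices with known ground truth
#'
#' Per gene g and sample s at time t, the log2 mRNA mean is
#' `mu(g,t) = m_g + a_g * cos(2*pi*(t - phi_g)/24)` with log2 half-amplitude
#' `a_g = log2(fold_g)/2` for RNA-rhythmic genes and 0 otherwise. A TE offset
#' `tau(g,t)` of the same form (half-amplitude `log2(fold_te)/2`, its own
#' phase) is added for TE-rhythmic genes. RNA counts are drawn
#' negative-binomial with mean `L_s * 2^mu`, RPF counts with mean
#' `L_s * 2^(mu + tau)`, where `L_s` is the sample's relative depth
#' (geometric mean 1 across samples of each assay).
#'
#' @param design a [ts_design()]; at least 4 distinct times.
#' @param params a [sim_params()].
#' @return list with `rpf` and `rna` [count_matrix()] objects (CDS feature)
#'   and `truth`, a data.frame with one row per gene: `gene_id`,
#'   `true_class` in \{arrhythmic, rna_only, translation_only, both\},
#'   `true_amplitude_rna`, `true_amplitude_te` (fold units, 1 = flat),
#'   `true_phase_rna`, `true_phase_te` (hours, NA when flat).
#' @examples
#' sim <- simulate_counts(ts_design(), sim_params(n_genes = 50, seed = 7))
#' table(sim$truth$true_class)
#' @export
simulate_counts <- function(design = ts_design(), params = sim_params()) {
  validate_design(design, min_times = 4)
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_genes
  period <- design_period(design)
  gene_id <- sprintf("gene%05d", seq_len(n))

  n_rna  <- round(n * params$fraction_rna_rhythmic)
  n_te   <- round(n * params$fraction_te_rhythmic)
  n_both <- round(n * params$fraction_both)
  cls <- rep("arrhythmic", n)
  idx <- sample.int(n, n_rna + n_te + n_both)
  cls[idx[seq_len(n_rna)]] <- "rna_only"
  cls[idx[n_rna + seq_len(n_te)]] <- "translation_only"
  cls[idx[n_rna + n_te + seq_len(n_both)]] <- "both"

  mesor <- stats::runif(n, params$log2_mesor_range[1], params$log2_mesor_range[2])
  rna_rhy <- cls %in% c("rna_only", "both")
  te_rhy  <- cls %in% c("translation_only", "both")
  fold_rna <- ifelse(rna_rhy,
                     stats::runif(n, params$fold_amplitude_range[1],
                                  params$fold_amplitude_range[2]), 1)
  fold_te <- ifelse(te_rhy,
                    stats::runif(n, params$fold_amplitude_range[1],
                                 params$fold_amplitude_range[2]), 1)
  phase_rna <- ifelse(rna_rhy, stats::runif(n, 0, period), NA_real_)
  phase_te  <- ifelse(te_rhy, stats::runif(n, 0, period), NA_real_)

  lib <- function() {
    l <- stats::runif(nrow(design), params$library_size_range[1],
                      params$library_size_range[2])
    l / exp(mean(log(l)))          # relative depths, geometric mean 1
  }
  lib_rna <- lib()
  lib_rpf <- lib()

  tt <- design$time
  cosmat <- function(fold, phase) {
    a <- log2(fold) / 2
    out <- outer(a, rep(1, length(tt)))
    ph <- ifelse(is.na(phase), 0, phase)
    out * cos(2 * pi * outer(ph, tt, function(p, t) t - p) / period)
  }
  mu_rna_log2 <- mesor + cosmat(fold_rna, phase_rna)
  tau_log2 <- cosmat(fold_te, phase_te)

  mu_rna <- sweep(2^mu_rna_log2, 2, lib_rna, `*`)
  mu_rpf <- sweep(2^(mu_rna_log2 + tau_log2), 2, lib_rpf, `*`)

  draw <- function(mu) {
    m <- matrix(rnbinom_mu(length(mu), as.vector(mu), params$dispersion),
                nrow = n, dimnames = list(gene_id, design$sample_id))
    m
  }
  rna <- count_matrix(draw(mu_rna), assay = "RNA", feature = "CDS", design)
  rpf <- count_matrix(draw(mu_rpf), assay = "RPF", feature = "CDS", design)

  truth <- data.frame(gene_id = gene_id, true_class = cls,
                      true_amplitude_rna = fold_rna,
                      true_amplitude_te = fold_te,
                      true_phase_rna = phase_rna,
                      true_phase_te = phase_te,
                      stringsAsFactors = FALSE)
  list(rpf = rpf, rna = rna, truth = truth)
}
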