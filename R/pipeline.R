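#' Default pipeline configuration
#'
#' All thresholds default to the conventional values of the analysis: calling
#' thresholds amplitude > 1.5 and FDR < 0.05, detection cutoff mean RPKM >= 1
#' in both assays, footprint size window 26-35 nt, RNA size window 21-60 nt.
#'
#' @param mode "synthetic" (counts simulated with [simulate_counts()]) or
#'   "real" (count matrices provided as TSV paths).
#' @param ... overrides of any default field (see the returned list).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    seed = 1L,
    n_genes = 1000L,
    fraction_rna_rhythmic = 0.1,
    fraction_te_rhythmic = 0.1,
    fraction_both = 0.1,
    dispersion = 0.05,
    amp_threshold = 1.5,
    fdr_threshold = 0.05,
    min_expression = 1.0,
    min_defined = 8L,
    rpf_size = c(26L, 35L),
    rna_size = c(21L, 60L),
    rpf_offset = 12L,
    rna_offset = 0L,
    require_te = FALSE,
    cds_length = 1000,     # synthetic mode: common CDS length for RPKM (nt)
    rpf_counts = NULL,     # real mode: TSV paths, genes x samples
    rna_counts = NULL,
    sample_sheet = NULL,   # real mode: TSV with sample_id, time, replicate
    lengths = NULL,        # real mode: TSV with gene_id, length
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()], `mode` required.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$mode)) stop("config must set 'mode'")
  do.call(pipeline_config, c(list(mode = y$mode),
                             y[setdiff(names(y), "mode")]))
}

#' Validate a pipeline configuration
#'
#' Collects every violation rather than stopping at the first.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  for (f in c("amp_threshold", "fdr_threshold", "min_expression"))
    if (!is.numeric(config[[f]]) || config[[f]] <= 0)
      add(paste0(f, " must be positive"))
  for (f in c("rpf_size", "rna_size")) {
    w <- config[[f]]
    if (length(w) != 2 || w[1] < 1 || w[1] > w[2])
      add(paste0(f, ": min>max or invalid window"))
  }
  if (config$mode == "real") {
    for (f in c("rpf_counts", "rna_counts", "sample_sheet", "lengths")) {
      p <- config[[f]]
      if (is.null(p)) add(paste0("real mode requires '", f, "'"))
      else if (!file.exists(p)) add(paste0(f, ": file not found: ", p))
    }
  } else {
    if (config$n_genes <= 0) add("n_genes must be positive")
    fr <- config$fraction_rna_rhythmic + config$fraction_te_rhythmic +
      config$fraction_both
    if (fr > 1) add("rhythmic fractions sum to > 1")
  }
  errs
}

write_tsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

matrix_tsv <- function(m, path, header = NULL) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}

#' Read a gene x sample matrix written by the pipeline
#' @param path TSV with a `gene_id` column; `#` lines are comments.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full rhythm-classification pipeline
#'
#' Executes counts -> normalization -> RPKM -> TE -> per-layer rhythm
#' detection (RNA, RPF, TE) -> classification, persisting every stage's
#' table under `out_dir` when given, and returns all intermediate objects.
#' In synthetic mode the counts come from [simulate_counts()] under the
#' config's seed and the result additionally carries the truth table and the
#' truth-based evaluation.
#'
#' @param config a [pipeline_config()].
#' @return list with `factors_rpf`, `factors_rna`, `rpkm_rpf`, `rpkm_rna`,
#'   `te`, `fits` (per-layer list), `calls` (per-layer list),
#'   `classification`, `summary`; in synthetic mode also `truth` and
#'   `evaluation`.
#' @export
run_pipeline <- function(config = pipeline_config("synthetic")) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))

  if (config$mode == "synthetic") {
    params <- sim_params(n_genes = config$n_genes,
                         fraction_rna_rhythmic = config$fraction_rna_rhythmic,
                         fraction_te_rhythmic = config$fraction_te_rhythmic,
                         fraction_both = config$fraction_both,
                         dispersion = config$dispersion,
                         seed = config$seed)
    design <- ts_design()
    sim <- simulate_counts(design, params)
    rpf_counts <- sim$rpf; rna_counts <- sim$rna; truth <- sim$truth
    lengths <- stats::setNames(rep(config$cds_length, nrow(rpf_counts)),
                               rownames(rpf_counts))
  } else {
    rpf_m <- read_matrix_tsv(config$rpf_counts)
    rna_m <- read_matrix_tsv(config$rna_counts)
    sheet <- utils::read.table(config$sample_sheet, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    design <- ts_design(times = sort(unique(sheet$time)),
                        n_replicates = max(sheet$replicate))
    design <- design[match(colnames(rna_m), design$sample_id), ]
    attr(design, "period") <- 24
    class(design) <- c("ts_design", "data.frame")
    storage.mode(rpf_m) <- "integer"; storage.mode(rna_m) <- "integer"
    rpf_counts <- count_matrix(rpf_m, "RPF", "CDS", design)
    rna_counts <- count_matrix(rna_m, "RNA", "CDS", design)
    lt <- utils::read.table(config$lengths, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    lengths <- stats::setNames(lt$length, lt$gene_id)
    truth <- NULL
  }

  factors_rpf <- upper_quartile_factors(rpf_counts)
  factors_rna <- upper_quartile_factors(rna_counts)
  rpkm_rpf <- rpkm(rpf_counts, factors_rpf, lengths)
  rpkm_rna <- rpkm(rna_counts, factors_rna, lengths)
  te <- translation_efficiency(rpkm_rpf, rpkm_rna)

  detected <- detected_genes(rpkm_rpf, rpkm_rna, config$min_expression)
  layers <- list(RNA = rpkm_rna[detected, , drop = FALSE],
                 RPF = rpkm_rpf[detected, , drop = FALSE],
                 TE  = te[detected, , drop = FALSE])
  fits <- lapply(names(layers), function(l)
    fit_rhythms(layers[[l]], design, layer = l,
                min_defined = config$min_defined))
  names(fits) <- names(layers)
  calls <- lapply(fits, call_rhythmic, amp_threshold = config$amp_threshold,
                  fdr_threshold = config$fdr_threshold)

  classification <- classify_genes(calls$RNA, calls$RPF, calls$TE,
                                   genes = detected,
                                   require_te = config$require_te)
  res <- list(design = design, factors_rpf = factors_rpf,
              factors_rna = factors_rna, rpkm_rpf = rpkm_rpf,
              rpkm_rna = rpkm_rna, te = te, fits = fits, calls = calls,
              classification = classification)
  res$summary <- list(
    n_detected_genes = length(detected),
    n_per_category = as.list(table(factor(classification$category,
      levels = c("both", "rna_only", "translation_only", "arrhythmic")))),
    fraction_rhythmic_rna = mean(classification$rna_rhythmic),
    fraction_rhythmic_rpf = mean(classification$rpf_rhythmic),
    seed = config$seed)
  if (config$mode == "synthetic") {
    res$truth <- truth
    res$evaluation <- evaluate_against_truth(classification, truth)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hd <- sprintf("clocktide run, mode=%s, seed=%d", config$mode, config$seed)
    out <- function(f) file.path(config$out_dir, f)
    matrix_tsv(unclass(rpf_counts), out("counts_rpf.tsv"), hd)
    matrix_tsv(unclass(rna_counts), out("counts_rna.tsv"), hd)
    write_tsv(factors_rpf, out("factors_rpf.tsv"), hd)
    write_tsv(factors_rna, out("factors_rna.tsv"), hd)
    matrix_tsv(rpkm_rpf, out("rpkm_rpf.tsv"), hd)
    matrix_tsv(rpkm_rna, out("rpkm_rna.tsv"), hd)
    matrix_tsv(te, out("te.tsv"), hd)
    for (l in names(calls))
      write_tsv(calls[[l]], out(sprintf("rhythm_%s.tsv", tolower(l))), hd)
    write_tsv(classification, out("classification.tsv"), hd)
    if (!is.null(truth)) write_tsv(truth, out("truth.tsv"), hd)
    jsonlite::write_json(res$summary, out("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
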