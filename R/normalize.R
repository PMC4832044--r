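geomean <- function(x) exp(mean(log(x)))

#' Upper-quartile normalization factors
#'
#' Per-sample scaling factors from the upper-quartile method: for sample s,
#' `q_s` is the 75th percentile (linear interpolation, R quantile type 7) of
#' that sample's counts restricted to genes with positive total count across
#' samples, divided by the sample's library size (column sum); the factor is
#' `q_s / geomean(q)`, so factors have geometric mean 1. The effective
#' library size is `library_size * factor`.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param lib_size per-sample library sizes (total mapped-and-counted
#'   reads); defaults to the column sums of `counts`, but can be supplied
#'   when the matrix covers only part of the library.
#' @return data.frame per sample: `sample_id`, `library_size`, `uq_factor`,
#'   `effective_size`.
#' @export
upper_quartile_factors <- function(counts, lib_size = colSums(counts)) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  stopifnot(length(lib_size) == ncol(counts))
  lib <- lib_size
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  pos <- rowSums(counts) > 0
  if (!any(pos)) stop("no gene with a positive count")
  q <- apply(counts[pos, , drop = FALSE], 2, stats::quantile,
             probs = 0.75, type = 7, names = FALSE)
  if (any(q == 0))
    stop("upper quartile is zero (sample too sparse): ",
         paste(colnames(counts)[q == 0], collapse = ", "))
  qn <- q / lib
  f <- qn / geomean(qn)
  data.frame(sample_id = colnames(counts), library_size = unname(lib),
             uq_factor = unname(f), effective_size = unname(lib * f),
             stringsAsFactors = FALSE)
}

#' RPKM on upper-quartile-normalized counts
#'
#' `RPKM[g,s] = counts[g,s] / (length_g / 1000) / (effective_size_s / 1e6)`
#' with `effective_size_s = library_size_s * uq_factor_s` (proportional to
#' the sample's upper quartile, the depth proxy). Equivalently: counts are
#' first rescaled to the common depth N — the geometric mean over samples of
#' the effective library size ("geometric mean of normalized read counts per
#' million") — and then divided by `(length/1000) * (N/1e6)`; the two forms
#' are identical, values are comparable across samples, and the whole matrix
#' is invariant to a uniform rescaling of all counts. Genes with feature
#' length 0 are dropped with a warning.
#'
#' @param counts gene x sample count matrix.
#' @param factors result of [upper_quartile_factors()] on `counts`.
#' @param lengths named numeric vector of feature lengths (nt) covering the
#'   genes of `counts`; must be > 0 (zero-length genes are dropped).
#' @return numeric matrix of RPKM values, same dimnames as the retained
#'   genes x samples; 0 exactly where the count is 0.
#' @export
rpkm <- function(counts, factors, lengths) {
  stopifnot(identical(colnames(counts), factors$sample_id))
  if (any(is.na(lengths[rownames(counts)])))
    stop("lengths missing for some genes")
  len <- lengths[rownames(counts)]
  if (any(len < 0)) stop("negative feature length")
  if (any(len == 0)) {
    warning("dropping ", sum(len == 0), " gene(s) with feature length 0")
    counts <- counts[len > 0, , drop = FALSE]
    len <- len[len > 0]
  }
  norm <- sweep(unclass(counts), 2, factors$effective_size / 1e6, `/`)
  sweep(norm, 1, len / 1000, `/`)
}

#' Translation efficiency
#'
#' `TE[g,s] = RPF_RPKM[g,s] / RNA_RPKM[g,s]`, the footprint density per unit
#' mRNA. Cells with RNA RPKM 0 are undefined (NA), never infinite, and are
#' excluded from downstream rhythm fits. Gene/sample sets are inner-joined
#' with a message if they differ; disjoint gene sets are an error.
#'
#' @param rpf_rpkm,rna_rpkm RPKM matrices from [rpkm()].
#' @return numeric matrix of TE values with NA where RNA RPKM = 0.
#' @export
translation_efficiency <- function(rpf_rpkm, rna_rpkm) {
  genes <- intersect(rownames(rpf_rpkm), rownames(rna_rpkm))
  samples <- intersect(colnames(rpf_rpkm), colnames(rna_rpkm))
  if (!length(genes)) stop("disjoint gene sets")
  if (!length(samples)) stop("disjoint sample sets")
  if (length(genes) < max(nrow(rpf_rpkm), nrow(rna_rpkm)) ||
      length(samples) < max(ncol(rpf_rpkm), ncol(rna_rpkm)))
    message("translation_efficiency: inner join to ", length(genes),
            " genes x ", length(samples), " samples")
  num <- rpf_rpkm[genes, samples, drop = FALSE]
  den <- rna_rpkm[genes, samples, drop = FALSE]
  te <- num / den
  te[den == 0] <- NA_real_
  te
}
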