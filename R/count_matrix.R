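#' Construct a count matrix for one assay and one annotation feature
#'
#' A thin wrapper around an integer gene x sample matrix carrying the assay
#' ("RPF" or "RNA"), the annotation feature the counts were made over
#' ("UTR5", "CDS" or "UTR3") and the sampling design.
#'
#' @param counts integer matrix, genes in rows, samples in columns; row and
#'   column names required.
#' @param assay "RPF" or "RNA".
#' @param feature "UTR5", "CDS" or "UTR3".
#' @param design a [ts_design()] whose `sample_id`s match `colnames(counts)`.
#' @return a `count_matrix` (an integer matrix with attributes).
#' @export
count_matrix <- function(counts, assay = c("RPF", "RNA"),
                         feature = c("CDS", "UTR5", "UTR3"),
                         design) {
  assay <- match.arg(assay)
  feature <- match.arg(feature)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  validate_design(design, min_times = 1)
  if (!identical(colnames(counts), design$sample_id))
    stop("colnames(counts) must equal design$sample_id (same order)")
  storage.mode(counts) <- "integer"
  structure(counts, assay = assay, feature = feature, design = design,
            class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples [assay=%s, feature=%s]\n",
              nrow(x), ncol(x), attr(x, "assay"), attr(x, "feature")))
  invisible(x)
}

cm_design <- function(x) attr(x, "design")
cm_assay <- function(x) attr(x, "assay")

# matrices lose attributes under subsetting on purpose: downstream code
# passes the design explicitly where it matters
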