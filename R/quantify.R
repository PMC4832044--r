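#' Load a gene annotation with 5'UTR/CDS/3'UTR features
#'
#' Reads a GTF (Ensembl dialect: feature types `CDS`, `five_prime_utr`,
#' `three_prime_utr`, with `gene_id` attributes) and assembles, per gene, the
#' union of intervals of each feature class with derived feature lengths.
#' GTF 1-based closed coordinates are converted to 0-based half-open
#' internally by the interval machinery (`GRanges` keeps 1-based closed; all
#' arithmetic goes through IRanges so the convention is consistent).
#' Overlapping intervals within a gene and feature class are merged
#' (union-of-exons counting), so each genomic base contributes once to the
#' feature length.
#'
#' @param path GTF file path. Alternatively pass a data.frame with columns
#'   `gene_id`, `chrom`, `strand`, `feature` (one of UTR5/CDS/UTR3),
#'   `start`, `end` (1-based closed) to build an annotation directly.
#' @return a `gene_annotation`: list with `features`, a `GRanges` whose mcols
#'   carry `gene_id` and `feature`, and `genes`, a data.frame of `gene_id`,
#'   `chrom`, `strand` and `len_UTR5`, `len_CDS`, `len_UTR3` (nt).
#' @export
load_annotation <- function(path) {
  if (is.data.frame(path)) {
    df <- path
    stopifnot(all(c("gene_id", "chrom", "strand", "feature", "start", "end")
                  %in% names(df)))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    S4Vectors::mcols(gr)$feature <- df$feature
  } else {
    g <- rtracklayer::import(path, format = "gtf")
    type_map <- c(CDS = "CDS", five_prime_utr = "UTR5",
                  three_prime_utr = "UTR3")
    g <- g[as.character(g$type) %in% names(type_map)]
    if (!length(g)) stop("no CDS/UTR features found in ", path)
    if (any(is.na(g$gene_id)) || is.null(g$gene_id))
      stop("GTF records must carry gene_id attributes")
    gr <- GenomicRanges::granges(g)
    S4Vectors::mcols(gr)$gene_id <- g$gene_id
    S4Vectors::mcols(gr)$feature <- unname(type_map[as.character(g$type)])
  }
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("all annotation records must be stranded")

  # merge overlapping intervals per (gene, feature)
  key <- paste(gr$gene_id, gr$feature, sep = "\r")
  parts <- GenomicRanges::reduce(
    GenomicRanges::split(gr, factor(key, levels = unique(key))))
  merged <- unlist(parts, use.names = FALSE)
  ids <- strsplit(rep(names(parts), lengths(parts)), "\r", fixed = TRUE)
  S4Vectors::mcols(merged)$gene_id <- vapply(ids, `[`, "", 1L)
  S4Vectors::mcols(merged)$feature <- vapply(ids, `[`, "", 2L)

  gene_ids <- unique(merged$gene_id)
  len <- function(feat) vapply(gene_ids, function(g) {
    sel <- merged$gene_id == g & merged$feature == feat
    sum(GenomicRanges::width(merged[sel]))
  }, numeric(1))
  first <- match(gene_ids, merged$gene_id)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(merged))[first],
    strand = as.character(GenomicRanges::strand(merged))[first],
    len_UTR5 = len("UTR5"), len_CDS = len("CDS"), len_UTR3 = len("UTR3"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(genes$len_CDS == 0))
    warning("genes without CDS intervals: ",
            paste(genes$gene_id[genes$len_CDS == 0], collapse = ", "))
  structure(list(features = merged, genes = genes),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d feature intervals\n",
              nrow(x$genes), length(x$features)))
  invisible(x)
}

#' Feature lengths of an annotation
#' @param annotation a `gene_annotation`.
#' @param feature "UTR5", "CDS" or "UTR3".
#' @return named numeric vector, nt per gene.
#' @export
feature_lengths <- function(annotation, feature = c("CDS", "UTR5", "UTR3")) {
  feature <- match.arg(feature)
  stats::setNames(annotation$genes[[paste0("len_", feature)]],
                  annotation$genes$gene_id)
}

#' Read alignments from SAM/BAM or BED
#'
#' @param path SAM/BAM (requires Rsamtools) or 6-column BED file.
#' @param sample_id sample the alignments belong to.
#' @return data.frame with `read_id`, `chrom`, `strand`, `start`, `end`
#'   (1-based closed, as used by [assign_read()]), `sample_id`.
#' @export
read_alignments <- function(path, sample_id) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required to read SAM/BAM")
    if (ext == "sam")
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "strand", "pos", "qwidth"))
    b <- Rsamtools::scanBam(Rsamtools::BamFile(path), param = p)[[1]]
    keep <- !is.na(b$pos)
    data.frame(read_id = b$qname[keep],
               chrom = as.character(b$rname)[keep],
               strand = as.character(b$strand)[keep],
               start = b$pos[keep],
               end = b$pos[keep] + b$qwidth[keep] - 1L,
               sample_id = sample_id, stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("BED input must have 6 columns")
    data.frame(read_id = bed[[4]], chrom = bed[[1]], strand = bed[[6]],
               start = bed[[2]] + 1L, end = bed[[3]],
               sample_id = sample_id, stringsAsFactors = FALSE)
  }
}

#' Assign reads to (gene, feature) by their offset 5' end
#'
#' Each read is reduced to a single point: its 5'-end position (start on the
#' + strand, end on the - strand), shifted `offset` nt in the 3' direction.
#' The gene/feature whose interval contains that point, on the same strand,
#' is returned; antisense reads and reads whose point falls outside every
#' annotated feature are unassigned. Ties across overlapping genes are broken
#' by CDS over UTR, then by the lexicographically smallest gene id. The point
#' rule makes counts additive and unambiguous at feature junctions; a typical
#' offset is 0 for RNA-seq and ~12 nt for footprints (P-site).
#'
#' @param reads data.frame with `chrom`, `strand`, `start`, `end` (1-based
#'   closed) and optionally `read_id`, `sample_id`.
#' @param annotation a [load_annotation()] result.
#' @param offset 3'-direction shift of the 5' end, in nt.
#' @return character matrix-free data.frame: the input with `gene_id` and
#'   `feature` columns (NA where unassigned).
#' @export
assign_read <- function(reads, annotation, offset = 0L) {
  if (!nrow(reads)) {
    reads$gene_id <- character(0); reads$feature <- character(0)
    return(reads)
  }
  plus <- reads$strand == "+"
  point <- ifelse(plus, reads$start + offset, reads$end - offset)
  q <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(point, point),
                              strand = reads$strand)
  hits <- GenomicRanges::findOverlaps(q, annotation$features)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  feat <- annotation$features$feature[sh]
  gid <- annotation$features$gene_id[sh]
  # tie-break: CDS beats UTRs, then smallest gene_id
  pri <- ifelse(feat == "CDS", 0L, 1L)
  ord <- order(qh, pri, gid)
  first <- ord[!duplicated(qh[ord])]
  gene_id <- rep(NA_character_, nrow(reads))
  feature <- rep(NA_character_, nrow(reads))
  gene_id[qh[first]] <- gid[first]
  feature[qh[first]] <- feat[first]
  reads$gene_id <- gene_id
  reads$feature <- feature
  reads
}

#' Count assigned reads per gene into a count matrix
#'
#' Tallies [assign_read()] outcomes for one assay and one feature class into
#' a gene x sample [count_matrix()]. All genes of the annotation appear as
#' rows (zero-filled); reads assigned to other feature classes or unassigned
#' are reported, not counted.
#'
#' @param alignments data.frame of aligned reads (see [read_alignments()]),
#'   with `sample_id` values covered by `design$sample_id`.
#' @param annotation a [load_annotation()] result.
#' @param design a [ts_design()].
#' @param assay "RPF" or "RNA".
#' @param feature which feature class to count ("CDS", "UTR5" or "UTR3").
#' @param offset 5'-end shift passed to [assign_read()].
#' @return list with `counts` (a [count_matrix()]) and `summary`
#'   (data.frame per sample: `n_alignments`, `n_assigned`, `n_unassigned`;
#'   `n_assigned` counts reads assigned to the requested feature class).
#' @export
count_reads <- function(alignments, annotation, design,
                        assay = c("RPF", "RNA"),
                        feature = c("CDS", "UTR5", "UTR3"), offset = 0L) {
  assay <- match.arg(assay)
  feature <- match.arg(feature)
  validate_design(design, min_times = 1)
  bad <- setdiff(unique(alignments$sample_id), design$sample_id)
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))

  asg <- assign_read(alignments, annotation, offset = offset)
  sel <- !is.na(asg$feature) & asg$feature == feature
  genes <- annotation$genes$gene_id
  tab <- table(factor(asg$gene_id[sel], levels = genes),
               factor(asg$sample_id[sel], levels = design$sample_id))
  m <- matrix(as.integer(tab), nrow = length(genes),
              dimnames = list(genes, design$sample_id))
  n_aln <- table(factor(alignments$sample_id, levels = design$sample_id))
  n_asg <- table(factor(asg$sample_id[sel], levels = design$sample_id))
  summary <- data.frame(sample_id = design$sample_id,
                        n_alignments = as.integer(n_aln),
                        n_assigned = as.integer(n_asg),
                        n_unassigned = as.integer(n_aln) - as.integer(n_asg),
                        stringsAsFactors = FALSE)
  list(counts = count_matrix(m, assay = assay, feature = feature, design),
       summary = summary)
}
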