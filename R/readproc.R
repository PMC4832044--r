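#' Read a FASTQ file into a reads table
#'
#' @param path FASTQ path (gzip transparent).
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub(" .*", "", names(x)),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a reads table to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$read_id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Trim a 3' adapter from reads by exact suffix-prefix overlap
#'
#' Removes from each read the longest suffix that exactly matches a prefix of
#' the adapter, provided the overlap is at least `min_overlap` bases (so a
#' full adapter occurrence at the 3' end, or a partial adapter running off
#' the read end, is removed). Qualities are trimmed in lockstep. Reads with
#' no qualifying match are returned unchanged. No mismatches are tolerated.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` (qualities
#'   the same length as sequences).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter prefix length that must match (>= 1).
#' @return the reads table with trimmed `sequence`/`quality` and a logical
#'   `trimmed` column.
#' @examples
#' r <- data.frame(read_id = "r1", sequence = paste0("ACGTACGT", "AGATCG"),
#'                 quality = strrep("I", 14))
#' trim_adapter(r, "AGATCGGAAGAGC")$sequence  # "ACGTACGT"
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L) {
  stopifnot(nzchar(adapter), min_overlap >= 1)
  if (any(nchar(reads$quality) != nchar(reads$sequence)))
    stop("quality strings must match sequence lengths")
  seqs <- reads$sequence
  nc <- nchar(seqs)
  keep_len <- nc
  max_ov <- pmin(nc, nchar(adapter))
  # longest overlap wins: test from the longest candidate down
  for (i in seq_along(seqs)) {
    for (ov in seq(max_ov[i], min_overlap, by = -1L)) {
      if (ov < min_overlap) break
      if (substr(seqs[i], nc[i] - ov + 1L, nc[i]) ==
          substr(adapter, 1L, ov)) {
        keep_len[i] <- nc[i] - ov
        break
      }
    }
  }
  out <- reads
  out$sequence <- substr(seqs, 1L, keep_len)
  out$quality <- substr(reads$quality, 1L, keep_len)
  out$trimmed <- keep_len < nc
  out
}

#' Filter reads by insert length
#'
#' Retains reads whose (post-trimming) length lies in `[min_len, max_len]`,
#' inclusive on both ends. The conventional windows are 26-35 nt for
#' ribosome footprints and 21-60 nt for RNA-seq; see [size_window()].
#'
#' @param reads reads table.
#' @param min_len,max_len inclusive length bounds, `1 <= min_len <= max_len`.
#' @return list with `pass` (reads table) and `fail_count`.
#' @export
size_filter <- function(reads, min_len, max_len) {
  if (min_len < 1 || min_len > max_len)
    stop("require 1 <= min_len <= max_len")
  len <- nchar(reads$sequence)
  ok <- len >= min_len & len <= max_len
  list(pass = reads[ok, , drop = FALSE], fail_count = sum(!ok))
}

#' Size-filter window presets per assay
#'
#' @param mode "rpf" (footprints, 26-35 nt) or "rna" (21-60 nt).
#' @return integer vector `c(min_len, max_len)`.
#' @export
size_window <- function(mode = c("rpf", "rna")) {
  mode <- match.arg(mode)
  switch(mode, rpf = c(26L, 35L), rna = c(21L, 60L))
}

ref_kmer_index <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  unique(kmers[!grepl("N", kmers, fixed = TRUE)])
}

#' Sequentially deplete contaminant reads
#'
#' Tests each read against the contaminant classes in the given order; a read
#' matching class i is removed and attributed to that class, and never tested
#' against later classes (so attribution, not survival, depends on the
#' order). A read matches a class when it is an exact, full-length substring
#' of one of the class's reference sequences or their reverse complements;
#' candidate reads are pre-screened by an exact k-mer seed. Reads containing
#' N never match.
#'
#' @param reads reads table (all at least `k` bases long).
#' @param references ordered named list or character vector of FASTA paths,
#'   one per contaminant class, in depletion order (conventionally mouse
#'   rRNA, human rRNA, mouse mt-tRNA, mouse tRNA).
#' @param k seed k-mer length (default 18).
#' @return list with `surviving` (reads table) and `report`, a
#'   `filter_report`-style list: `input_count`, `removed_per_class` (named
#'   integer vector in class order), `surviving_count`.
#' @export
filter_contaminants <- function(reads, references, k = 18L) {
  if (!length(references)) stop("references must be non-empty")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named by contaminant class")
  n <- nrow(reads)
  if (n && min(nchar(reads$sequence)) < k)
    stop("k exceeds the shortest read length")

  ref_seqs <- lapply(references, function(p) {
    s <- as.character(Biostrings::readDNAStringSet(p))
    c(s, as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(s))))
  })
  idx <- lapply(ref_seqs, ref_kmer_index, k = k)

  assigned <- rep(NA_character_, n)
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  for (cl in names(references)) {
    todo <- which(is.na(assigned) & !has_n)
    if (!length(todo)) break
    seed_hit <- substr(reads$sequence[todo], 1L, k) %in% idx[[cl]]
    for (i in todo[seed_hit]) {
      if (any(grepl(reads$sequence[i], ref_seqs[[cl]], fixed = TRUE)))
        assigned[i] <- cl
    }
  }
  removed <- vapply(names(references),
                    function(cl) sum(assigned == cl, na.rm = TRUE),
                    integer(1))
  surviving <- reads[is.na(assigned), , drop = FALSE]
  list(surviving = surviving,
       report = list(input_count = n,
                     removed_per_class = removed,
                     surviving_count = nrow(surviving)))
}

#' Preprocess a FASTQ file: trim, size-filter, deplete contaminants
#'
#' Runs the full read-preprocessing chain on one FASTQ file: exact 3'
#' adapter trimming, insert-size filtering with the assay's window
#' ([size_window()]), and ordered contaminant depletion
#' ([filter_contaminants()]).
#'
#' @param fastq input FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param mode "rpf" or "rna" (sets the size window).
#' @param contaminants ordered named vector of FASTA paths (class ->
#'   reference); defaults to the bundled toy classes.
#' @param out optional output FASTQ path for surviving reads.
#' @param k seed k-mer length for contaminant matching.
#' @param min_overlap minimum adapter overlap for trimming.
#' @return list with `surviving` reads table and `report`: `input_count`,
#'   `trimmed_count`, `size_fail_count`, `size_pass_count`,
#'   `removed_per_class`, `surviving_count`. The buckets partition the
#'   input: `input_count = size_fail_count + size_pass_count` and
#'   `size_pass_count = sum(removed_per_class) + surviving_count`.
#' @export
preprocess_reads <- function(fastq, adapter, mode = c("rpf", "rna"),
                             contaminants = toy_references()[-1],
                             out = NULL, k = 18L, min_overlap = 3L) {
  mode <- match.arg(mode)
  reads <- read_fastq(fastq)
  trimmed <- trim_adapter(reads, adapter, min_overlap = min_overlap)
  win <- size_window(mode)
  sf <- size_filter(trimmed, win[1], win[2])
  fc <- filter_contaminants(sf$pass, contaminants, k = k)
  if (!is.null(out)) write_fastq(fc$surviving, out)
  report <- list(input_count = nrow(reads),
                 trimmed_count = sum(trimmed$trimmed),
                 size_fail_count = sf$fail_count,
                 size_pass_count = nrow(sf$pass),
                 removed_per_class = fc$report$removed_per_class,
                 surviving_count = fc$report$surviving_count)
  list(surviving = fc$surviving, report = report)
}
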