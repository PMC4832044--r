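#' Bundled toy reference sequences
#'
#' Paths to the small synthetic FASTA references shipped with the package:
#' a clean transcript set and the four contaminant classes that footprint
#' libraries are depleted of, in the order they are removed (mouse rRNA,
#' human rRNA, mouse mt-tRNA, mouse tRNA). The sequences are random toy
#' stand-ins for the real contaminant databases and are suitable only for
#' testing the preprocessing machinery, not for real depletion.
#'
#' @return named character vector of FASTA paths; the `clean` entry first,
#'   then the contaminant classes in depletion order.
#' @export
toy_references <- function() {
  f <- function(x) system.file("extdata", x, package = "clocktide",
                               mustWork = TRUE)
  c(clean      = f("toy_clean_transcripts.fa"),
    rRNA_mouse = f("toy_rRNA_mouse.fa"),
    rRNA_human = f("toy_rRNA_human.fa"),
    mt_tRNA    = f("toy_mt_tRNA.fa"),
    tRNA       = f("toy_tRNA.fa"))
}

#' Simulate a FASTQ file of adapter-tagged reads with known origin
#'
#' Emits reads built as insert + adapter (truncated to `read_length`
#' sequencing cycles), with inserts drawn as random substrings of the
#' bundled toy references: clean transcripts plus the four contaminant
#' classes. A manifest records each read's true origin and insert length, so
#' the preprocessing filter's per-class depletion report can be checked
#' against ground truth.
#'
#' @param n_clean number of reads drawn from the clean transcript set.
#' @param n_contaminant named integer vector, reads per contaminant class;
#'   names must be a subset of `c("rRNA_mouse","rRNA_human","mt_tRNA","tRNA")`.
#' @param length_distribution named numeric vector mapping insert length to
#'   probability (normalized internally), e.g. `c("30" = 1)`.
#' @param adapter 3' adapter sequence appended to every insert.
#' @param read_length sequencing cycles; the emitted read is the first
#'   `read_length` bases of insert + adapter (the full insert plus a full or
#'   partial adapter copy). Inserts longer than `read_length` are an error.
#' @param seed integer seed.
#' @param fastq_path,manifest_path output paths; defaults under `tempdir()`.
#' @return list with `fastq`, `manifest_path` and `manifest` (data.frame:
#'   `read_id`, `origin` in \{clean, rRNA_mouse, rRNA_human, mt_tRNA, tRNA\},
#'   `insert_length`).
#' @export
simulate_fastq <- function(n_clean = 100,
                           n_contaminant = c(rRNA_mouse = 50, rRNA_human = 20,
                                             mt_tRNA = 15, tRNA = 15),
                           length_distribution = stats::setNames(
                             rep(1 / 6, 6), 28:33),
                           adapter = "AGATCGGAAGAGCACACGTCT",
                           read_length = 50,
                           seed = 1L,
                           fastq_path = tempfile(fileext = ".fastq"),
                           manifest_path = tempfile(fileext = ".tsv")) {
  stopifnot(nzchar(adapter), n_clean >= 0)
  lens <- as.integer(names(length_distribution))
  if (any(is.na(lens)) || any(lens < 1))
    stop("length_distribution names must be integer lengths >= 1")
  if (any(lens > read_length))
    stop("insert length exceeds the read length budget (", read_length, ")")
  if (length(n_contaminant) &&
      !all(names(n_contaminant) %in% names(toy_references())[-1]))
    stop("unknown contaminant class in n_contaminant")
  set.seed(seed)

  refs <- toy_references()
  load_ref <- function(path) as.character(Biostrings::readDNAStringSet(path))
  origins <- c(rep("clean", n_clean),
               rep(names(n_contaminant), times = n_contaminant))
  n <- length(origins)
  prob <- length_distribution / sum(length_distribution)
  ins_len <- lens[sample.int(length(lens), n, replace = TRUE, prob = prob)]

  seqs_by_class <- lapply(refs, load_ref)
  insert <- character(n)
  for (i in seq_len(n)) {
    pool <- seqs_by_class[[origins[i]]]
    src <- pool[[sample.int(length(pool), 1)]]
    if (nchar(src) < ins_len[i]) stop("reference shorter than insert length")
    start <- sample.int(nchar(src) - ins_len[i] + 1, 1)
    insert[i] <- substr(src, start, start + ins_len[i] - 1)
  }
  read_seq <- substr(paste0(insert, adapter), 1, read_length)
  read_id <- sprintf("read%05d", seq_len(n))

  reads <- Biostrings::DNAStringSet(read_seq)
  names(reads) <- read_id
  quals <- Biostrings::BStringSet(vapply(nchar(read_seq), function(l)
    strrep("I", l), character(1)))
  Biostrings::writeXStringSet(reads, fastq_path, format = "fastq",
                              qualities = quals)

  manifest <- data.frame(read_id = read_id, origin = origins,
                         insert_length = ins_len, stringsAsFactors = FALSE)
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fastq = fastq_path, manifest_path = manifest_path, manifest = manifest)
}
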