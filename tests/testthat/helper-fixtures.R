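# shared fixture builders; everything is generated in code at test time

make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  data.frame(read_id = ids, sequence = seqs,
             quality = vapply(nchar(seqs), function(l) strrep("I", l), ""),
             stringsAsFactors = FALSE)
}

# single-exon gene: tx spans [tx_start, tx_end], CDS [cds_start, cds_end]
# (1-based closed); UTRs derived on the given strand
toy_annotation_df <- function(gene_id = "G1", chrom = "chr1", strand = "+",
                              tx = c(101, 400), cds = c(161, 340)) {
  utr_left <- c(tx[1], cds[1] - 1)
  utr_right <- c(cds[2] + 1, tx[2])
  u5 <- if (strand == "+") utr_left else utr_right
  u3 <- if (strand == "+") utr_right else utr_left
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             feature = c("UTR5", "CDS", "UTR3"),
             start = c(u5[1], cds[1], u3[1]),
             end = c(u5[2], cds[2], u3[2]), stringsAsFactors = FALSE)
}

write_toy_gtf <- function(path, strand = "+") {
  df <- toy_annotation_df(strand = strand)
  type <- c(UTR5 = "five_prime_utr", CDS = "CDS", UTR3 = "three_prime_utr")
  lines <- sprintf(
    '%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    df$chrom, type[df$feature], df$start, df$end, df$strand,
    df$gene_id, df$gene_id)
  writeLines(lines, path)
  path
}

circ_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
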