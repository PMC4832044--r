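#' Genes detected in both assays
#'
#' A gene counts as detected when its mean RPKM reaches `min_expression` in
#' both the footprint and the RNA matrix — the working definition of the
#' expressed gene universe that all rhythm classification is restricted to.
#'
#' @param rpf_rpkm,rna_rpkm RPKM matrices sharing the design.
#' @param min_expression mean-RPKM cutoff (default 1).
#' @return character vector of detected gene ids.
#' @export
detected_genes <- function(rpf_rpkm, rna_rpkm, min_expression = 1.0) {
  genes <- intersect(rownames(rpf_rpkm), rownames(rna_rpkm))
  ok <- rowMeans(rpf_rpkm[genes, , drop = FALSE]) >= min_expression &
    rowMeans(rna_rpkm[genes, , drop = FALSE]) >= min_expression
  genes[ok]
}

#' Classify genes by which layers are rhythmic
#'
#' Combines per-layer rhythm calls into four exclusive categories:
#' `both` (mRNA abundance and footprints rhythmic), `rna_only` (mRNA
#' rhythmic, footprints not), `translation_only` (footprints rhythmic on a
#' flat mRNA — rhythmicity generated at the level of protein synthesis), and
#' `arrhythmic`. The TE-layer call is carried alongside as supporting
#' evidence and is not required by default.
#'
#' @details In strict mode (`require_te = TRUE`) a gene is labelled
#' `translation_only` only when `rpf_rhythmic & !rna_rhythmic & te_rhythmic`;
#' genes with rhythmic footprints and flat mRNA but a non-rhythmic TE are
#' then labelled `arrhythmic` (the stricter evidence rule treats their
#' footprint rhythm as unsupported).
#'
#' @param rna_calls,rpf_calls,te_calls [call_rhythmic()] outputs for the
#'   three layers, each covering every gene to classify.
#' @param genes gene ids to classify (default: genes common to the three
#'   call sets); an error is raised if a requested gene is missing from any
#'   layer.
#' @param require_te require a rhythmic TE for the `translation_only` label.
#' @return data.frame: `gene_id`, `rna_rhythmic`, `rpf_rhythmic`,
#'   `te_rhythmic`, `category`.
#' @export
classify_genes <- function(rna_calls, rpf_calls, te_calls, genes = NULL,
                           require_te = FALSE) {
  if (is.null(genes))
    genes <- Reduce(intersect, list(rna_calls$gene_id, rpf_calls$gene_id,
                                    te_calls$gene_id))
  pick <- function(calls, layer) {
    i <- match(genes, calls$gene_id)
    if (any(is.na(i)))
      stop("gene(s) missing from ", layer, " calls: ",
           paste(utils::head(genes[is.na(i)], 5), collapse = ", "))
    calls$rhythmic[i]
  }
  rna <- pick(rna_calls, "RNA")
  rpf <- pick(rpf_calls, "RPF")
  te <- pick(te_calls, "TE")
  category <- ifelse(rna & rpf, "both",
              ifelse(rna & !rpf, "rna_only",
              ifelse(!rna & rpf, "translation_only", "arrhythmic")))
  if (require_te)
    category[category == "translation_only" & !te] <- "arrhythmic"
  data.frame(gene_id = genes, rna_rhythmic = rna, rpf_rhythmic = rpf,
             te_rhythmic = te, category = category, stringsAsFactors = FALSE)
}

#' Summarize classifications against simulated ground truth
#'
#' Synthetic-mode evaluation: per-category sensitivity (recall among genes
#' truly of that category) and specificity (true-negative rate among genes
#' truly not of it), plus the full confusion matrix.
#'
#' @param classifications [classify_genes()] output.
#' @param truth truth table from [simulate_counts()].
#' @return list with `n_detected_genes`, `n_per_category` (named counts over
#'   the detected set), `fraction_rhythmic_rna`, `fraction_rhythmic_rpf`,
#'   `confusion` (truth x called table) and `per_category`, a data.frame of
#'   sensitivity/specificity per category.
#' @export
evaluate_against_truth <- function(classifications, truth) {
  i <- match(classifications$gene_id, truth$gene_id)
  if (any(is.na(i))) stop("classified gene(s) absent from the truth table")
  lev <- c("both", "rna_only", "translation_only", "arrhythmic")
  called <- factor(classifications$category, levels = lev)
  true <- factor(truth$true_class[i], levels = lev)
  confusion <- table(truth = true, called = called)
  per_category <- do.call(rbind, lapply(lev, function(cl) {
    tp <- sum(true == cl & called == cl)
    fn <- sum(true == cl & called != cl)
    tn <- sum(true != cl & called != cl)
    fp <- sum(true != cl & called == cl)
    data.frame(category = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(n_detected_genes = nrow(classifications),
       n_per_category = stats::setNames(as.integer(table(called)), lev),
       fraction_rhythmic_rna = mean(classifications$rna_rhythmic),
       fraction_rhythmic_rpf = mean(classifications$rpf_rhythmic),
       confusion = confusion,
       per_category = per_category)
}
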