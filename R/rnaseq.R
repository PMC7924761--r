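#' Effective gene lengths as exon-union sums
#' @param genes a `gene_models` object.
#' @return named numeric vector of summed exon lengths (bp).
#' @export
effective_lengths <- function(genes) {
  ex <- genes$exons
  len <- vapply(split(ex$end - ex$start, ex$gene_id), sum, 0)
  len[genes$genes$gene_id]
}

#' Transcripts-per-million from gene counts and effective lengths
#'
#' `rate_i = count_i / length_i`; `TPM_i = 1e6 * rate_i / sum(rate)`.
#' Columns sum to 1e6. Replicate-averaged per-condition columns are added
#' when a sample sheet is supplied.
#'
#' @param counts gene x sample count matrix (rownames = gene ids).
#' @param lengths effective lengths (bp), recycled against rows by name if
#'   named.
#' @param samples optional sample sheet with `sample_id`, `condition`.
#' @return list with `tpm` (matrix) and, if `samples` given, `by_condition`
#'   (replicate-averaged matrix).
#' @export
tpm <- function(counts, lengths, samples = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("lengths must be > 0")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with zero total rate")
  tp <- 1e6 * sweep(rate, 2, tot, "/")
  out <- list(tpm = tp)
  if (!is.null(samples)) {
    conds <- unique(samples$condition)
    avg <- vapply(conds, function(cd)
      rowMeans(tp[, samples$sample_id[samples$condition == cd],
                  drop = FALSE]), numeric(nrow(tp)))
    out$by_condition <- avg
  }
  out
}

#' Differential gene expression via the shared count machinery
#'
#' Runs the negative-binomial Wald pipeline in pooled mode (expression is
#' not chromosome-stratified) with a single genome-wide BH adjustment.
#'
#' @param cm a [count_matrix()] of gene counts (genes as regions).
#' @param comparison list with `id`, `target`, `reference`.
#' @param stratified set TRUE to stratify by the regions' stratum labels
#'   (off by default for expression).
#' @return data.frame as [stratified_differential()].
#' @export
de_genes <- function(cm, comparison, stratified = FALSE) {
  stratified_differential(cm, comparison,
                          mode = if (stratified) "stratified" else "pooled")
}

#' Expression bias of genes neighbouring opened versus closed peaks
#'
#' Maps each condition-specific peak to its nearest gene, deduplicates
#' genes within the opened and closed groups (a gene near both kinds of
#' peak appears in both), extracts their expression log2 fold changes from
#' a differential-expression table, and compares the two groups with a
#' two-sided Welch two-sample t-test.
#'
#' @param de differential-expression table ([de_genes()]); orientation of
#'   its `log2fc` is reported unchanged.
#' @param annotations result of [annotate_peaks()] on the peak regions.
#' @param specificity result of [intersect_classify()] on the same regions.
#' @return list: `t`, `df` (Welch-Satterthwaite), `pvalue`,
#'   `mean_open`, `mean_closed`, `genes_open`, `genes_closed`.
#' @export
neighbor_expression_bias <- function(de, annotations, specificity) {
  key_a <- paste(annotations$chrom, annotations$start, annotations$end)
  key_s <- paste(specificity$chrom, specificity$start, specificity$end)
  ann <- annotations[match(key_s, key_a), , drop = FALSE]
  pick <- function(status) {
    g <- unique(ann$nearest_gene_id[specificity$status == status])
    lfc <- de$log2fc[match(g, de$name)]
    lfc[!is.na(lfc)]
  }
  open_lfc <- pick("opened_in_target")
  closed_lfc <- pick("closed_in_target")
  if (length(open_lfc) < 2 || length(closed_lfc) < 2)
    stop("each neighbour group needs >= 2 genes with expression results")
  tt <- stats::t.test(open_lfc, closed_lfc, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value,
       mean_open = mean(open_lfc), mean_closed = mean(closed_lfc),
       genes_open = length(open_lfc), genes_closed = length(closed_lfc))
}
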