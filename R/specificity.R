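#' Classify condition-specific regions from two differential comparisons
#'
#' A region significant (FDR below threshold) in both comparisons with a
#' shared fold-change sign is called `opened_in_target` or
#' `closed_in_target`; significant in both with opposite signs is
#' `discordant` (reported with a warning, excluded from opened/closed);
#' everything else is `not_specific`. Both inputs must be oriented
#' target/reference over the same region set.
#'
#' @param resA,resB results of [stratified_differential()] on the same
#'   consensus, both oriented with the shared target condition in the
#'   numerator.
#' @param fdr_threshold significance threshold (default 0.05).
#' @return data.frame: region columns, `status`, `log2fc_1`, `log2fc_2`,
#'   `fdr_1`, `fdr_2`.
#' @export
intersect_classify <- function(resA, resB, fdr_threshold = 0.05) {
  keyA <- paste(resA$chrom, resA$start, resA$end)
  keyB <- paste(resB$chrom, resB$start, resB$end)
  if (length(keyA) != length(keyB) || !setequal(keyA, keyB))
    stop("the two comparisons must cover the same region set")
  resB <- resB[match(keyA, keyB), , drop = FALSE]
  sigA <- resA$fdr < fdr_threshold
  sigB <- resB$fdr < fdr_threshold
  both <- sigA & sigB
  same_sign <- sign(resA$log2fc) == sign(resB$log2fc)
  status <- rep("not_specific", length(keyA))
  status[both & same_sign & resA$log2fc > 0] <- "opened_in_target"
  status[both & same_sign & resA$log2fc < 0] <- "closed_in_target"
  status[both & !same_sign] <- "discordant"
  if (any(status == "discordant"))
    warning(sum(status == "discordant"),
            " region(s) significant in both comparisons with opposite",
            " directions (discordant)")
  out <- data.frame(resA[, intersect(c("chrom", "start", "end", "name",
                                       "stratum"), names(resA))],
                    status = status,
                    log2fc_1 = resA$log2fc, log2fc_2 = resB$log2fc,
                    fdr_1 = resA$fdr, fdr_2 = resB$fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclusive membership counts over named sets (UpSet-style)
#'
#' @param sets named list (>= 2) of character id vectors.
#' @return data.frame `subset` (ampersand-joined set names), `count`;
#'   counts sum to the size of the union.
#' @export
upset_counts <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(key)
  data.frame(subset = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
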