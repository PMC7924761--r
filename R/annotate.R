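#' Annotate regions with their nearest gene and genomic feature class
#'
#' Each region midpoint is classified with precedence
#' promoter > exon > intron > intergenic, where promoter means within
#' `promoter_halfwidth` bp of any TSS, exon means inside an exon, intron
#' inside a gene span but not an exon. The nearest gene minimizes
#' |midpoint - TSS| over genes on the same chromosome (falling back to all
#' genes when the chromosome has none); ties go to the lexicographically
#' smallest gene id. Distance is signed (midpoint minus TSS), 0 inside the
#' promoter window.
#'
#' @param regions interval data.frame.
#' @param genes a `gene_models` object ([read_gene_models()]).
#' @param promoter_halfwidth promoter window half-width in bp (default 50).
#' @return data.frame: region columns, `midpoint`, `nearest_gene_id`,
#'   `distance`, `feature_class`.
#' @export
annotate_peaks <- function(regions, genes, promoter_halfwidth = 50) {
  if (nrow(genes$genes) == 0) stop("no genes supplied")
  g <- genes$genes
  ex <- genes$exons
  mid <- floor((regions$start + regions$end) / 2)
  n <- nrow(regions)
  nearest <- character(n); dist <- numeric(n); feat <- character(n)
  for (i in seq_len(n)) {
    same <- g$chrom == regions$chrom[i]
    cand <- if (any(same)) g[same, , drop = FALSE] else g
    d <- abs(mid[i] - cand$tss)
    best <- which(d == min(d))
    if (length(best) > 1)
      best <- best[order(cand$gene_id[best])[1]]
    nearest[i] <- cand$gene_id[best]
    dist[i] <- mid[i] - cand$tss[best]
    # promoter: within the window of ANY TSS on the same chromosome
    in_prom <- any(same) &&
      any(abs(mid[i] - g$tss[same]) <= promoter_halfwidth)
    sel_ex <- ex$chrom == regions$chrom[i] & ex$start <= mid[i] &
      mid[i] < ex$end
    in_gene <- any(same & g$start <= mid[i] & mid[i] < g$end)
    feat[i] <- if (in_prom) "promoter" else if (any(sel_ex)) "exon"
      else if (in_gene) "intron" else "intergenic"
    if (in_prom) dist[i] <- 0
  }
  out <- data.frame(regions[, intersect(c("chrom", "start", "end", "name"),
                                        names(regions))],
                    midpoint = mid, nearest_gene_id = nearest,
                    distance = dist, feature_class = feat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment against a custom background
#'
#' Upper-tail hypergeometric test of each term's overlap with the selected
#' gene set, relative to a user-supplied background (the selected set must
#' be a subset of it). Terms with no background gene are skipped. P-values
#' are BH-adjusted across terms.
#'
#' @param selected character vector of selected gene ids.
#' @param background character vector of background gene ids.
#' @param term_map data.frame with columns `term` and `gene`.
#' @return data.frame `term`, `k`, `K`, `n`, `N`, `pvalue`, `fdr`, ordered
#'   by p-value.
#' @export
term_enrichment <- function(selected, background, term_map) {
  selected <- unique(selected); background <- unique(background)
  if (!all(selected %in% background))
    stop("selected genes must be a subset of the background")
  N <- length(background); n <- length(selected)
  rows <- lapply(split(term_map$gene, term_map$term), unique)
  out <- lapply(names(rows), function(tm) {
    tg <- intersect(rows[[tm]], background)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no term with background genes")
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative distance of query intervals to a set of reference sites
#'
#' For each query midpoint lying between two consecutive reference
#' midpoints b1 < b2 (same chromosome), the relative distance is
#' `min(a - b1, b2 - a) / (b2 - b1)`, in [0, 0.5]; uniform placement gives
#' a flat distribution with mean 0.25, clustering at reference sites shifts
#' it toward 0. Query midpoints outside the reference span are skipped (and
#' counted). Also reports the fraction of query intervals overlapping any
#' reference interval by >= 1 bp.
#'
#' @param A query interval data.frame.
#' @param B reference interval data.frame; needs >= 2 sites on at least one
#'   chromosome shared with A.
#' @param chroms optional chromosome restriction (e.g. `"chrX"` only).
#' @return list: `d` (values), `histogram` (bins of 0.02), `mean`,
#'   `fraction_overlapping_B`, `n_used`, `n_skipped`.
#' @export
relative_distance <- function(A, B, chroms = NULL) {
  if (!is.null(chroms)) {
    A <- A[A$chrom %in% chroms, , drop = FALSE]
    B <- B[B$chrom %in% chroms, , drop = FALSE]
  }
  midA <- floor((A$start + A$end) / 2)
  midB <- floor((B$start + B$end) / 2)
  shared <- intersect(unique(A$chrom), unique(B$chrom))
  usable <- shared[vapply(shared, function(ch) sum(B$chrom == ch) >= 2,
                          TRUE)]
  if (length(usable) == 0)
    stop("need >= 2 reference sites on at least one shared chromosome")
  d <- numeric(0); n_skipped <- 0
  for (ch in usable) {
    a <- midA[A$chrom == ch]
    b <- sort(unique(midB[B$chrom == ch]))
    inside <- a >= b[1] & a <= b[length(b)]
    n_skipped <- n_skipped + sum(!inside)
    a <- a[inside]
    if (length(a) == 0) next
    i <- findInterval(a, b)
    at_site <- a == b[i]
    i2 <- pmin(i, length(b) - 1)  # guard for a == max(b)
    b1 <- b[i2]; b2 <- b[i2 + 1]
    di <- ifelse(at_site, 0, pmin(a - b1, b2 - a) / (b2 - b1))
    d <- c(d, di)
  }
  n_skipped <- n_skipped + sum(!(A$chrom %in% usable))
  breaks <- seq(0, 0.5, by = 0.02)
  bin <- pmin(floor(d / 0.02) + 1L, 25L)
  hcounts <- tabulate(bin, nbins = 25L)
  ir_a <- split(seq_len(nrow(A)), A$chrom)
  n_olap <- 0
  for (ch in intersect(names(ir_a), unique(B$chrom))) {
    ia <- IRanges::IRanges(A$start[A$chrom == ch] + 1,
                           A$end[A$chrom == ch])
    ib <- IRanges::IRanges(B$start[B$chrom == ch] + 1,
                           B$end[B$chrom == ch])
    n_olap <- n_olap + sum(IRanges::countOverlaps(ia, ib) > 0)
  }
  list(d = d,
       histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1], count = hcounts),
       mean = mean(d),
       fraction_overlapping_B = n_olap / nrow(A),
       n_used = length(d), n_skipped = n_skipped)
}
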