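#' Windowed fragment counts over a locus, with optional fold change
#'
#' Tiles `locus` with windows of `W` bp left to right (the last window may
#' be shorter and is reported with its true width); fragments are assigned
#' to the window containing their midpoint. When two sample groups are
#' given, a per-window moderated fold change of normalized counts is added:
#' `(mean_B/s + c) / (mean_A/s + c)` with `c = 0.5`.
#'
#' @param fragments_per_sample named list of interval data.frames.
#' @param locus one-row interval data.frame (or list with `chrom`, `start`,
#'   `end`).
#' @param W window width in bp (default 5000).
#' @param sf optional named size-factor vector (e.g. the autosome-stratum
#'   factors); defaults to 1 for every sample.
#' @param group_a,group_b optional character vectors of sample ids
#'   (reference = a); enables the `fold_change` column (b over a).
#' @return data.frame with `win_start`, `win_end`, `width`, one raw count
#'   column per sample, per-group normalized means, and `fold_change`.
#' @export
windowed_counts <- function(fragments_per_sample, locus, W = 5000,
                            sf = NULL, group_a = NULL, group_b = NULL) {
  stopifnot(W >= 1)
  ls <- locus$start[1]; le <- locus$end[1]; chr <- locus$chrom[1]
  starts <- seq(ls, le - 1, by = W)
  ends <- pmin(starts + W, le)
  ids <- names(fragments_per_sample)
  if (is.null(sf)) sf <- stats::setNames(rep(1, length(ids)), ids)
  cnt <- sapply(fragments_per_sample, function(fr) {
    mid <- floor((fr$start + fr$end) / 2)
    mid <- mid[fr$chrom == chr & mid >= ls & mid < le]
    tabulate(floor((mid - ls) / W) + 1L, nbins = length(starts))
  })
  cnt <- matrix(cnt, nrow = length(starts),
                dimnames = list(NULL, ids))
  out <- data.frame(win_start = starts, win_end = ends,
                    width = ends - starts)
  for (id in ids) out[[paste0("count_", id)]] <- cnt[, id]
  if (!is.null(group_a) && !is.null(group_b)) {
    norm <- sweep(cnt, 2, sf[ids], "/")
    ma <- rowMeans(norm[, group_a, drop = FALSE])
    mb <- rowMeans(norm[, group_b, drop = FALSE])
    out$norm_mean_a <- ma
    out$norm_mean_b <- mb
    out$fold_change <- (mb + 0.5) / (ma + 0.5)
  }
  out
}

#' Count fragments across whole gene loci
#'
#' Each fragment is assigned by its midpoint to every gene whose span
#' contains it (overlapping genes each count it once).
#'
#' @param fragments_per_sample named list of interval data.frames.
#' @param genes a `gene_models` object.
#' @return data.frame `gene_id`, `length` (span bp), then per sample
#'   `count_<id>` and `rate_<id>` (count per bp).
#' @export
gene_scale_counts <- function(fragments_per_sample, genes) {
  g <- genes$genes
  out <- data.frame(gene_id = g$gene_id, length = g$end - g$start,
                    stringsAsFactors = FALSE)
  for (id in names(fragments_per_sample)) {
    fr <- fragments_per_sample[[id]]
    mid <- floor((fr$start + fr$end) / 2)
    cnt <- vapply(seq_len(nrow(g)), function(i)
      sum(fr$chrom == g$chrom[i] & mid >= g$start[i] & mid < g$end[i]), 0)
    out[[paste0("count_", id)]] <- cnt
    out[[paste0("rate_", id)]] <- cnt / out$length
  }
  out
}

#' Turn a gene-scale count table into a count matrix for differential tests
#'
#' @param gc result of [gene_scale_counts()].
#' @param genes the `gene_models` object used to build it.
#' @param samples sample sheet whose `sample_id`s match the count columns.
#' @param genome optional [genome_spec()] for stratum labels.
#' @return A [count_matrix()] with genes as regions.
#' @export
gene_counts_matrix <- function(gc, genes, samples, genome = NULL) {
  g <- genes$genes[match(gc$gene_id, genes$genes$gene_id), , drop = FALSE]
  regions <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                        name = gc$gene_id,
                        stratum = if (!is.null(genome))
                          chrom_stratum(g$chrom, genome) else "autosome",
                        stringsAsFactors = FALSE)
  counts <- as.matrix(gc[, paste0("count_", samples$sample_id),
                         drop = FALSE])
  count_matrix(regions, samples, counts)
}

#' Anchored signal matrix over regions (center or scaled-body mode)
#'
#' Center mode averages a per-bp track within equal bins across
#' `[midpoint - flank, midpoint + flank)` of each region. Scaled-body mode
#' rescales each region body to `bins` bins and adds `flank_bins` native-bp
#' bins on each side; minus-strand regions are reversed so profiles read
#' 5' to 3'. Bins extending beyond a chromosome are masked (NA) and
#' excluded from the mean profile.
#'
#' @param track named list of per-bp numeric vectors (see
#'   [read_bedgraph()]).
#' @param regions interval data.frame; a `strand` column is honoured in
#'   scaled mode.
#' @param mode `"center"` or `"scaled"`.
#' @param flank flank size in bp.
#' @param bins number of bins (center mode: across the whole window;
#'   scaled mode: across the body).
#' @param flank_bins bins per flank in scaled mode.
#' @return list with `matrix` (regions x bins, NA = masked) and `profile`
#'   (column means over unmasked cells).
#' @export
anchored_signal <- function(track, regions, mode = c("center", "scaled"),
                            flank = 1000, bins = 50, flank_bins = 10) {
  mode <- match.arg(mode)
  stopifnot(bins >= 1)
  n <- nrow(regions)
  bin_mean <- function(chr, lo, hi, nb) {
    # mean track signal in nb equal bins over [lo, hi); NA outside chrom
    v <- track[[chr]]
    if (is.null(v)) stop("no track for chromosome ", chr)
    L <- length(v)
    edges <- round(seq(lo, hi, length.out = nb + 1))
    vapply(seq_len(nb), function(b) {
      a <- edges[b]; z <- edges[b + 1]
      if (a >= z) z <- a + 1
      if (a < 0 || z > L) return(NA_real_)
      mean(v[(a + 1):z])
    }, 0)
  }
  if (mode == "center") {
    mat <- t(vapply(seq_len(n), function(i) {
      mid <- floor((regions$start[i] + regions$end[i]) / 2)
      bin_mean(regions$chrom[i], mid - flank, mid + flank, bins)
    }, numeric(bins)))
  } else {
    total <- 2 * flank_bins + bins
    mat <- t(vapply(seq_len(n), function(i) {
      ch <- regions$chrom[i]
      row <- c(bin_mean(ch, regions$start[i] - flank, regions$start[i],
                        flank_bins),
               bin_mean(ch, regions$start[i], regions$end[i], bins),
               bin_mean(ch, regions$end[i], regions$end[i] + flank,
                        flank_bins))
      if (!is.null(regions$strand) && regions$strand[i] == "-")
        row <- rev(row)
      row
    }, numeric(total)))
  }
  list(matrix = mat, profile = colMeans(mat, na.rm = TRUE))
}

#' Pairwise rank correlation of binned fragment counts
#'
#' The genome is tiled into `bin` bp bins; per-bin midpoint counts per
#' sample are compared by Spearman correlation.
#'
#' @param fragments_per_sample named list of interval data.frames (>= 2).
#' @param genome a [genome_spec()].
#' @param bin bin width, bp (default 10000).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(fragments_per_sample, genome, bin = 10000) {
  if (length(fragments_per_sample) < 2) stop("need >= 2 samples")
  nb <- sum(ceiling(genome$length / bin))
  offs <- cumsum(c(0, ceiling(genome$length / bin)))
  counts <- sapply(fragments_per_sample, function(fr) {
    mid <- floor((fr$start + fr$end) / 2)
    ci <- match(fr$chrom, genome$chrom)
    tabulate(offs[ci] + floor(mid / bin) + 1L, nbins = nb)
  })
  stats::cor(counts, method = "spearman")
}

#' Per-sample fraction of fragments per chromosome stratum
#'
#' @param fragments_per_sample named list of interval data.frames.
#' @param genome a [genome_spec()].
#' @return data.frame `sample_id`, `stratum`, `fraction`; fractions sum to
#'   1 within each sample.
#' @export
chrom_read_fractions <- function(fragments_per_sample, genome) {
  out <- lapply(names(fragments_per_sample), function(id) {
    fr <- fragments_per_sample[[id]]
    st <- chrom_stratum(fr$chrom, genome)
    tab <- table(factor(st, levels = unique(genome$stratum)))
    data.frame(sample_id = id, stratum = names(tab),
               fraction = as.numeric(tab) / nrow(fr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Squared correlation of accessibility and expression on log scale
#'
#' Pearson r^2 of `log10(x + 1)`-transformed normalized gene accessibility
#' (count per bp) against expression (TPM) over shared genes.
#'
#' @param accessibility named numeric vector (gene-level normalized
#'   accessibility).
#' @param expression named numeric vector (TPM).
#' @return list `r2`, `n` (shared genes).
#' @export
accessibility_expression_r2 <- function(accessibility, expression) {
  shared <- intersect(names(accessibility), names(expression))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  r <- stats::cor(log10(accessibility[shared] + 1),
                  log10(expression[shared] + 1))
  list(r2 = r^2, n = length(shared))
}
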