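#' Build consensus regions from several peak sets
#'
#' Positions covered by peaks from at least `min_samples` of the input sets
#' are retained; maximal runs of retained positions become the consensus
#' regions used as the shared coordinate frame for differential testing.
#' Within a set, overlapping peaks count once.
#'
#' @param peak_sets list of peak data.frames (need `chrom`, `start`, `end`).
#' @param min_samples minimum number of supporting sets per position.
#' @return interval data.frame of disjoint consensus regions, named
#'   `consensus_00001`, ...
#' @export
build_consensus <- function(peak_sets, min_samples = 2L) {
  if (length(peak_sets) < 1) stop("need at least one peak set")
  if (min_samples > length(peak_sets))
    stop("min_samples exceeds number of peak sets")
  chroms <- unique(unlist(lapply(peak_sets, function(p) p$chrom)))
  out <- list()
  for (chr in sort(chroms)) {
    per_set <- lapply(peak_sets, function(p) {
      sel <- p$chrom == chr
      IRanges::reduce(IRanges::IRanges(start = p$start[sel] + 1,
                                       end = p$end[sel]))
    })
    width <- max(vapply(per_set, function(ir)
      if (length(ir)) max(IRanges::end(ir)) else 0L, 0))
    cov <- Reduce(`+`, lapply(per_set, IRanges::coverage, width = width))
    sl <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
    if (length(sl) > 0)
      out[[chr]] <- data.frame(chrom = chr, start = IRanges::start(sl) - 1,
                               end = IRanges::end(sl),
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(make_intervals(character(0), numeric(0), numeric(0))[0, ])
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  make_intervals(df$chrom, df$start, df$end,
                 name = sprintf("consensus_%05d", seq_len(nrow(df))))
}

#' Count fragment midpoints in disjoint regions
#'
#' A fragment is assigned to the (at most one) region containing its
#' midpoint, using half-open convention: a midpoint equal to `start` counts,
#' one equal to `end` does not.
#'
#' @param fragments_per_sample named list of interval data.frames.
#' @param regions disjoint interval data.frame (e.g. [build_consensus()]).
#' @param samples optional sample sheet (`sample_id`, `condition`, ...);
#'   defaults to the list names as both id and condition.
#' @param genome optional [genome_spec()] supplying stratum labels.
#' @return A [count_matrix()].
#' @export
count_in_regions <- function(fragments_per_sample, regions, samples = NULL,
                             genome = NULL) {
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  by_chr <- split(seq_len(nrow(regions)), regions$chrom)
  for (idx in by_chr) {
    s <- regions$start[idx]; e <- regions$end[idx]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)]))
      stop("overlapping regions; counting requires a disjoint region set")
  }
  if (is.null(samples))
    samples <- data.frame(sample_id = names(fragments_per_sample),
                          condition = names(fragments_per_sample),
                          stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(regions), length(fragments_per_sample))
  for (j in seq_along(fragments_per_sample)) {
    fr <- fragments_per_sample[[j]]
    mid <- floor((fr$start + fr$end) / 2)
    for (chr in names(by_chr)) {
      idx <- by_chr[[chr]]
      sel <- fr$chrom == chr
      if (!any(sel)) next
      # half-open membership: start <= mid < end
      pos <- findInterval(mid[sel], regions$start[idx])
      ok <- pos >= 1 & pos <= length(idx)
      pos_ok <- pos[ok]
      inside <- mid[sel][ok] < regions$end[idx][pos_ok]
      counts[idx, j] <- counts[idx, j] +
        tabulate(pos_ok[inside], nbins = length(idx))
    }
  }
  if (!("name" %in% names(regions)) || anyNA(regions$name))
    regions$name <- sprintf("region_%05d", seq_len(nrow(regions)))
  regions$stratum <- if (!is.null(genome)) {
    chrom_stratum(regions$chrom, genome)
  } else if ("stratum" %in% names(regions)) regions$stratum else "autosome"
  count_matrix(regions[, c("chrom", "start", "end", "name", "stratum")],
               samples, counts)
}

# median-of-ratios size factors for a plain count matrix (samples in columns),
# rescaled so the geometric mean of the factors is 1
median_ratio_sf <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos))
    stop("no region with all-positive counts in stratum; ",
         "increase simulation depth or region set")
  m <- mat[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  s <- apply(m / ref, 2, stats::median)
  s / exp(mean(log(s)))
}

#' Per-stratum or pooled median-of-ratios size factors
#'
#' The reference is the per-region geometric mean over samples (regions with
#' any zero excluded); each sample's factor is the median ratio to the
#' reference, rescaled to geometric mean 1 within each stratum.
#'
#' @param cm a [count_matrix()].
#' @param mode `"stratified"` (independent factors within each stratum) or
#'   `"pooled"` (one factor per sample over all regions).
#' @return data.frame `sample_id`, `stratum`, `sf`.
#' @export
size_factors <- function(cm, mode = c("stratified", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    s <- median_ratio_sf(cm$counts)
    return(data.frame(sample_id = cm$samples$sample_id, stratum = "pooled",
                      sf = as.numeric(s), stringsAsFactors = FALSE))
  }
  out <- lapply(unique(cm$regions$stratum), function(st) {
    s <- median_ratio_sf(cm$counts[cm$regions$stratum == st, , drop = FALSE])
    data.frame(sample_id = cm$samples$sample_id, stratum = st,
               sf = as.numeric(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Estimate negative-binomial dispersion with a 1/mean trend
#'
#' On normalized counts, per-region method-of-moments dispersions pooled
#' within condition groups are fitted with the trend
#' `alpha(m) = a0 + a1/m` by least squares over regions with mean above 1;
#' final dispersions are the trend values floored at `alpha_floor`. With
#' fewer than 10 usable regions the median raw dispersion is used instead.
#'
#' @param mat integer count matrix (regions x samples).
#' @param sf numeric size factors, one per column.
#' @param groups list of column-index vectors, one per condition group
#'   (each of size >= 2).
#' @param alpha_floor lower bound for the final dispersion.
#' @return list with `raw`, `fitted`, `final` per-region vectors and the
#'   trend coefficients `a0`, `a1`.
#' @export
estimate_dispersion <- function(mat, sf, groups, alpha_floor = 1e-4) {
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 samples")
  y <- sweep(mat, 2, sf, "/")
  n <- nrow(mat)
  m_i <- rowMeans(y)
  # variance pooled within groups
  ss <- 0; df <- 0
  for (g in groups) {
    yg <- y[, g, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
    df <- df + (length(g) - 1)
  }
  v_i <- ss / df
  raw <- ifelse(m_i > 0, pmax(0, (v_i - m_i) / m_i^2), 0)
  use <- m_i > 1
  if (sum(use) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / m_i[use]), raw[use])
    a0 <- fit$coefficients[1]; a1 <- fit$coefficients[2]
    fitted <- a0 + a1 / pmax(m_i, 1e-8)
  } else {
    a0 <- stats::median(raw); a1 <- 0
    fitted <- rep(a0, n)
  }
  list(raw = raw, fitted = fitted, final = pmax(fitted, alpha_floor),
       a0 = unname(a0), a1 = unname(a1))
}

#' Wald test on moderated group means of normalized counts
#'
#' Log2 fold change is `log2((m_B + c)/(m_A + c))` with moderation constant
#' `c = 0.5` on normalized-count means; its standard error propagates the
#' negative-binomial variance `mu + alpha mu^2` of each sample through the
#' group means. The z statistic is referred to the standard normal,
#' two-sided. Orientation: group B over group A.
#'
#' @param mat count matrix (regions x samples).
#' @param sf size factors per column.
#' @param alpha per-region final dispersions.
#' @param groupA,groupB column indices of the two groups (reference = A).
#' @param moderation moderation constant `c` (default 0.5).
#' @return data.frame `base_mean`, `log2fc`, `se`, `wald_z`, `pvalue`.
#' @export
nb_wald_test <- function(mat, sf, alpha, groupA, groupB, moderation = 0.5) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("empty sample group")
  y <- sweep(mat, 2, sf, "/")
  c0 <- moderation
  grp_stats <- function(g) {
    mg <- rowMeans(y[, g, drop = FALSE])
    mu_hat <- outer(mg, sf[g])          # mu_hat_ij = s_j * m_g
    var_m <- rowSums(sweep(mu_hat + alpha * mu_hat^2, 2, sf[g]^2, "/")) /
      length(g)^2
    list(m = mg, var = var_m)
  }
  A <- grp_stats(groupA); B <- grp_stats(groupB)
  log2fc <- log2((B$m + c0) / (A$m + c0))
  se <- (1 / log(2)) * sqrt(A$var / (A$m + c0)^2 + B$var / (B$m + c0)^2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(base_mean = rowMeans(y), log2fc = log2fc, se = se,
             wald_z = z, pvalue = p)
}

#' Chromosome-stratified (or pooled) differential accessibility
#'
#' In stratified mode, size factors, dispersion trend, Wald tests and
#' Benjamini-Hochberg adjustment are computed independently within the X and
#' autosome strata, then the per-stratum lists are concatenated. Pooled mode
#' uses one normalization and one global adjustment over all regions, which
#' reproduces the X-dosage bias that the stratified correction removes.
#'
#' @param cm a [count_matrix()] with stratum labels.
#' @param comparison list with `id`, `target`, `reference` (condition
#'   labels). Reported `log2fc` is target over reference.
#' @param mode `"stratified"` or `"pooled"`.
#' @param fdr_scope `"stratum"` (BH within stratum, the default and the
#'   stratified procedure's convention) or `"global"`.
#' @param alpha_floor dispersion floor passed to [estimate_dispersion()].
#' @return data.frame with region columns, `base_mean`, `log2fc`, `se`,
#'   `wald_z`, `pvalue`, `fdr`, `comparison`; attribute `orientation`
#'   states the fold-change direction.
#' @export
stratified_differential <- function(cm, comparison,
                                    mode = c("stratified", "pooled"),
                                    fdr_scope = c("stratum", "global"),
                                    alpha_floor = 1e-4) {
  mode <- match.arg(mode)
  fdr_scope <- match.arg(fdr_scope)
  jA <- which(cm$samples$condition == comparison$reference)
  jB <- which(cm$samples$condition == comparison$target)
  if (length(jA) == 0 || length(jB) == 0)
    stop("comparison conditions not present in sample sheet")
  use <- c(jA, jB)
  run_block <- function(region_idx) {
    mat <- cm$counts[region_idx, use, drop = FALSE]
    sf <- median_ratio_sf(mat)
    groups <- list(seq_along(jA), length(jA) + seq_along(jB))
    disp <- estimate_dispersion(mat, sf, groups, alpha_floor = alpha_floor)
    res <- nb_wald_test(mat, sf, disp$final, groups[[1]], groups[[2]])
    cbind(cm$regions[region_idx, , drop = FALSE], res)
  }
  if (mode == "pooled") {
    out <- run_block(seq_len(nrow(cm$regions)))
    out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  } else {
    blocks <- lapply(split(seq_len(nrow(cm$regions)), cm$regions$stratum),
                     run_block)
    if (fdr_scope == "stratum") {
      blocks <- lapply(blocks, function(b) {
        b$fdr <- stats::p.adjust(b$pvalue, method = "BH"); b
      })
      out <- do.call(rbind, blocks)
    } else {
      out <- do.call(rbind, blocks)
      out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
    }
    out <- out[order(out$chrom, out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out$comparison <- comparison$id
  attr(out, "orientation") <-
    paste0("log2fc = ", comparison$target, " / ", comparison$reference)
  out
}

#' Manhattan-style table of a differential result
#'
#' One row per region with a cumulative genome coordinate, ready for
#' plotting; regions above the FDR threshold are labelled `ns`.
#'
#' @param da result of [stratified_differential()].
#' @param genome a [genome_spec()] (defines chromosome order and offsets).
#' @param fdr_threshold significance threshold for the bias label.
#' @return data.frame `chrom`, `position`, `genome_position`, `log2fc`,
#'   `fdr`, `bias` (`target_up` / `target_down` / `ns`).
#' @export
manhattan_table <- function(da, genome, fdr_threshold = 0.05) {
  offs <- stats::setNames(cumsum(c(0, genome$length[-nrow(genome)])),
                          genome$chrom)
  mid <- floor((da$start + da$end) / 2)
  data.frame(chrom = da$chrom, position = mid,
             genome_position = mid + offs[da$chrom],
             log2fc = da$log2fc, fdr = da$fdr,
             bias = ifelse(da$fdr < fdr_threshold,
                           ifelse(da$log2fc > 0, "target_up", "target_down"),
                           "ns"),
             stringsAsFactors = FALSE, row.names = NULL)
}
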