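#' Fragment coverage track
#'
#' Midpoint mode adds one event at `floor((start + end) / 2)` of each
#' fragment; span mode increments every covered bp. Midpoint mode is the
#' counting mode used for peak calling; span mode is for signal display.
#'
#' @param fragments interval data.frame (see [read_intervals()]).
#' @param genome a [genome_spec()]; fragments on unknown chromosomes are an
#'   error.
#' @param mode `"midpoint"` or `"span"`.
#' @return A `coverage_track`: list with `cov` (named list of per-bp integer
#'   vectors), `total_events`, `mode`.
#' @export
compute_coverage <- function(fragments, genome, mode = c("midpoint", "span")) {
  mode <- match.arg(mode)
  chrom_stratum(fragments$chrom, genome)  # validates chromosomes
  if (any(fragments$end > genome$length[match(fragments$chrom, genome$chrom)]))
    stop("fragment beyond chromosome end")
  cov <- vector("list", nrow(genome))
  names(cov) <- genome$chrom
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    sel <- fragments$chrom == genome$chrom[i]
    if (mode == "midpoint") {
      mid <- floor((fragments$start[sel] + fragments$end[sel]) / 2)
      cov[[i]] <- tabulate(mid + 1L, nbins = L)
    } else {
      ir <- IRanges::IRanges(start = fragments$start[sel] + 1,
                             end = fragments$end[sel])
      v <- as.integer(IRanges::coverage(ir, width = L))
      cov[[i]] <- v
    }
  }
  total <- if (mode == "midpoint") sum(vapply(cov, sum, 0)) else
    nrow(fragments)
  structure(list(cov = cov, total_events = total, mode = mode),
            class = "coverage_track")
}

# upper-tail Poisson probability P(X >= k; lambda)
poisson_upper_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Call peaks by sliding-window Poisson test against a local background
#'
#' Each window of `window` bp (advanced by `step`) is tested against a
#' Poisson expectation `lambda = window * max(genome-wide rate, local rates)`
#' where local rates are measured over each of `local_scales` bp centred on
#' the window. P-values are adjusted by Benjamini-Hochberg over all windows
#' genome-wide; significant windows (q below `q_threshold`) that overlap or
#' are adjacent are merged, the merged peak inheriting the minimum p/q and
#' the leftmost coverage-maximum bp as summit.
#'
#' @param track a `coverage_track` from [compute_coverage()].
#' @param window window width, bp.
#' @param step window step, bp (`window >= step >= 1`).
#' @param local_scales local background scales, bp.
#' @param q_threshold FDR threshold for retaining windows (default 0.001).
#' @return data.frame of peak calls: `chrom`, `start`, `end`, `name`,
#'   `summit`, `max_count`, `pvalue`, `qvalue`, `score` (-log10 q).
#' @export
call_peaks <- function(track, window = 200L, step = 50L,
                       local_scales = c(5000L, 10000L), q_threshold = 0.001) {
  if (!(window >= step && step >= 1)) stop("need window >= step >= 1")
  lens <- lengths(track$cov)
  genome_rate <- track$total_events / sum(lens)
  win <- list()
  for (chr in names(track$cov)) {
    L <- lens[[chr]]
    if (window > L) {
      warning("window larger than chromosome ", chr, "; skipped")
      next
    }
    cov <- track$cov[[chr]]
    cs <- cumsum(c(0, cov))
    starts <- seq(0L, L - window, by = step)
    k <- cs[starts + window + 1] - cs[starts + 1]
    centre <- starts + window / 2
    rate <- rep(genome_rate, length(starts))
    for (S in local_scales) {
      lo <- pmax(0, floor(centre - S / 2))
      hi <- pmin(L, ceiling(centre + S / 2))
      rate <- pmax(rate, (cs[hi + 1] - cs[lo + 1]) / (hi - lo))
    }
    win[[chr]] <- data.frame(chrom = chr, start = starts,
                             end = starts + window, k = k,
                             lambda = window * rate)
  }
  if (length(win) == 0) return(empty_peak_frame())
  w <- do.call(rbind, win)
  rownames(w) <- NULL
  w$pvalue <- poisson_upper_tail(w$k, w$lambda)
  w$qvalue <- stats::p.adjust(w$pvalue, method = "BH")
  sig <- w[w$qvalue < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty_peak_frame())
  peaks <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(s$start[-1] > cummax(s$end[-nrow(s)]))))
    cov <- track$cov[[chr]]
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      ps <- min(m$start); pe <- max(m$end)
      seg <- cov[(ps + 1):pe]
      summit <- ps + which.max(seg) - 1L  # leftmost max
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = chr, start = ps, end = pe, summit = summit,
        max_count = max(seg), pvalue = min(m$pvalue),
        qvalue = min(m$qvalue), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("peakcall_%05d", seq_len(nrow(out)))
  out$score <- -log10(pmax(out$qvalue, 1e-300))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "summit", "max_count",
          "pvalue", "qvalue", "score")]
}

empty_peak_frame <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), summit = numeric(0),
             max_count = numeric(0), pvalue = numeric(0),
             qvalue = numeric(0), score = numeric(0))
}
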