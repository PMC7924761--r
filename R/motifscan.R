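#' Exact null distribution of a PWM log-odds score
#'
#' Pseudocounted probabilities `p' = (p + pc * bg) / (1 + pc)` give
#' per-column log-odds `log2(p'/bg)`, rounded to multiples of `epsilon`
#' bits. The distribution of the total score of one width-w alignment of
#' i.i.d. background bases is computed exactly by column-wise convolution
#' on the integer grid; tail probabilities `P(score >= s)` follow by
#' suffix summation. Scanning uses the same grid, so looked-up p-values
#' are exact for the discretized score.
#'
#' @param pwm a [pwm()].
#' @param epsilon score grid resolution in bits (default 0.01).
#' @return A `score_distribution`: `motif_id`, `epsilon`, `lods_int`
#'   (4 x width integer log-odds), `grid_min`, `pmf`, `tail`.
#' @export
score_distribution <- function(pwm, epsilon = 0.01) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  bg <- pwm$background
  pc <- pwm$pseudocount
  pp <- sweep(pwm$probs, 1, pc * bg, "+") / (1 + pc)
  lods <- log2(sweep(pp, 1, bg, "/"))
  li <- matrix(as.integer(round(lods / epsilon)), nrow = 4,
               dimnames = dimnames(lods))
  pmf <- 1; gmin <- 0L
  for (k in seq_len(ncol(li))) {
    lo <- min(li[, k]); hi <- max(li[, k])
    new <- numeric(length(pmf) + hi - lo)
    for (b in 1:4) {
      off <- li[b, k] - lo
      idx <- seq_along(pmf) + off
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new
    gmin <- gmin + lo
  }
  tail <- rev(cumsum(rev(pmf)))
  structure(list(motif_id = pwm$motif_id, epsilon = epsilon, lods_int = li,
                 grid_min = gmin, pmf = pmf, tail = tail),
            class = "score_distribution")
}

# P(score >= s) for an integer grid score
tail_p <- function(dist, int_score) {
  i <- int_score - dist$grid_min + 1
  n <- length(dist$tail)
  ifelse(i <= 1, 1, ifelse(i > n, 0, dist$tail[pmax(pmin(i, n), 1)]))
}

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Best motif match in one sequence (both strands, exact p-value)
#'
#' Scores every width-w alignment on both strands with the integer-grid
#' log-odds of `dist` and returns the maximum; its p-value is the exact
#' tail probability of that score for a single alignment (no correction
#' for sequence length, matching best-hit-minimum scanning practice). Ties
#' resolve to the smallest position, then the + strand. Non-ACGT
#' characters contribute 0 log-odds and set `flagged`; sequences shorter
#' than the motif return p = 1, flagged.
#'
#' @param sequence character or `DNAString`.
#' @param dist a [score_distribution()].
#' @return one-row data.frame: `score_bits`, `pvalue`, `position`
#'   (0-based), `strand`, `flagged`, `length`.
#' @export
scan_best_hit <- function(sequence, dist) {
  s <- toupper(as.character(sequence))
  code <- BASE_CODE[strsplit(s, "")[[1]]]
  code[is.na(code)] <- 5L
  L <- length(code)
  ambiguous <- sum(code == 5L)
  if (L > 0 && ambiguous / L > 0.5)
    stop("sequence with > 50% ambiguous bases")
  w <- ncol(dist$lods_int)
  if (L < w)
    return(data.frame(score_bits = NA_real_, pvalue = 1,
                      position = NA_integer_, strand = NA_character_,
                      flagged = TRUE, length = L))
  M <- rbind(dist$lods_int, 0L)              # row 5: ambiguous base
  Mrc <- M[c(4L, 3L, 2L, 1L, 5L), w:1, drop = FALSE]
  np <- L - w + 1
  sp <- integer(np); sm <- integer(np)
  for (k in seq_len(w)) {
    ck <- code[k:(k + np - 1)]
    sp <- sp + M[ck + (k - 1L) * 5L]
    sm <- sm + Mrc[ck + (k - 1L) * 5L]
  }
  best <- max(sp, sm)
  pos_plus <- which(sp == best)
  pos_minus <- which(sm == best)
  first_plus <- if (length(pos_plus)) pos_plus[1] else Inf
  first_minus <- if (length(pos_minus)) pos_minus[1] else Inf
  if (first_plus <= first_minus) {
    position <- first_plus; strand <- "+"
  } else {
    position <- first_minus; strand <- "-"
  }
  data.frame(score_bits = best * dist$epsilon, pvalue = tail_p(dist, best),
             position = as.integer(position - 1), strand = strand,
             flagged = ambiguous > 0, length = L)
}

#' Empirical 0-order base composition of a sequence set
#' @param seqs `DNAStringSet` or character vector.
#' @return length-4 probability vector (A, C, G, T).
#' @export
empirical_background <- function(seqs) {
  s <- paste(toupper(as.character(seqs)), collapse = "")
  code <- BASE_CODE[strsplit(s, "")[[1]]]
  tab <- tabulate(code[!is.na(code)], nbins = 4)
  tab / sum(tab)
}

#' Scan a sequence set for the best hit per region
#'
#' Region id and an optional `class=` key are parsed from the sequence
#' names. The background model defaults to the scan set's empirical base
#' composition (configurable to uniform or the PWM's own background).
#'
#' @param seqs named `DNAStringSet` or character vector; names like
#'   `"peak_00001 class=FruM_closed"`.
#' @param motif a [pwm()].
#' @param background `"empirical"`, `"uniform"`, or `"pwm"`.
#' @param epsilon score grid resolution (bits).
#' @return data.frame: `region_id`, `class`, then the [scan_best_hit()]
#'   columns; attribute `distribution` carries the score distribution.
#' @export
motif_scan_set <- function(seqs, motif,
                           background = c("empirical", "uniform", "pwm"),
                           epsilon = 0.01) {
  background <- match.arg(background)
  bg <- switch(background,
               empirical = empirical_background(seqs),
               uniform = rep(0.25, 4),
               pwm = motif$background)
  m <- pwm(motif$motif_id, motif$probs, background = bg,
           pseudocount = motif$pseudocount)
  dist <- score_distribution(m, epsilon = epsilon)
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("seq_%05d", seq_along(seqs))
  region_id <- sub(" .*", "", nm)
  class <- ifelse(grepl("class=", nm),
                  sub(".*class=([^ ]+).*", "\\1", nm), NA_character_)
  rows <- lapply(seq_along(seqs), function(i)
    scan_best_hit(as.character(seqs[[i]]), dist))
  out <- cbind(data.frame(region_id = region_id, class = class,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  attr(out, "distribution") <- dist
  out
}

#' Compare best-hit motif strength across peak classes
#'
#' For each class, the cumulative distribution of best-hit p-values (on a
#' -log10 scale); for each class pair, a two-sample Kolmogorov-Smirnov test
#' and a Fisher exact test on the 2 x 2 table of regions with a
#' well-matched motif (best p below `threshold`) versus not. Class length
#' distributions are summarized alongside, since best-hit p-values are not
#' length-corrected.
#'
#' @param hits data.frame from [motif_scan_set()] (needs `class`,
#'   `pvalue`, `length`).
#' @param threshold well-matched-motif p-value threshold (default 1e-3).
#' @return list: `ecdf` (class, neglog10_p, cumfreq), `pairs` (KS and
#'   Fisher statistics per class pair), `classes` (n, n_below, mean
#'   length).
#' @export
class_comparison <- function(hits, threshold = 1e-3) {
  cls <- unique(hits$class)
  if (length(cls) < 2) stop("need >= 2 classes")
  by_class <- split(-log10(hits$pvalue), hits$class)
  if (any(lengths(by_class) == 0)) stop("empty class")
  ecdf_tab <- do.call(rbind, lapply(names(by_class), function(cl) {
    x <- sort(by_class[[cl]])
    data.frame(class = cl, neglog10_p = x,
               cumfreq = seq_along(x) / length(x),
               stringsAsFactors = FALSE)
  }))
  below <- vapply(split(hits$pvalue < threshold, hits$class), sum, 0)
  sizes <- vapply(split(hits$pvalue, hits$class), length, 0)
  pr <- utils::combn(names(by_class), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(pr)), function(i) {
    a <- pr[1, i]; b <- pr[2, i]
    ks <- suppressWarnings(stats::ks.test(by_class[[a]], by_class[[b]]))
    tab <- matrix(c(below[a], sizes[a] - below[a],
                    below[b], sizes[b] - below[b]), 2, byrow = TRUE)
    fi <- stats::fisher.test(tab)
    data.frame(class_a = a, class_b = b, ks_D = unname(ks$statistic),
               ks_p = ks$p.value, fisher_odds = unname(fi$estimate),
               fisher_p = fi$p.value, n_a = sizes[a], n_b = sizes[b],
               below_a = below[a], below_b = below[b],
               stringsAsFactors = FALSE)
  }))
  lens <- split(hits$length, hits$class)
  classes <- data.frame(class = names(by_class),
                        n = as.integer(sizes[names(by_class)]),
                        n_below = as.integer(below[names(by_class)]),
                        mean_length = vapply(lens[names(by_class)], mean, 0),
                        stringsAsFactors = FALSE)
  list(ecdf = ecdf_tab, pairs = pairs, classes = classes)
}

#' A synthetic 8-bp test motif
#'
#' Deterministic position weight matrix with consensus `ATGCAAAT`
#' (0.85 consensus base per column, 0.05 others), used by the bundled
#' simulations and examples.
#'
#' @param pseudocount pseudocount weight (default 0.1).
#' @return A [pwm()].
#' @export
fru_like_motif <- function(pseudocount = 0.1) {
  cons <- strsplit("ATGCAAAT", "")[[1]]
  probs <- vapply(cons, function(b) {
    p <- rep(0.05, 4); names(p) <- c("A", "C", "G", "T")
    p[b] <- 0.85
    p
  }, numeric(4))
  pwm("fru_like", probs, pseudocount = pseudocount)
}
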