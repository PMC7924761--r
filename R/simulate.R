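#' Simulation configuration for the synthetic ATAC experiment
#'
#' Encodes the statistical structure of the study design: 4 conditions
#' (male/female x fru+/fru-) with `replicates` libraries each, a haploid-male
#' / diploid-female X chromosome, dosage-compensation (DCC) sites boosted on
#' the male X, peaks opened or closed only in male fru+ cells, per-peak cell
#' fractions modelling the proportion of profiled cells using each element,
#' and a bimodal (sub-nucleosomal / mono-nucleosomal) fragment-length mixture.
#'
#' @param seed integer seed; all outputs are byte-identical under the same
#'   seed.
#' @param genome a [genome_spec()]; default [default_genome()].
#' @param n_peaks_per_chrom accessible regions placed per chromosome.
#' @param peak_width width of each planted peak in bp.
#' @param baseline_mu expected fragments per peak per replicate before
#'   dosage/effect/cell-fraction factors.
#' @param alpha negative-binomial dispersion (variance = mu + alpha mu^2);
#'   0 gives Poisson counts.
#' @param replicates replicates per condition.
#' @param frac_dcc_sites_on_X fraction of X peaks that are DCC sites.
#' @param dcc_boost multiplicative accessibility boost at DCC sites in male
#'   samples (>= 1).
#' @param n_open_planted,n_closed_planted autosomal peaks opened/closed only
#'   in male fru+ samples.
#' @param delta absolute planted log2 fold change for opened/closed peaks
#'   (> 0).
#' @param cell_fraction_range range (low, high) in (0, 1] for the per-peak
#'   cell fraction, drawn uniformly and applied to all samples alike.
#' @param background_rate genome-wide background fragments per bp per sample.
#' @param fragment_length_mix list with `weights`, `mean`, `sd` (each length
#'   2) for the sub-nucleosomal and mono-nucleosomal length components.
#' @param motif_plant_prob named probabilities of planting a motif instance,
#'   by peak class (`unchanged`, `FruM_open`, `FruM_closed`, `DCC`).
#' @param gc_content GC fraction of simulated background sequence.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome = default_genome(),
                       n_peaks_per_chrom = 300L,
                       peak_width = 400L,
                       baseline_mu = 50,
                       alpha = 0.05,
                       replicates = 2L,
                       frac_dcc_sites_on_X = 0.1,
                       dcc_boost = 2,
                       n_open_planted = 40L,
                       n_closed_planted = 30L,
                       delta = 2,
                       cell_fraction_range = c(0.3, 1),
                       background_rate = 1e-3,
                       fragment_length_mix = list(weights = c(0.6, 0.4),
                                                  mean = c(75, 200),
                                                  sd = c(25, 40)),
                       motif_plant_prob = c(unchanged = 0.1, FruM_open = 0.1,
                                            FruM_closed = 0.8, DCC = 0.1),
                       gc_content = 0.43) {
  stopifnot(delta > 0, dcc_boost >= 1, alpha >= 0,
            all(cell_fraction_range > 0), all(cell_fraction_range <= 1),
            frac_dcc_sites_on_X >= 0, frac_dcc_sites_on_X <= 1,
            all(motif_plant_prob >= 0), all(motif_plant_prob <= 1),
            gc_content >= 0, gc_content <= 1)
  structure(list(seed = as.integer(seed), genome = genome,
                 n_peaks_per_chrom = n_peaks_per_chrom,
                 peak_width = peak_width, baseline_mu = baseline_mu,
                 alpha = alpha, replicates = as.integer(replicates),
                 frac_dcc_sites_on_X = frac_dcc_sites_on_X,
                 dcc_boost = dcc_boost,
                 n_open_planted = as.integer(n_open_planted),
                 n_closed_planted = as.integer(n_closed_planted),
                 delta = delta, cell_fraction_range = cell_fraction_range,
                 background_rate = background_rate,
                 fragment_length_mix = fragment_length_mix,
                 motif_plant_prob = motif_plant_prob,
                 gc_content = gc_content),
            class = "sim_config")
}

#' Fixed configuration for the X-dosage normalization demonstration
#'
#' Deep, tightly replicated libraries (expected 500 fragments per peak,
#' dispersion 0.02, cell fraction 1) with female 2x X dosage, a
#' dosage-compensation boost of 2 at 10% of X peaks, and no planted Fru-M
#' effects. Dosage compensation acts chromosome-wide and cell-autonomously,
#' so the per-element cell-fraction heterogeneity is switched off here; the
#' depth reflects that the demonstration concerns normalization behaviour,
#' not detection power at marginal coverage.
#'
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
bias_demo_config <- function(seed = 1L) {
  sim_config(seed = seed, baseline_mu = 500, alpha = 0.02,
             cell_fraction_range = c(1, 1), n_open_planted = 0L,
             n_closed_planted = 0L, dcc_boost = 2, frac_dcc_sites_on_X = 0.1)
}

# stable per-stage child seed (< 2^31) derived from the global seed
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' The four study conditions
#' @return character vector of condition labels.
#' @export
study_conditions <- function() {
  c("male_fru+", "male_fru-", "female_fru+", "female_fru-")
}

sample_sheet <- function(replicates) {
  cond <- study_conditions()
  df <- expand.grid(replicate = seq_len(replicates), condition = cond,
                    stringsAsFactors = FALSE)
  df$sex <- sub("_.*", "", df$condition)
  df$fru <- ifelse(grepl("\\+$", df$condition), "fru+", "fru-")
  df$sample_id <- paste0(df$condition, "_rep", df$replicate)
  df[, c("sample_id", "condition", "sex", "fru", "replicate")]
}

#' Construct a count matrix container
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `name`, `stratum`;
#'   must be unique and is sorted by (chrom, start).
#' @param samples data.frame with at least `sample_id` and `condition`.
#' @param counts non-negative integer matrix, regions x samples.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(regions, samples, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(regions) || ncol(counts) != nrow(samples))
    stop("counts dimensions must match regions x samples")
  if (any(counts < 0)) stop("negative counts")
  key <- paste(regions$chrom, regions$start, regions$end)
  if (anyDuplicated(key)) stop("duplicate regions")
  o <- order(regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  counts <- counts[o, , drop = FALSE]
  rownames(regions) <- NULL
  rownames(counts) <- regions$name
  colnames(counts) <- samples$sample_id
  structure(list(regions = regions, samples = samples, counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$regions), "regions x", nrow(x$samples),
      "samples\n")
  invisible(x)
}

# non-overlapping peak placement with a safety margin at chromosome ends
place_peaks <- function(genome, n_per_chrom, width, margin = 2000) {
  out <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    cand <- seq(margin, L - margin - width, by = 2 * width)
    if (length(cand) < n_per_chrom)
      stop("chromosome ", genome$chrom[i], " too short for ",
           n_per_chrom, " peaks")
    s <- sort(sample(cand, n_per_chrom))
    data.frame(chrom = genome$chrom[i], start = s, end = s + width,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$name <- sprintf("peak_%05d", seq_len(nrow(df)))
  df$stratum <- chrom_stratum(df$chrom, genome)
  df
}

#' Simulate the peak-by-sample fragment count matrix with planted truth
#'
#' The expected count of peak i in sample j is
#' `mu_ij = s_j * f_i * mu_base * x_ij * d_ij * g_ij` where `x_ij = 2` for
#' female samples at X peaks (two X chromosomes) else 1, `d_ij = dcc_boost`
#' for male samples at DCC peaks else 1, and `g_ij = 2^(+/-delta)` only for
#' male fru+ samples at FruM_open / FruM_closed peaks. `f_i` is the per-peak
#' cell fraction and `s_j` a log-uniform library size factor in (0.7, 1.4).
#' Counts are negative binomial with dispersion `alpha`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]), `truth` (per-peak
#'   data.frame recording class, factors and true per-comparison log2 fold
#'   changes), `tether_sites` (DCC peak midpoints as width-1 intervals), and
#'   `mu` (the expected-count matrix).
#' @export
simulate_counts <- function(config) {
  set.seed(child_seed(config$seed, "counts"))
  genome <- config$genome
  peaks <- place_peaks(genome, config$n_peaks_per_chrom, config$peak_width)
  n <- nrow(peaks)
  samples <- sample_sheet(config$replicates)
  m <- nrow(samples)

  is_x <- peaks$stratum == "X"
  n_dcc <- round(sum(is_x) * config$frac_dcc_sites_on_X)
  class <- rep("unchanged", n)
  if (n_dcc > 0) class[sample(which(is_x), n_dcc)] <- "DCC"
  auto_idx <- which(!is_x)
  n_planted <- config$n_open_planted + config$n_closed_planted
  if (n_planted > length(auto_idx))
    stop("planted peak counts exceed available autosomal peaks")
  if (n_planted > 0) {
    pl <- sample(auto_idx, n_planted)
    class[pl[seq_len(config$n_open_planted)]] <- "FruM_open"
    if (config$n_closed_planted > 0)
      class[pl[config$n_open_planted + seq_len(config$n_closed_planted)]] <-
        "FruM_closed"
  }

  f <- stats::runif(n, config$cell_fraction_range[1],
                    config$cell_fraction_range[2])
  s <- exp(stats::runif(m, log(0.7), log(1.4)))

  x_fac <- outer(is_x, samples$sex == "female", function(a, b)
    ifelse(a & b, 2, 1))
  d_fac <- outer(class == "DCC", samples$sex == "male", function(a, b)
    ifelse(a & b, config$dcc_boost, 1))
  g <- matrix(1, n, m)
  mfp <- samples$sex == "male" & samples$fru == "fru+"
  g[class == "FruM_open", mfp] <- 2^config$delta
  g[class == "FruM_closed", mfp] <- 2^(-config$delta)
  mu <- config$baseline_mu * (f %o% s) * x_fac * d_fac * g

  counts <- if (config$alpha > 0) {
    matrix(stats::rnbinom(n * m, mu = mu, size = 1 / config$alpha), n, m)
  } else {
    matrix(stats::rpois(n * m, mu), n, m)
  }

  truth <- cbind(peaks,
                 data.frame(class = class, cell_fraction = f,
                            # male fru+ over male fru- (FruM effect)
                            true_lfc_fru = ifelse(class == "FruM_open",
                                                  config$delta,
                                                  ifelse(class == "FruM_closed",
                                                         -config$delta, 0)),
                            # male fru+ over female fru+ within-stratum signal
                            true_lfc_sex = ifelse(class == "DCC",
                                                  log2(config$dcc_boost), 0) +
                              ifelse(class == "FruM_open", config$delta,
                                     ifelse(class == "FruM_closed",
                                            -config$delta, 0)),
                            motif_planted = FALSE,
                            motif_pos = NA_integer_,
                            motif_strand = NA_character_,
                            stringsAsFactors = FALSE))
  mid <- floor((peaks$start + peaks$end) / 2)
  dcc <- class == "DCC"
  tether <- make_intervals(peaks$chrom[dcc], mid[dcc], mid[dcc] + 1,
                           name = paste0("tether_", seq_len(sum(dcc))))
  cm <- count_matrix(peaks, samples, counts)
  # keep truth and mu aligned to the sorted count-matrix region order
  o <- match(cm$regions$name, truth$name)
  truth <- truth[o, , drop = FALSE]
  rownames(truth) <- NULL
  mu <- mu[o, , drop = FALSE]
  list(counts = cm, truth = truth, tether_sites = tether, mu = mu)
}

# bimodal fragment-length draw, truncated at >= 20 bp
draw_lengths <- function(n, mix) {
  comp <- sample.int(2, n, replace = TRUE, prob = mix$weights)
  len <- round(stats::rnorm(n, mix$mean[comp], mix$sd[comp]))
  pmax(len, 20L)
}

#' Emit per-sample fragment intervals realizing a simulated count matrix
#'
#' For each peak x sample the matrix's count of fragments is emitted with
#' midpoints uniform within the peak, plus Poisson background fragments
#' genome-wide at `background_rate` per bp. Fragment lengths follow the
#' configured bimodal mixture; fragments are clipped to chromosome bounds.
#' The `name` column flags origin (`peak_id` or `background`).
#'
#' @param config the [sim_config()] used for [simulate_counts()].
#' @param sim result of [simulate_counts()].
#' @return named list (one per sample) of interval data.frames.
#' @export
simulate_fragments <- function(config, sim) {
  set.seed(child_seed(config$seed, "fragments"))
  cm <- sim$counts
  genome <- config$genome
  chrlen <- stats::setNames(genome$length, genome$chrom)
  tot_len <- sum(genome$length)
  out <- vector("list", nrow(cm$samples))
  names(out) <- cm$samples$sample_id
  for (j in seq_len(nrow(cm$samples))) {
    cnt <- cm$counts[, j]
    idx <- rep.int(seq_along(cnt), cnt)
    npk <- length(idx)
    mid <- cm$regions$start[idx] +
      floor(stats::runif(npk) * (cm$regions$end[idx] - cm$regions$start[idx]))
    chrom <- cm$regions$chrom[idx]
    name <- cm$regions$name[idx]
    nbg <- stats::rpois(1, config$background_rate * tot_len)
    if (nbg > 0) {
      pos <- floor(stats::runif(nbg) * tot_len)
      cb <- cumsum(c(0, genome$length))
      ci <- findInterval(pos, cb, rightmost.closed = FALSE)
      chrom <- c(chrom, genome$chrom[ci])
      mid <- c(mid, pos - cb[ci])
      name <- c(name, rep("background", nbg))
    }
    len <- draw_lengths(length(mid), config$fragment_length_mix)
    fs <- mid - floor(len / 2)
    fe <- fs + len
    fs <- pmax(fs, 0)
    fe <- pmin(fe, chrlen[chrom])
    keep <- fs < fe
    out[[j]] <- make_intervals(chrom[keep], fs[keep], fe[keep],
                               name = name[keep])
  }
  out
}

# consensus sequence of a PWM: column-wise argmax, ties to the
# alphabetically first base (A < C < G < T, the row order)
pwm_consensus <- function(p) {
  paste(rownames(p$probs)[apply(p$probs, 2, which.max)], collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate peak sequences with class-dependent motif planting
#'
#' Background bases are i.i.d. at the configured GC content; with
#' probability `motif_plant_prob[class]` one consensus instance of the motif
#' (or its reverse complement, strand uniform) is embedded at a uniform
#' position. Planted positions and strands are recorded in the returned
#' truth table.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_counts()] (its truth table is updated).
#' @param motif a [pwm()].
#' @return list with `sequences` (named `DNAStringSet`; names carry a
#'   `class=` key) and `truth` (updated per-peak table).
#' @export
simulate_sequences <- function(config, sim, motif) {
  set.seed(child_seed(config$seed, "sequences"))
  truth <- sim$truth
  gc <- config$gc_content
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cons <- pwm_consensus(motif)
  w <- motif$width
  seqs <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    L <- truth$end[i] - truth$start[i]
    s <- paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
               collapse = "")
    prob <- config$motif_plant_prob[[truth$class[i]]]
    if (is.null(prob)) prob <- 0
    if (stats::runif(1) < prob) {
      if (L < w) {
        warning("peak ", truth$name[i], " shorter than motif; not planted")
      } else {
        pos <- sample.int(L - w + 1, 1) - 1L  # 0-based offset
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") cons else revcomp(cons)
        substr(s, pos + 1, pos + w) <- ins
        truth$motif_planted[i] <- TRUE
        truth$motif_pos[i] <- pos
        truth$motif_strand[i] <- strand
      }
    }
    seqs[i] <- s
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- paste0(truth$name, " class=", truth$class)
  list(sequences = ss, truth = truth)
}

#' Simulate gene-level RNA counts with optional sex or fru bias
#'
#' Negative-binomial gene counts over the four study conditions. Baseline
#' means are log-normal; named entries of `sex_lfc` (male over female) and
#' `fru_lfc` (fru+ over fru-) plant expression biases split symmetrically
#' between the two groups.
#'
#' @param gene_ids character gene identifiers.
#' @param mu_base median baseline expected count.
#' @param replicates replicates per condition.
#' @param sex_lfc,fru_lfc named numeric vectors of planted log2 fold changes
#'   (names must be gene ids).
#' @param alpha negative-binomial dispersion.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()] with genes as regions,
#'   stratum `"autosome"`) and `mu` (expected counts).
#' @export
simulate_gene_counts <- function(gene_ids, mu_base = 100, replicates = 2L,
                                 sex_lfc = numeric(), fru_lfc = numeric(),
                                 alpha = 0.05, seed = 1L) {
  set.seed(child_seed(seed, "gene_counts"))
  n <- length(gene_ids)
  samples <- sample_sheet(replicates)
  base <- mu_base * exp(stats::rnorm(n, 0, 0.5))
  b_sex <- b_fru <- numeric(n)
  b_sex[match(names(sex_lfc), gene_ids)] <- sex_lfc
  b_fru[match(names(fru_lfc), gene_ids)] <- fru_lfc
  mu <- outer(seq_len(n), seq_len(nrow(samples)), function(i, j) {
    sx <- ifelse(samples$sex[j] == "male", 1, -1)
    fr <- ifelse(samples$fru[j] == "fru+", 1, -1)
    base[i] * 2^(sx * b_sex[i] / 2) * 2^(fr * b_fru[i] / 2)
  })
  counts <- if (alpha > 0) {
    matrix(stats::rnbinom(n * nrow(samples), mu = mu, size = 1 / alpha),
           n, nrow(samples))
  } else {
    matrix(stats::rpois(n * nrow(samples), mu), n, nrow(samples))
  }
  regions <- data.frame(chrom = "genes", start = seq_len(n) * 10 - 10,
                        end = seq_len(n) * 10, name = gene_ids,
                        stratum = "autosome", stringsAsFactors = FALSE)
  list(counts = count_matrix(regions, samples, counts), mu = mu)
}

#' Simulate a long multi-intron gene with fru+-only enhancer peaks
#'
#' Builds a single-chromosome fragment set for the four study conditions in
#' which intronic enhancer peaks within a long gene carry fragments only in
#' fru+ samples, on top of uniform background. Used to exercise gene-scale
#' counting and windowed fold-change displays.
#'
#' @param gene_length gene span in bp.
#' @param n_enhancers intronic enhancer peaks active only in fru+ samples.
#' @param enhancer_mu expected fragments per enhancer per fru+ sample.
#' @param flanking_mu expected fragments at each of the constitutive
#'   flanking control peaks (all samples).
#' @param background_rate background fragments per bp per sample.
#' @param replicates replicates per condition.
#' @param seed integer seed.
#' @return list with `genome` (one 200-kb autosome), `gene` (a
#'   `gene_models` object), `fragments` (per-sample interval list),
#'   `enhancers` (interval data.frame), `samples`.
#' @export
simulate_fru_locus <- function(gene_length = 100000, n_enhancers = 4,
                               enhancer_mu = 80, flanking_mu = 80,
                               background_rate = 2e-3, replicates = 2L,
                               seed = 1L) {
  set.seed(child_seed(seed, "fru_locus"))
  chrom <- "chr3"; chrlen <- 200000
  genome <- genome_spec(chrom, chrlen, "autosome")
  gene_start <- 50000; gene_end <- gene_start + gene_length
  # short exons; everything between is intron
  n_ex <- 8
  ex_start <- round(seq(gene_start, gene_end - 500, length.out = n_ex))
  exons <- data.frame(gene_id = "fru_like", chrom = chrom, start = ex_start,
                      end = ex_start + 300, strand = "+",
                      stringsAsFactors = FALSE)
  # constitutive control genes outside the locus anchor the normalization
  ctrl_mid <- c(5000, 15000, 25000, 35000, 45000, 160000, 170000, 180000,
                190000)
  ctrl_mid <- ctrl_mid[ctrl_mid + 2000 < gene_start |
                         ctrl_mid - 2000 > gene_end]
  ctrl_ex <- do.call(rbind, lapply(seq_along(ctrl_mid), function(k)
    data.frame(gene_id = sprintf("ctrl_gene_%02d", k), chrom = chrom,
               start = ctrl_mid[k] - 1500, end = ctrl_mid[k] + 1500,
               strand = "+", stringsAsFactors = FALSE)))
  gene <- gene_models_from_exons(rbind(exons, ctrl_ex))
  # enhancers centred inside introns
  enh_mid <- round(seq(gene_start + 8000, gene_end - 8000,
                       length.out = n_enhancers))
  enh <- make_intervals(chrom, enh_mid - 200, enh_mid + 200,
                        name = paste0("enh_", seq_len(n_enhancers)))
  ctrl <- make_intervals(chrom, ctrl_mid - 200, ctrl_mid + 200,
                         name = paste0("ctrl_", seq_along(ctrl_mid)))
  samples <- sample_sheet(replicates)
  frags <- vector("list", nrow(samples))
  names(frags) <- samples$sample_id
  for (j in seq_len(nrow(samples))) {
    mids <- integer(0); who <- character(0)
    emit <- function(iv, mu) {
      k <- stats::rpois(nrow(iv), mu)
      idx <- rep.int(seq_len(nrow(iv)), k)
      list(mid = iv$start[idx] +
             floor(stats::runif(length(idx)) * (iv$end[idx] - iv$start[idx])),
           name = iv$name[idx])
    }
    if (samples$fru[j] == "fru+") {
      e <- emit(enh, enhancer_mu); mids <- c(mids, e$mid); who <- c(who, e$name)
    }
    cc <- emit(ctrl, flanking_mu); mids <- c(mids, cc$mid); who <- c(who, cc$name)
    nbg <- stats::rpois(1, background_rate * chrlen)
    mids <- c(mids, floor(stats::runif(nbg) * chrlen))
    who <- c(who, rep("background", nbg))
    len <- draw_lengths(length(mids), list(weights = c(0.6, 0.4),
                                           mean = c(75, 200), sd = c(25, 40)))
    fs <- pmax(mids - floor(len / 2), 0)
    fe <- pmin(fs + len, chrlen)
    frags[[j]] <- make_intervals(chrom, fs, fe, name = who)
  }
  list(genome = genome, gene = gene, fragments = frags, enhancers = enh,
       controls = ctrl, samples = samples)
}
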