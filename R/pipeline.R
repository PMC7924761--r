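#' Simulate a sparse gene annotation over a genome
#'
#' Places non-overlapping multi-exon genes (random strand) for use by the
#' annotation and expression stages of the bundled synthetic analysis.
#'
#' @param genome a [genome_spec()].
#' @param n_genes_per_chrom genes per chromosome.
#' @param seed integer seed.
#' @return A `gene_models` object.
#' @export
simulate_gene_models <- function(genome, n_genes_per_chrom = 60L,
                                 seed = 1L) {
  set.seed(child_seed(seed, "gene_models"))
  ex <- list()
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    slot <- floor(L / n_genes_per_chrom)
    for (k in seq_len(n_genes_per_chrom)) {
      gid <- sprintf("gene_%s_%03d", sub("^chr", "", genome$chrom[i]), k)
      g0 <- (k - 1) * slot + 500
      glen <- min(sample(2000:15000, 1), slot - 1000)
      n_ex <- sample(1:4, 1)
      # non-overlapping exons spread over the gene span
      bounds <- sort(sample(seq(g0, g0 + glen, by = 200), 2 * n_ex))
      es <- bounds[seq(1, 2 * n_ex, by = 2)]
      ee <- pmax(bounds[seq(2, 2 * n_ex, by = 2)], es + 100)
      ex[[gid]] <- data.frame(gene_id = gid, chrom = genome$chrom[i],
                              start = es, end = ee,
                              strand = sample(c("+", "-"), 1),
                              stringsAsFactors = FALSE)
    }
  }
  gene_models_from_exons(do.call(rbind, ex))
}

#' Pipeline configuration
#'
#' @param seed global seed; per-stage child seeds are derived from it by a
#'   stable hash of the stage name.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param peak_q peak-calling FDR threshold (default 0.001).
#' @param fdr differential accessibility/expression FDR threshold
#'   (default 0.05).
#' @param motif_p well-matched-motif p-value threshold (default 1e-3).
#' @param min_samples consensus support requirement (default 2).
#' @param n_genes_per_chrom genes per chromosome for the synthetic
#'   annotation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, peak_q = 0.001,
                            fdr = 0.05, motif_p = 1e-3, min_samples = 2L,
                            n_genes_per_chrom = 60L) {
  stopifnot(peak_q > 0, peak_q < 1, fdr > 0, fdr < 1,
            motif_p > 0, motif_p < 1)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), sim = sim, peak_q = peak_q,
                 fdr = fdr, motif_p = motif_p,
                 min_samples = as.integer(min_samples),
                 n_genes_per_chrom = n_genes_per_chrom),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # version-independent serialization for a stable hash
  writeBin(serialize(config, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic analysis end to end
#'
#' Stages: simulate counts/fragments/sequences, call peaks per sample,
#' build the consensus, count fragments, run stratified and pooled
#' differential accessibility for the male-fru+ comparisons, classify
#' condition-specific regions, annotate them against a synthetic gene set,
#' compute relative distances of male-biased X regions to the planted
#' tether sites, scan sequences for the bundled motif and compare classes,
#' QC coverage summaries, and the expression arm. All tables are written
#' as TSV under `out_dir`; a manifest (seed, config hash, thresholds,
#' per-stage row counts, wall time) is written last.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  genome <- config$sim$genome
  rows <- list()
  out <- function(name) file.path(out_dir, name)

  # --- simulate -----------------------------------------------------------
  sim <- simulate_counts(config$sim)
  frags <- simulate_fragments(config$sim, sim)
  motif <- fru_like_motif()
  seqres <- simulate_sequences(config$sim, sim, motif)
  sim$truth <- seqres$truth
  write_tsv(sim$truth, out("truth_peaks.tsv"))
  write_intervals(sim$tether_sites, out("tether_sites.bed"))
  utils::write.table(cbind(sim$counts$regions, sim$counts$counts),
                     out("simulated_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (id in names(frags)) write_intervals(frags[[id]],
                                           out(paste0("fragments_", id, ".bed")))
  Biostrings::writeXStringSet(seqres$sequences, out("peak_sequences.fa"))
  rows$simulate <- nrow(sim$truth)

  # --- peak calling -------------------------------------------------------
  peak_sets <- lapply(frags, function(fr)
    call_peaks(compute_coverage(fr, genome, "midpoint"),
               q_threshold = config$peak_q))
  for (id in names(peak_sets))
    write_tsv(peak_sets[[id]], out(paste0("peaks_", id, ".tsv")))
  rows$callpeaks <- sum(vapply(peak_sets, nrow, 0L))

  # --- consensus and counting --------------------------------------------
  consensus <- build_consensus(peak_sets, min_samples = config$min_samples)
  cm <- count_in_regions(frags, consensus, samples = sim$counts$samples,
                         genome = genome)
  write_intervals(consensus, out("consensus.bed"))
  rows$consensus <- nrow(consensus)

  # --- differential accessibility ----------------------------------------
  comparisons <- list(
    fru = list(id = "malefru+_vs_malefru-", target = "male_fru+",
               reference = "male_fru-"),
    sex = list(id = "malefru+_vs_femalefru+", target = "male_fru+",
               reference = "female_fru+"))
  da <- list()
  for (nm in names(comparisons)) {
    da[[nm]] <- stratified_differential(cm, comparisons[[nm]],
                                        mode = "stratified")
    write_tsv(da[[nm]], out(paste0("da_", nm, "_stratified.tsv")))
    pooled <- stratified_differential(cm, comparisons[[nm]], mode = "pooled")
    write_tsv(pooled, out(paste0("da_", nm, "_pooled.tsv")))
  }
  write_tsv(manhattan_table(da$sex, genome, config$fdr),
            out("manhattan_sex.tsv"))
  rows$diff <- nrow(da$fru)

  # --- specificity --------------------------------------------------------
  spec <- intersect_classify(da$fru, da$sex, fdr_threshold = config$fdr)
  write_tsv(spec, out("specificity.tsv"))
  sets <- list(
    fru = da$fru$name[da$fru$fdr < config$fdr],
    sex = da$sex$name[da$sex$fdr < config$fdr])
  write_tsv(upset_counts(sets), out("upset.tsv"))
  rows$specificity <- sum(spec$status %in%
                            c("opened_in_target", "closed_in_target"))

  # --- annotation ---------------------------------------------------------
  genes <- simulate_gene_models(genome, config$n_genes_per_chrom,
                                seed = config$seed)
  ann <- annotate_peaks(consensus, genes)
  write_tsv(ann, out("annotation.tsv"))
  rows$annotate <- nrow(ann)

  # --- relative distance to tether sites ---------------------------------
  male_x <- da$sex[da$sex$stratum == "X" & da$sex$fdr < config$fdr &
                     da$sex$log2fc > 0, , drop = FALSE]
  reldist_rows <- 0
  if (nrow(male_x) >= 1 && nrow(sim$tether_sites) >= 2) {
    rd <- relative_distance(male_x, sim$tether_sites, chroms = "chrX")
    write_tsv(rd$histogram, out("reldist_histogram.tsv"))
    write_tsv(data.frame(mean_d = rd$mean,
                         fraction_overlapping = rd$fraction_overlapping_B,
                         n_used = rd$n_used, n_skipped = rd$n_skipped),
              out("reldist_summary.tsv"))
    reldist_rows <- rd$n_used
  }
  rows$reldist <- reldist_rows

  # --- motif scan ---------------------------------------------------------
  hits <- motif_scan_set(seqres$sequences, motif)
  hits$class <- c(FruM_open = "opened", FruM_closed = "closed",
                  unchanged = "unchanged", DCC = "unchanged")[hits$class]
  write_tsv(hits, out("motif_best_hits.tsv"))
  cc <- class_comparison(hits, threshold = config$motif_p)
  write_tsv(cc$ecdf, out("motif_ecdf.tsv"))
  write_tsv(cc$pairs, out("motif_class_tests.tsv"))
  rows$motif <- nrow(hits)

  # --- coverage QC --------------------------------------------------------
  fracs <- chrom_read_fractions(frags, genome)
  write_tsv(fracs, out("chrom_read_fractions.tsv"))
  corr <- sample_correlation(frags, genome)
  write_tsv(data.frame(sample_id = rownames(corr), corr,
                       check.names = FALSE), out("sample_correlation.tsv"))
  rows$coverage <- nrow(fracs)

  # --- expression arm -----------------------------------------------------
  gid <- genes$genes$gene_id
  set.seed(child_seed(config$seed, "expr_targets"))
  fru_targets <- sample(gid, min(20, length(gid)))
  ge <- simulate_gene_counts(gid, mu_base = 100,
                             replicates = config$sim$replicates,
                             fru_lfc = stats::setNames(rep(2, length(fru_targets)),
                                                       fru_targets),
                             alpha = config$sim$alpha, seed = config$seed)
  lens <- effective_lengths(genes)
  tp <- tpm(ge$counts$counts, lens[gid], samples = ge$counts$samples)
  write_tsv(data.frame(gene_id = rownames(tp$tpm), tp$tpm,
                       check.names = FALSE), out("tpm.tsv"))
  de <- de_genes(ge$counts, list(id = "malefru+_vs_malefru-",
                                 target = "male_fru+",
                                 reference = "male_fru-"))
  write_tsv(de, out("de_fru.tsv"))
  rows$rnaseq <- nrow(de)

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   thresholds = list(peak_q = config$peak_q,
                                     fdr = config$fdr,
                                     motif_p = config$motif_p,
                                     min_samples = config$min_samples),
                   rows = rows,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(list(sim = sim, fragments = frags, peak_sets = peak_sets,
                 consensus = consensus, counts = cm, da = da,
                 specificity = spec, annotation = ann, hits = hits,
                 class_comparison = cc, fractions = fracs, de = de,
                 manifest = manifest))
}
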