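#' Define a genome as ordered chromosomes with stratum labels
#'
#' Every interval-bearing file consumed by the pipeline is validated against a
#' genome specification; stratum labels drive the X-versus-autosome split used
#' by the stratified normalization.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (all > 0).
#' @param stratum character vector, each element `"X"` or `"autosome"`.
#' @return A `genome_spec` data.frame with columns `chrom`, `length`,
#'   `stratum`, rows in the given order.
#' @examples
#' genome_spec(c("chrX", "chr2"), c(2e6, 3e6), c("X", "autosome"))
#' @export
genome_spec <- function(chrom, length, stratum) {
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in genome spec")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (!all(stratum %in% c("X", "autosome")))
    stop("stratum must be 'X' or 'autosome'")
  if (!(base::length(chrom) == base::length(length) &&
        base::length(chrom) == base::length(stratum)))
    stop("chrom, length and stratum must have equal length")
  out <- data.frame(chrom = as.character(chrom),
                    length = as.numeric(length),
                    stratum = as.character(stratum),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_spec", "data.frame")
  out
}

#' Default synthetic genome: chrX 2 Mb, chr2 3 Mb, chr3 3 Mb
#' @return A [genome_spec()] with one X chromosome and two autosomes.
#' @export
default_genome <- function() {
  genome_spec(c("chrX", "chr2", "chr3"), c(2e6, 3e6, 3e6),
              c("X", "autosome", "autosome"))
}

# internal: map chrom -> stratum, erroring on unknown chromosomes
chrom_stratum <- function(chrom, genome) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    bad <- unique(chrom[is.na(i)])
    stop("chromosome(s) not in genome spec: ", paste(bad, collapse = ", "))
  }
  genome$stratum[i]
}

# internal: validated interval data.frame constructor (0-based half-open)
make_intervals <- function(chrom, start, end, name = NA_character_,
                           score = NA_real_, strand = ".") {
  if (length(chrom) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0)
    stop("invalid interval(s) (need 0 <= start < end) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  df
}

#' Read intervals from a BED file
#'
#' Coordinates are kept in BED convention: 0-based, half-open. Empty lines
#' and lines starting with `#`, `track` or `browser` are skipped; the input
#' order is preserved.
#'
#' @param path path to a tab-separated BED file.
#' @param format `"BED3"` or `"BED6"`; BED6 additionally reads name, score
#'   and strand columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (the last three `NA`/`"."` for BED3).
#' @export
read_intervals <- function(path, format = c("BED6", "BED3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  ncol_need <- if (format == "BED3") 3L else 6L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_need))
    stop("line ", lineno[which(nf < ncol_need)[1]], ": expected >= ",
         ncol_need, " tab-separated fields")
  get <- function(k) vapply(fields, `[[`, "", k)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad) > 0)
    stop("line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0)
    stop("line ", lineno[bad[1]], ": invalid interval (start >= end or start < 0)")
  if (format == "BED3") {
    make_intervals(get(1), start, end)
  } else {
    sc <- suppressWarnings(as.numeric(get(5)))
    strand <- get(6)
    if (!all(strand %in% c("+", "-", ".")))
      stop("line ", lineno[which(!strand %in% c("+", "-", "."))[1]],
           ": strand must be +, - or .")
    make_intervals(get(1), start, end, name = get(4), score = sc,
                   strand = strand)
  }
}

#' Write intervals to a BED file
#'
#' @param intervals data.frame as returned by [read_intervals()].
#' @param path output path.
#' @param format `"BED6"` (default) or `"BED3"`.
#' @export
write_intervals <- function(intervals, path, format = c("BED6", "BED3")) {
  format <- match.arg(format)
  df <- intervals
  if (format == "BED3") {
    out <- df[, c("chrom", "start", "end")]
  } else {
    name <- ifelse(is.na(df$name), ".", df$name)
    score <- ifelse(is.na(df$score), 0, df$score)
    strand <- if ("strand" %in% names(df)) df$strand else "."
    out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                      format(df$end, scientific = FALSE, trim = TRUE),
                      name, score, strand)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file (exon features only)
#'
#' Only rows with feature type `exon` are used; each must carry a `gene_id`
#' attribute. GTF 1-based inclusive coordinates are converted to 0-based
#' half-open on read. Exons of a gene are sorted and must not overlap; the
#' TSS is the span start on the + strand and span end - 1 on the - strand.
#'
#' @param path path to a GTF file.
#' @return A `gene_models` object: list with `genes` (data.frame `gene_id`,
#'   `chrom`, `strand`, `tss`, `start`, `end`) and `exons` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`), both 0-based half-open.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) stop("GTF line with fewer than 9 fields")
  feat <- vapply(fields, `[[`, "", 3)
  fields <- fields[feat == "exon"]
  if (length(fields) == 0) stop("no exon features in GTF")
  attrs <- vapply(fields, `[[`, "", 9)
  m <- regmatches(attrs, regexpr('gene_id "[^"]*"', attrs))
  has <- grepl('gene_id "', attrs, fixed = TRUE)
  if (!all(has)) stop("exon without gene_id attribute (row ",
                      which(!has)[1], " of exon rows)")
  gene_id <- sub('gene_id "([^"]*)"', "\\1", m)
  df <- data.frame(
    gene_id = gene_id,
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 4)) - 1,  # to 0-based
    end = as.numeric(vapply(fields, `[[`, "", 5)),        # inclusive -> half-open
    strand = vapply(fields, `[[`, "", 7),
    stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop("exon with strand other than + or -")
  if (any(df$start < 0 | df$start >= df$end)) stop("invalid exon coordinates")
  gene_models_from_exons(df)
}

#' Build gene models from an exon table
#'
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @return A `gene_models` object; see [read_gene_models()].
#' @export
gene_models_from_exons <- function(exons) {
  sp <- split(exons, exons$gene_id)
  genes <- lapply(sp, function(e) {
    if (length(unique(e$strand)) != 1)
      stop("mixed strands within gene ", e$gene_id[1])
    if (length(unique(e$chrom)) != 1)
      stop("exons of gene ", e$gene_id[1], " on multiple chromosomes")
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within gene ", e$gene_id[1])
    span_start <- min(e$start); span_end <- max(e$end)
    tss <- if (e$strand[1] == "+") span_start else span_end - 1
    list(gene = data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                           strand = e$strand[1], tss = tss,
                           start = span_start, end = span_end,
                           stringsAsFactors = FALSE),
         exons = e[, c("gene_id", "chrom", "start", "end")])
  })
  out <- list(genes = do.call(rbind, lapply(genes, `[[`, "gene")),
              exons = do.call(rbind, lapply(genes, `[[`, "exons")))
  rownames(out$genes) <- NULL
  rownames(out$exons) <- NULL
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read position weight matrices from MEME minimal text format
#'
#' Parses the ACGT letter-probability matrices of a MEME minimal motif file.
#' Columns must sum to 1 within 1e-3 and are renormalized exactly after
#' validation. Background frequencies are taken from the file's
#' `Background letter frequencies` line when present, else uniform.
#'
#' @param path path to a MEME minimal format motif file.
#' @param pseudocount pseudocount weight applied when log-odds are formed
#'   (stored on the PWM; see [score_distribution()]). Default 0.1.
#' @return list of `pwm` objects: `motif_id`, `width`, `probs` (4 x width
#'   matrix, rows A,C,G,T), `background` (length-4), `pseudocount`.
#' @export
read_motifs <- function(path, pseudocount = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) == 1 && bgl < length(lines)) {
    toks <- strsplit(trimws(lines[bgl + 1]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      v <- as.numeric(toks[c(2, 4, 6, 8)])
      names(v) <- toks[c(1, 3, 5, 7)]
      bg <- v[c("A", "C", "G", "T")]
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("no MOTIF blocks found in ", path)
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > starts[i]][1]
    if (is.na(hdr)) stop("motif ", id, ": missing letter-probability matrix")
    w <- suppressWarnings(as.integer(
      sub(".*w= *([0-9]+).*", "\\1", lines[hdr])))
    rows <- list(); j <- hdr + 1
    while (j <= length(lines)) {
      tl <- trimws(lines[j])
      if (!nzchar(tl) || grepl("^(MOTIF|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4) break
      rows[[length(rows) + 1]] <- vals
      j <- j + 1
    }
    if (length(rows) == 0) stop("motif ", id, ": empty matrix (width 0)")
    if (!is.na(w) && w != length(rows))
      stop("motif ", id, ": header width ", w, " but ", length(rows),
           " matrix rows")
    probs <- t(do.call(rbind, rows))  # 4 x width, rows A C G T
    rownames(probs) <- c("A", "C", "G", "T")
    sums <- colSums(probs)
    if (any(abs(sums - 1) > 1e-3))
      stop("motif ", id, ": column ", which(abs(sums - 1) > 1e-3)[1],
           " sums to ", signif(sums[which(abs(sums - 1) > 1e-3)[1]], 4))
    probs <- sweep(probs, 2, sums, "/")
    motifs[[i]] <- structure(
      list(motif_id = id, width = ncol(probs), probs = probs,
           background = unname(bg) / sum(bg), pseudocount = pseudocount),
      class = "pwm")
  }
  motifs
}

#' Construct a PWM directly
#' @param motif_id motif name.
#' @param probs 4 x width probability matrix (rows A,C,G,T; columns sum to 1).
#' @param background length-4 background base probabilities (sums to 1).
#' @param pseudocount pseudocount weight for log-odds formation.
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, probs, background = rep(0.25, 4), pseudocount = 0.1) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A,C,G,T)")
  if (ncol(probs) < 1) stop("PWM width must be >= 1")
  if (any(abs(colSums(probs) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, width = ncol(probs), probs = probs,
                 background = as.numeric(background),
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$motif_id, "width", x$width, "\n")
  invisible(x)
}

#' Read a bedGraph track into per-base vectors
#'
#' Loads a bedGraph file as one numeric vector per chromosome (one value per
#' bp, 0 where the track has no line). Overlapping bedGraph intervals are an
#' error; intervals on chromosomes absent from the genome spec are an error.
#'
#' @param path bedGraph file path.
#' @param genome a [genome_spec()].
#' @return named list of numeric vectors, one per genome chromosome.
#' @export
read_bedgraph <- function(path, genome) {
  iv <- read_intervals(path, format = "BED3")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  vals <- vapply(strsplit(lines[keep], "\t", fixed = TRUE), function(f) {
    if (length(f) < 4) stop("bedGraph line with fewer than 4 fields")
    as.numeric(f[4])
  }, 0)
  chrom_stratum(iv$chrom, genome)  # validates chromosomes
  track <- lapply(seq_len(nrow(genome)), function(i)
    numeric(genome$length[i]))
  names(track) <- genome$chrom
  for (chr in unique(iv$chrom)) {
    sel <- iv$chrom == chr
    s <- iv$start[sel]; e <- iv$end[sel]; v <- vals[sel]
    if (any(e > genome$length[match(chr, genome$chrom)]))
      stop("bedGraph interval beyond chromosome end on ", chr)
    o <- order(s)
    s <- s[o]; e <- e[o]; v <- v[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)]))
      stop("overlapping bedGraph intervals on ", chr)
    for (k in seq_along(s)) track[[chr]][(s[k] + 1):e[k]] <- v[k]
  }
  track
}

#' Write a table as deterministic TSV (header, no quoting, no row names)
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV with header
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
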