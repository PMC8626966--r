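# Synthetic fixtures: truncated power-law length samples, a planted
# transcript locus with a gap-bearing model read and surrounding fragments,
# and screening-cascade truth tables. Everything is generated from a seeded
# configuration so tests and examples need no downloads.

#' Simulation configuration
#'
#' Defaults mirror the data shapes the method targets: a 149 bp model read
#' carrying a 23 bp alignment gap, a planted transcript of 1556 bp, sonicated
#' fragments of mean 200 bp, a transcript-length exponent near 0.6 with the
#' median cutoff near 6932 bp, and screening categories at the proportions
#' observed in a real unmapped fraction (scaled to 1000 reads).
#'
#' @param seed Integer RNG seed.
#' @param alpha Power-law exponent of transcript length.
#' @param x_min,x_max Support bounds in bp.
#' @param n_transcripts Number of transcript lengths to sample.
#' @param planted_length Planted transcript length in bp.
#' @param model_read_length Model read length in bp.
#' @param gap_length Reference gap inside the model read's alignment (bp).
#' @param model_offset Distance from transcript start to the model
#'   alignment's start (bp); the planted left extension.
#' @param fragment_count Number of fragments drawn from the transcript.
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution (bp), clipped at 20 bp.
#' @param decoy_count Off-transcript decoy fragments.
#' @param category_counts Named integer vector over the screening categories.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       alpha = 0.594,
                       x_min = 1,
                       x_max = 6932,
                       n_transcripts = 5000L,
                       planted_length = 1556L,
                       model_read_length = 149L,
                       gap_length = 23L,
                       model_offset = 1117L,
                       fragment_count = 80L,
                       fragment_length_mean = 200,
                       fragment_length_sd = 30,
                       decoy_count = 0L,
                       category_counts = c(unpaired = 324L, contaminant = 32L,
                                           low_quality = 2L, annotated = 464L,
                                           low_score = 167L,
                                           new_annotated = 5L,
                                           candidate = 6L)) {
  stopifnot(x_min < x_max, gap_length >= 1, planted_length >= 1,
            all(category_counts >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Continuous truncated power-law sampler
#'
#' Inverse-CDF draws from a density proportional to `x^-alpha` on
#' `[x_min, x_max]` (`alpha = 1` handled by the log-uniform branch).
#'
#' @param n Sample size.
#' @inheritParams ptrunc_powerlaw
#' @return Numeric vector of length `n`.
#' @export
rtrunc_powerlaw <- function(n, alpha, x_min, x_max) {
  if (!(x_min > 0 && x_min < x_max)) stop("need 0 < x_min < x_max")
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    x_min * (x_max / x_min)^u
  } else {
    b <- 1 - alpha
    (x_min^b + u * (x_max^b - x_min^b))^(1 / b)
  }
}

#' Sample a synthetic transcript-length table
#'
#' Draws `n_transcripts` truncated power-law lengths and floors them to
#' integer bp (flooring keeps the empirical upper tail at integer thresholds
#' equal to the continuous tail). Seeded from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [transcript_lengths()] table.
#' @export
sample_truncated_powerlaw <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  x <- rtrunc_powerlaw(config$n_transcripts, config$alpha,
                       config$x_min, config$x_max)
  lengths <- pmax(floor(x), ceiling(config$x_min))
  transcript_lengths(lengths, source_label = sprintf(
    "simulated: alpha=%g, support=[%g,%g], seed=%d",
    config$alpha, config$x_min, config$x_max, config$seed))
}

#' Write a sampled transcript-length population as a GTF annotation
#'
#' Lays the table's transcripts head to tail (1 kb apart) on one virtual
#' chromosome, each as a single-exon transcript, so the annotation readers
#' recover exactly the sampled lengths.
#'
#' @param table A [transcript_lengths()] table.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_lengths_gtf <- function(table, path) {
  starts <- cumsum(c(1, utils::head(table$length, -1L) + 1000))
  ends <- starts + table$length - 1
  attrs <- sprintf('gene_id "g_%s"; transcript_id "%s";',
                   table$transcript_id, table$transcript_id)
  lines <- c(
    sprintf("chrL\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s", starts, ends, attrs),
    sprintf("chrL\tsim\texon\t%d\t%d\t.\t+\t.\t%s", starts, ends, attrs))
  # interleave transcript/exon per transcript for a conventional layout
  writeLines(lines[order(rep(seq_len(nrow(table)), 2L))], path)
  invisible(path)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sam_header <- function(chrom, len) {
  c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}

#' Generate a planted transcript locus
#'
#' Builds one random chromosome holding a single planted transcript, a model
#' read whose alignment contains an internal reference gap (CIGAR `N`
#' operation), and sonication-style fragments drawn as subintervals of the
#' transcript (uniform start, Gaussian length). Optional decoy fragments are
#' placed outside the transcript. Emits genome FASTA, annotation GTF, model
#' read SAM, fragments as paired-end SAM and as BED, and a truth JSON
#' recording the planted span and every fragment's distance to the anchor.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the output `paths` and the `truth` list.
#' @export
make_planted_locus <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  L <- config$planted_length
  margin <- 3000L
  chrom <- "chrS"
  chrom_len <- L + 2L * margin
  if (config$decoy_count > 0L) {
    # room for decoys beyond the model support on the right flank
    chrom_len <- chrom_len + as.integer(ceiling(1.5 * config$x_max))
  }
  genome <- random_dna(chrom_len)

  t_start <- margin + 1L
  t_end <- margin + L
  ref_span <- config$model_read_length + config$gap_length
  if (config$model_offset + ref_span > L) {
    stop("model read (plus gap) does not fit the planted transcript at this offset")
  }
  m_start <- t_start + config$model_offset
  m_end <- m_start + ref_span - 1L
  gap_after <- min(60L, config$model_read_length - 1L)
  cigar <- sprintf("%dM%dN%dM", gap_after, config$gap_length,
                   config$model_read_length - gap_after)
  anchor_center <- interval_center(m_start, m_end)

  # fragments are subintervals of the planted transcript (sonicated cDNA)
  frag_len <- pmin(pmax(round(stats::rnorm(config$fragment_count,
                                           config$fragment_length_mean,
                                           config$fragment_length_sd)), 20L), L)
  frag_start <- vapply(frag_len, function(l)
    sample(seq.int(t_start, t_end - l + 1L), 1L), numeric(1L))
  frag <- data.frame(
    name = sprintf("frag%05d", seq_len(config$fragment_count)),
    start = as.integer(frag_start),
    end = as.integer(frag_start + frag_len - 1L),
    is_decoy = rep(FALSE, config$fragment_count), stringsAsFactors = FALSE)

  if (config$decoy_count > 0L) {
    # decoy centers beyond the model support: membership probability 0
    dl <- pmin(pmax(round(stats::rnorm(config$decoy_count,
                                       config$fragment_length_mean,
                                       config$fragment_length_sd)), 20L), margin - 1L)
    dc <- round(anchor_center +
                  stats::runif(config$decoy_count,
                               config$x_max + config$fragment_length_mean,
                               1.4 * config$x_max))
    ds <- as.integer(dc - floor(dl / 2))
    frag <- rbind(frag, data.frame(
      name = sprintf("decoy%05d", seq_len(config$decoy_count)),
      start = ds, end = as.integer(ds + dl - 1L),
      is_decoy = TRUE, stringsAsFactors = FALSE))
  }
  frag$center <- interval_center(frag$start, frag$end)
  frag$distance <- abs(frag$center - anchor_center)

  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "annotation.gtf"),
    model_sam = file.path(outdir, "model.sam"),
    fragments_sam = file.path(outdir, "fragments.sam"),
    fragments_bed = file.path(outdir, "fragments.bed"),
    truth = file.path(outdir, "truth.json")
  )

  writeLines(c(paste0(">", chrom), genome), paths$genome)

  attr_str <- 'gene_id "geneS1"; transcript_id "txS1";'
  gtf <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tgene_id \"geneS1\";",
            chrom, t_start, t_end),
    sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s", chrom, t_start, t_end, attr_str),
    sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\t%s", chrom, t_start, t_end, attr_str)
  )
  writeLines(gtf, paths$gtf)

  # model read: the aligned bases flank the gap
  seq1 <- substr(genome, m_start, m_start + gap_after - 1L)
  seq2 <- substr(genome, m_start + gap_after + config$gap_length, m_end)
  model_seq <- paste0(seq1, seq2)
  writeLines(c(
    sam_header(chrom, chrom_len),
    paste("model_read", 0L, chrom, m_start, 60L, cigar, "*", 0L, 0L,
          model_seq, strrep("I", nchar(model_seq)), sep = "\t")
  ), paths$model_sam)

  # fragments as read pairs (template = outermost mate coordinates)
  sam <- sam_header(chrom, chrom_len)
  for (i in seq_len(nrow(frag))) {
    s <- frag$start[i]; e <- frag$end[i]
    len <- e - s + 1L
    mlen <- min(75L, len)
    p1 <- s; p2 <- e - mlen + 1L
    r1 <- substr(genome, p1, p1 + mlen - 1L)
    r2 <- substr(genome, p2, p2 + mlen - 1L)
    q <- strrep("I", mlen)
    sam <- c(sam,
      paste(frag$name[i], 99L, chrom, p1, 60L, paste0(mlen, "M"), "=", p2,
            len, r1, q, sep = "\t"),
      paste(frag$name[i], 147L, chrom, p2, 60L, paste0(mlen, "M"), "=", p1,
            -len, r2, q, sep = "\t"))
  }
  writeLines(sam, paths$fragments_sam)
  nfr <- nrow(frag)
  write_bed(data.frame(chrom = rep(chrom, nfr), start = frag$start,
                       end = frag$end, name = frag$name,
                       score = rep(0, nfr), strand = rep("+", nfr)),
            paths$fragments_bed)

  truth <- list(
    schema = "readbait/locus_truth/1",
    chrom = chrom, chrom_length = chrom_len,
    transcript_start = t_start, transcript_end = t_end,
    transcript_length = L,
    model_start = m_start, model_end = m_end, model_cigar = cigar,
    model_read_length = config$model_read_length,
    gap_length = config$gap_length,
    anchor_center = anchor_center,
    ext_left = m_start - t_start, ext_right = t_end - m_end,
    fragments = frag
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(paths = paths, truth = truth))
}

#' Generate a screening-cascade fixture with planted category truth
#'
#' Emits a FASTQ pair, contaminant / annotation / new-annotation id lists and
#' a BLAT-style PSL score file such that [classify_reads()] must reproduce
#' `config$category_counts` exactly. Unpaired reads appear in the first-mate
#' file only; low-quality reads carry Phred 2 bases; low-score reads get PSL
#' score 50, every other read 200.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the output `paths` and the `truth` list.
#' @export
make_screen_fixture <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- config$category_counts
  stopifnot(all(SCREEN_CATEGORIES %in% names(counts)))
  counts <- counts[SCREEN_CATEGORIES]
  category <- rep(SCREEN_CATEGORIES, counts)
  n <- length(category)
  ids <- sprintf("read%06d", seq_len(n))
  read_len <- 100L

  paths <- list(
    fastq1 = file.path(outdir, "reads_R1.fastq"),
    fastq2 = file.path(outdir, "reads_R2.fastq"),
    contaminant_ids = file.path(outdir, "contaminant_ids.txt"),
    annot_ids = file.path(outdir, "annot_ids.txt"),
    new_annot_ids = file.path(outdir, "new_annot_ids.txt"),
    psl = file.path(outdir, "hits.psl"),
    truth = file.path(outdir, "truth.json")
  )

  con1 <- file(paths$fastq1, "w"); con2 <- file(paths$fastq2, "w")
  for (i in seq_len(n)) {
    qual <- if (category[i] == "low_quality") strrep("#", read_len)
            else strrep("I", read_len)
    writeLines(c(paste0("@", ids[i], "/1"), random_dna(read_len), "+", qual), con1)
    if (category[i] != "unpaired") {
      writeLines(c(paste0("@", ids[i], "/2"), random_dna(read_len), "+", qual), con2)
    }
  }
  close(con1); close(con2)

  writeLines(ids[category == "contaminant"], paths$contaminant_ids)
  writeLines(ids[category == "annotated"], paths$annot_ids)
  writeLines(ids[category == "new_annotated"], paths$new_annot_ids)

  score <- ifelse(category == "low_score", 50L, 200L)
  psl <- sprintf(
    "%d\t0\t0\t0\t0\t0\t0\t0\t+\t%s\t%d\t0\t%d\tchrT\t100000\t0\t%d\t1\t%d,\t0,\t0,",
    score, ids, read_len, read_len, read_len, read_len)
  writeLines(psl, paths$psl)

  truth <- list(schema = "readbait/screen_truth/1", total = n,
                counts = as.list(counts),
                category = data.frame(read_id = ids, category = category,
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(paths = paths, truth = truth))
}
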