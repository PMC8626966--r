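# Coordinate conventions, alignment/BED readers, small writers.
#
# Internal representation is 1-based inclusive (SAM convention); BED is
# 0-based half-open. Converters are exact inverses.

#' Construct a genomic interval (internal 1-based inclusive convention)
#'
#' @param chrom Sequence name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 1) || any(end < 1)) stop("coordinates must be positive")
  if (any(start > end)) stop("start must not exceed end")
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Convert an interval between coordinate dialects
#'
#' `bed` is 0-based half-open (`start - 1`, `end`); `sam` and `internal` are
#' 1-based inclusive. Round trips are lossless.
#'
#' @param interval A [genomic_interval()] (assumed in `from` dialect).
#' @param from,to One of `"internal"`, `"sam"`, `"bed"`.
#' @return A `genomic_interval` in the target dialect.
#' @export
convert_coordinates <- function(interval, from = "internal", to = "bed") {
  dialects <- c("internal", "sam", "bed")
  from <- match.arg(from, dialects); to <- match.arg(to, dialects)
  s <- interval$start; e <- interval$end
  if (any(s < 0) || any(e < 0)) stop("coordinates must be non-negative")
  # normalize to internal
  if (from == "bed") s <- s + 1
  if (to == "bed") s <- s - 1
  out <- interval
  out$start <- s; out$end <- e
  attr(out, "dialect") <- to
  out
}

# ensure a SAM/BAM path is usable by Rsamtools: convert SAM to a temporary
# BAM on the fly
as_bam_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

# read alignment records needed downstream from SAM or BAM
read_alignment_records <- function(path) {
  bam <- as_bam_path(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq")
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    stringsAsFactors = FALSE
  )
}

# sequence names declared in a SAM/BAM header
alignment_seqnames <- function(path) {
  bam <- as_bam_path(path)
  names(Rsamtools::scanBamHeader(bam)[[1L]]$targets)
}

#' Read a BED file into 1-based inclusive fragment intervals
#'
#' @param path BED3+ file (0-based half-open on disk).
#' @return data.frame with `name`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed_fragments <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) gr$name else sprintf("frag%05d", seq_along(gr))
  data.frame(
    name = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write 1-based inclusive intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else "."
  score <- if (!is.null(df$score)) df$score else 0
  strand <- if (!is.null(df$strand)) df$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$chrom, as.integer(df$start - 1L), as.integer(df$end),
                   name, format(score, trim = TRUE), strand)
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain list of read identifiers (one per line)
#'
#' @param path Text file; blank lines and `#` comments are ignored.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Run the whole salvage pipeline: screen, fit, extend
#'
#' Executes the three analysis stages on one configuration and writes their
#' outputs plus a manifest into a run directory. The configuration is a named
#' list (or the path of a YAML file holding one) with elements:
#'
#' * `inputs`: `unmapped` (SAM/BAM of the unmapped fraction), `fastq1`/
#'   `fastq2`, `contaminant_ids`, `annot_ids`, `psl`, `new_annot_ids`
#'   (screen stage); `gtf` (fit stage); `alignments` (SAM/BAM/BED of
#'   resequencing fragments), `genome` (FASTA) (extend stage).
#' * `params`: `anchor` (`"chrom:pos"`), `model_span` (`"chrom:start-end"`),
#'   `strand`, and optionally `bin_width`, `mode`, `threshold`, `minscore`,
#'   `min_gap`, `min_mean_phred`, `min_length`, `window`, `seed`.
#' * `outdir`: run directory, created if needed.
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, a list with the three stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$outdir))
  inp <- config$inputs
  par <- if (is.null(config$params)) list() else config$params
  needed <- c("unmapped", "fastq1", "contaminant_ids", "annot_ids", "psl",
              "new_annot_ids", "gtf", "alignments", "genome")
  for (k in needed) {
    if (is.null(inp[[k]]) || !file.exists(inp[[k]])) {
      stop("pipeline input missing before any stage ran: ", k)
    }
  }
  if (is.null(par$anchor) || is.null(par$model_span)) {
    stop("params must provide anchor ('chrom:pos') and model_span ('chrom:start-end')")
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  getp <- function(name, default) if (is.null(par[[name]])) default else par[[name]]

  # stage 1: screening cascade + gap rule
  reads <- read_fastq_reads(inp$fastq1, if (is.null(inp$fastq2)) NULL else inp$fastq2)
  report <- classify_reads(
    reads,
    contaminant_hits = read_id_list(inp$contaminant_ids),
    annotation_hits = read_id_list(inp$annot_ids),
    score_table = read_psl_scores(inp$psl),
    new_annotation_hits = read_id_list(inp$new_annot_ids),
    minscore = getp("minscore", 130),
    min_mean_phred = getp("min_mean_phred", 15),
    min_length = getp("min_length", 36)
  )
  gaps <- gap_candidates(inp$unmapped, min_gap = getp("min_gap", 21))
  write_screen_report(report, file.path(outdir, "screen"))
  if (nrow(gaps)) {
    write_bed(data.frame(chrom = gaps$chrom, start = gaps$gap_start,
                         end = gaps$gap_end, name = gaps$read_id),
              file.path(outdir, "screen_gaps.bed"))
  }
  write_tsv(gaps, file.path(outdir, "screen_gaps.tsv"))

  # stage 2: power-law fit of the transcript length distribution
  fitres <- fit_length_distribution(inp$gtf, bin_width = getp("bin_width", 100))
  write_fit_json(fitres$fit, file.path(outdir, "fit.json"),
                 median_cutoff = fitres$median, text_report = TRUE)

  # stage 3: fragment scoring and span estimation
  anchor <- parse_anchor(par$anchor, par$model_span, getp("strand", "*"))
  model <- membership_model(fitres$fit, mode = getp("mode", "truncated"),
                            threshold = getp("threshold", 0.3))
  frags <- collect_fragments(inp$alignments, anchor,
                             window = getp("window", fitres$fit$x_max))
  scored <- score_fragments(frags, model)
  est <- estimate_extension(anchor, scored)
  write_extension_outputs(est, scored, inp$genome, outdir)

  manifest <- list(
    schema = "readbait/manifest/1",
    stages = c("screen", "fitlaw", "extend"),
    inputs = inp,
    params = par,
    package_version = as.character(utils::packageVersion("readbait"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(screen = report, gaps = gaps, fit = fitres$fit,
                 estimate = est, manifest = manifest))
}

# parse "chrom:pos" / "chrom:start-end" into an anchor_point
parse_anchor <- function(anchor, model_span, strand = "*") {
  a <- strsplit(anchor, ":", fixed = TRUE)[[1L]]
  m <- strsplit(model_span, "[:-]")[[1L]]
  if (length(a) != 2L || length(m) != 3L) {
    stop("expected anchor 'chrom:pos' and model_span 'chrom:start-end'")
  }
  anchor_point(chrom = a[1L], center = as.numeric(gsub(",", "", a[2L])),
               model_start = as.numeric(gsub(",", "", m[2L])),
               model_end = as.numeric(gsub(",", "", m[3L])),
               strand = strand)
}
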