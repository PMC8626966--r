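# The salvage cascade on the unmapped fraction: category accounting,
# quality filtering and the >20 bp alignment-gap rule.
#
# The external aligners and filters (rRNA screening, annotation mapping,
# BLAT/BLAST) are consumed through their outputs: id sets and score tables.
# The cascade itself -- its fixed order and thresholds -- is what this module
# implements.

#' Read FASTQ reads into a plain table
#'
#' @param fastq1 Path to the first-mate (or single-end) FASTQ.
#' @param fastq2 Optional second-mate FASTQ.
#' @return data.frame with `read_id`, `mate` (1, 2 or 0 for unpaired input),
#'   `sequence`, `quality` (Phred-33 string).
#' @export
read_fastq_reads <- function(fastq1, fastq2 = NULL) {
  one <- function(path, mate) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    ids <- sub("[/ ].*$", "", names(x))
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    seqs <- x
    names(seqs) <- NULL
    S4Vectors::mcols(seqs) <- NULL
    data.frame(
      read_id = ids,
      mate = rep(mate, length(ids)),
      sequence = as.character(seqs),
      quality = if (is.null(qual)) character(0L) else qual,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(fastq2)) return(one(fastq1, 0L))
  rbind(one(fastq1, 1L), one(fastq2, 2L))
}

#' Mean-quality / length filter for reads
#'
#' A read passes when its mean Phred score is at least `min_mean_phred`
#' (inclusive at the boundary) and its length is at least `min_length`.
#' These explicit thresholds replace tool-version-dependent "default
#' arguments" of read-trimming programs so results are reproducible.
#'
#' @param reads data.frame with `sequence` and `quality` (Phred-33) columns,
#'   as from [read_fastq_reads()].
#' @param min_mean_phred Minimum mean base quality (default 15).
#' @param min_length Minimum read length in bp (default 36).
#' @return Logical vector, `TRUE` for reads that pass.
#' @export
quality_filter <- function(reads, min_mean_phred = 15, min_length = 36) {
  if (nrow(reads) == 0L) return(logical(0L))
  codes <- lapply(reads$quality, function(q) utf8ToInt(q) - 33L)
  bad <- vapply(codes, function(v) any(v < 0L | v > 93L), logical(1L))
  if (any(bad)) {
    stop("non-Phred-33 quality characters in read(s): ",
         paste(utils::head(reads$read_id[bad], 3L), collapse = ", "))
  }
  mean_q <- vapply(codes, function(v) if (length(v)) mean(v) else 0, numeric(1L))
  len <- nchar(reads$sequence)
  if (any(len != nchar(reads$quality))) {
    stop("sequence and quality lengths differ")
  }
  mean_q >= min_mean_phred & len >= min_length
}

SCREEN_CATEGORIES <- c("unpaired", "contaminant", "low_quality", "annotated",
                       "low_score", "new_annotated", "candidate")

#' Classify unmapped reads through the salvage cascade
#'
#' Each read is assigned to exactly the first matching category of the fixed
#' cascade: unpaired, contaminant (rRNA / mitochondrial / microbial hits),
#' low quality, annotated (already present in the reference annotation; the
#' union of the annotation aligners' hits), low alignment score (below
#' `minscore`), newly annotated transcript, and finally candidate -- the
#' surviving salvageable reads.
#'
#' Classification is per read id (sequencing template): the two mates of a
#' pair are one unit of accounting, a template is unpaired when one mate is
#' missing (or the input is single-end, `mate == 0`), and it is low quality
#' when any of its mates fails [quality_filter()].
#'
#' @param reads data.frame from [read_fastq_reads()] (`read_id`, `mate`,
#'   `sequence`, `quality`).
#' @param contaminant_hits,annotation_hits,new_annotation_hits Character
#'   vectors of read ids flagged by the external screens. Pass the union of
#'   several aligners' hits as `annotation_hits` when more than one was run.
#' @param score_table Named numeric vector of alignment scores per read id
#'   (e.g. from [read_psl_scores()]); ids absent from it score `-Inf`.
#' @param minscore Minimum alignment score to survive (default 130).
#' @param min_mean_phred,min_length Passed to [quality_filter()].
#' @return A `screen_report` list: `total`, `counts`, `fractions` (both named
#'   by category), `candidate_ids`, and `category` (per input read).
#' @export
classify_reads <- function(reads,
                           contaminant_hits = character(),
                           annotation_hits = character(),
                           score_table = numeric(),
                           new_annotation_hits = character(),
                           minscore = 130,
                           min_mean_phred = 15,
                           min_length = 36) {
  stopifnot(is.data.frame(reads))
  n <- nrow(reads)
  for (s in list(contaminant_hits, annotation_hits, new_annotation_hits)) {
    missing <- setdiff(s, reads$read_id)
    if (length(missing)) {
      warning(length(missing), " hit id(s) absent from the input reads (e.g. ",
              missing[1L], ")")
    }
  }
  ids <- unique(reads$read_id)
  n_ids <- length(ids)
  if (n_ids == 0L) {
    counts <- stats::setNames(integer(length(SCREEN_CATEGORIES)), SCREEN_CATEGORIES)
    return(structure(list(total = 0L, counts = counts,
                          fractions = counts * 0,
                          candidate_ids = character(),
                          category = stats::setNames(character(), character())),
                     class = "screen_report"))
  }
  mates <- split(reads$mate, reads$read_id)[ids]
  paired <- vapply(mates, function(m) all(c(1L, 2L) %in% m), logical(1L))
  rec_ok <- quality_filter(reads, min_mean_phred, min_length)
  qual_ok <- vapply(split(rec_ok, reads$read_id)[ids], all, logical(1L))
  scores <- ifelse(ids %in% names(score_table),
                   unname(score_table[ids]), -Inf)

  category <- rep("candidate", n_ids)
  remaining <- rep(TRUE, n_ids)
  steps <- list(
    list(!paired, "unpaired"),
    list(ids %in% contaminant_hits, "contaminant"),
    list(!qual_ok, "low_quality"),
    list(ids %in% annotation_hits, "annotated"),
    list(scores < minscore, "low_score"),
    list(ids %in% new_annotation_hits, "new_annotated")
  )
  for (s in steps) {
    take <- remaining & s[[1L]]
    category[take] <- s[[2L]]
    remaining <- remaining & !take
  }
  counts <- stats::setNames(
    vapply(SCREEN_CATEGORIES, function(k) sum(category == k), integer(1L)),
    SCREEN_CATEGORIES)
  structure(list(
    total = n_ids,
    counts = counts,
    fractions = counts / n_ids,
    candidate_ids = ids[category == "candidate"],
    category = stats::setNames(category, ids)
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Unmapped-read salvage report:", x$total, "reads\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-14s %8d  (%5.1f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  }
  invisible(x)
}

#' Write a screen report as TSV and JSON
#'
#' @param report A `screen_report`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_screen_report <- function(report, prefix) {
  df <- data.frame(category = names(report$counts),
                   count = as.integer(report$counts),
                   fraction = as.numeric(report$fractions))
  write_tsv(df, paste0(prefix, ".tsv"))
  jsonlite::write_json(
    list(schema = "readbait/screen_report/1", total = report$total,
         counts = as.list(report$counts),
         fractions = as.list(report$fractions),
         candidate_ids = report$candidate_ids),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Alignment scores from a BLAT PSL file
#'
#' Computes the standard BLAT score `matches + repMatches - misMatches -
#' qNumInsert - tNumInsert` per row and keeps the best score per query.
#' A `psLayout` header, if present, is skipped.
#'
#' @param path PSL file.
#' @return Named numeric vector of scores keyed by query name.
#' @export
read_psl_scores <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- grep("^[0-9]+\t", lines, value = TRUE)
  if (!length(body)) return(stats::setNames(numeric(0L), character(0L)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 21L)) {
    stop("PSL line with fewer than 21 columns (first at body line ",
         which(nf < 21L)[1L], ")")
  }
  m <- vapply(fields, function(f) as.numeric(f[c(1L, 2L, 3L, 5L, 7L)]),
              numeric(5L))
  score <- m[1L, ] + m[3L, ] - m[2L, ] - m[4L, ] - m[5L, ]
  qname <- vapply(fields, `[[`, character(1L), 10L)
  out <- tapply(score, qname, max)
  stats::setNames(as.numeric(out), names(out))
}

#' Reference-space gaps of a CIGAR string
#'
#' Walks a CIGAR from a 1-based alignment start and reports every `N`
#' (skipped region / intron) or `D` (deletion) operation as a 1-based
#' inclusive reference interval. Insertions and clips do not consume
#' reference and never produce gaps.
#'
#' @param cigar CIGAR string (e.g. `"60M23N66M"`).
#' @param pos 1-based leftmost aligned reference position.
#' @return data.frame with `gap_start`, `gap_end`, `gap_length`, `cigar_op`
#'   (one row per N/D operation, zero rows when there is none).
#' @export
cigar_gaps <- function(cigar, pos) {
  if (is.na(cigar) || cigar == "*") {
    stop("cannot walk an absent CIGAR ('*')")
  }
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  ref_consuming <- op %in% c("M", "D", "N", "=", "X")
  out <- data.frame(gap_start = integer(), gap_end = integer(),
                    gap_length = integer(), cigar_op = character(),
                    stringsAsFactors = FALSE)
  refpos <- pos
  for (i in seq_along(op)) {
    if (op[i] %in% c("N", "D")) {
      out <- rbind(out, data.frame(
        gap_start = refpos, gap_end = refpos + len[i] - 1L,
        gap_length = len[i], cigar_op = op[i], stringsAsFactors = FALSE))
    }
    if (ref_consuming[i]) refpos <- refpos + len[i]
  }
  out
}

#' Gap-bearing candidate reads from alignments
#'
#' Scans alignments for reads whose CIGAR contains a reference gap (`N` or
#' `D` operation) strictly longer than 20 bp -- such reads are likely to
#' straddle an unannotated intron and are the salvage candidates. A read
#' with several qualifying gaps yields several rows.
#'
#' @param alignments SAM/BAM path, or a data.frame with columns `qname`,
#'   `chrom`, `pos`, `cigar`.
#' @param min_gap Minimum qualifying gap length in bp; the default 21 encodes
#'   "strictly greater than 20 bp".
#' @return data.frame with `read_id`, `chrom`, `gap_start`, `gap_end`
#'   (1-based inclusive), `gap_length`, `cigar_op`.
#' @export
gap_candidates <- function(alignments, min_gap = 21) {
  if (is.character(alignments)) {
    alignments <- read_alignment_records(alignments)
    alignments <- alignments[!is.na(alignments$pos), , drop = FALSE]
  }
  empty <- data.frame(read_id = character(), chrom = character(),
                      gap_start = integer(), gap_end = integer(),
                      gap_length = integer(), cigar_op = character(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  rows <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    cg <- alignments$cigar[i]
    if (is.na(cg) || cg == "*") {
      warning("skipping record with absent CIGAR: ", alignments$qname[i])
      next
    }
    g <- cigar_gaps(cg, alignments$pos[i])
    g <- g[g$gap_length >= min_gap, , drop = FALSE]
    if (nrow(g)) {
      rows[[i]] <- cbind(data.frame(read_id = alignments$qname[i],
                                    chrom = alignments$chrom[i],
                                    stringsAsFactors = FALSE), g)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write candidate reads as FASTQ
#'
#' @param reads data.frame from [read_fastq_reads()].
#' @param ids Read ids to keep.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_candidate_fastq <- function(reads, ids, path) {
  keep <- reads[reads$read_id %in% ids, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(keep))) {
    suffix <- if (keep$mate[i] %in% c(1L, 2L)) paste0("/", keep$mate[i]) else ""
    writeLines(c(paste0("@", keep$read_id[i], suffix), keep$sequence[i],
                 "+", keep$quality[i]), con)
  }
  invisible(path)
}
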