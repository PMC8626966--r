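# Scoring fragments around a model-read anchor and estimating the
# full-length transcript span.

#' Define the model-read anchor
#'
#' @param chrom Chromosome of the model read.
#' @param center 1-based anchor coordinate (the model-read center).
#' @param model_start,model_end 1-based inclusive reference span of the model
#'   read's alignment (gap included).
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @return An `anchor_point` list.
#' @export
anchor_point <- function(chrom, center, model_start, model_end,
                         strand = c("*", "+", "-")) {
  strand <- match.arg(strand)
  if (!(model_start <= center && center <= model_end)) {
    stop("anchor center must lie inside the model span")
  }
  structure(list(chrom = chrom, center = as.numeric(center),
                 model_start = as.numeric(model_start),
                 model_end = as.numeric(model_end), strand = strand),
            class = "anchor_point")
}

# floor midpoint of 1-based inclusive intervals; even-length intervals bias
# the center < 1 bp toward the start
interval_center <- function(start, end) floor((start + end) / 2)

#' Collect mapped fragments near the anchor
#'
#' Reads alignments (SAM/BAM) or intervals (BED) and returns the fragments on
#' the anchor chromosome whose centers lie within `window` of the anchor
#' center. For paired-end alignments the two mates of a template are merged
#' into one fragment spanning their outermost coordinates when both map to
#' the anchor chromosome; a lone mapped mate stands for its fragment alone.
#' Secondary and supplementary alignments are excluded.
#'
#' @param alignments SAM/BAM/BED path.
#' @param anchor An [anchor_point()].
#' @param window Maximum center-to-center distance in bp.
#' @return data.frame of unscored fragment candidates: `name`, `chrom`,
#'   `start`, `end` (1-based inclusive), `center`, `distance_x`.
#' @export
collect_fragments <- function(alignments, anchor, window) {
  stopifnot(inherits(anchor, "anchor_point"), window > 0)
  ext <- tolower(tools::file_ext(alignments))
  if (ext == "bed") {
    frag <- read_bed_fragments(alignments)
  } else {
    if (!(anchor$chrom %in% alignment_seqnames(alignments))) {
      stop("anchor chromosome '", anchor$chrom, "' absent from alignment header")
    }
    rec <- read_alignment_records(alignments)
    rec <- rec[!is.na(rec$pos) & !is.na(rec$cigar), , drop = FALSE]
    # drop unmapped (0x4), secondary (0x100) and supplementary (0x800)
    keep <- bitwAnd(rec$flag, 0x4L) == 0L &
      bitwAnd(rec$flag, 0x100L) == 0L &
      bitwAnd(rec$flag, 0x800L) == 0L
    rec <- rec[keep & rec$chrom == anchor$chrom, , drop = FALSE]
    if (nrow(rec) == 0L) {
      frag <- data.frame(name = character(), chrom = character(),
                         start = integer(), end = integer())
    } else {
      rec$end <- rec$pos +
        GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar) - 1L
      starts <- tapply(rec$pos, rec$qname, min)
      ends <- tapply(rec$end, rec$qname, max)
      frag <- data.frame(name = names(starts), chrom = anchor$chrom,
                         start = as.integer(starts),
                         end = as.integer(ends[names(starts)]),
                         stringsAsFactors = FALSE)
    }
  }
  frag <- frag[frag$chrom == anchor$chrom, , drop = FALSE]
  if (nrow(frag) == 0L) {
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(), center = numeric(),
                      distance_x = numeric(), stringsAsFactors = FALSE))
  }
  frag$center <- interval_center(frag$start, frag$end)
  frag$distance_x <- abs(frag$center - anchor$center)
  frag <- frag[frag$distance_x <= window, , drop = FALSE]
  rownames(frag) <- NULL
  frag
}

#' Score fragments for co-membership with the model read
#'
#' Each fragment's probability of belonging to the model read's transcript is
#' the membership probability at its center-to-center distance; a fragment is
#' retained when that probability strictly exceeds the model's threshold.
#' A distance of zero (fragment center on the anchor) is clamped to the
#' model's `x_min` before scoring.
#'
#' @param fragments data.frame from [collect_fragments()].
#' @param model A [membership_model()].
#' @return The input with `probability` and `retained` columns added.
#' @export
score_fragments <- function(fragments, model) {
  stopifnot(inherits(model, "membership_model"))
  if (nrow(fragments) == 0L) {
    fragments$probability <- numeric(0L)
    fragments$retained <- logical(0L)
    return(fragments)
  }
  x <- pmax(fragments$distance_x, model$fit$x_min)
  fragments$probability <- membership_probability(model, x)
  fragments$retained <- fragments$probability > model$threshold
  fragments
}

#' Estimate the full-length span and its 5'/3' extensions
#'
#' The estimated span is the union of the model span with every retained
#' fragment: `[min(model_start, starts), max(model_end, ends)]`. Left/right
#' extensions are relabeled 5'/3' by strand (`+`: 5' is left; `-`: swapped;
#' unknown strand reports left/right with `strand_resolved = FALSE`).
#'
#' @param anchor An [anchor_point()].
#' @param scored data.frame from [score_fragments()] (possibly empty).
#' @return An `extension_estimate` list: `anchor`, `retained` (data.frame),
#'   `span_start`, `span_end`, `ext_left`, `ext_right`, `ext_5p`, `ext_3p`,
#'   `total_extension`, `full_length`, `strand_resolved`.
#' @export
estimate_extension <- function(anchor, scored) {
  stopifnot(inherits(anchor, "anchor_point"))
  kept <- if (nrow(scored)) scored[scored$retained, , drop = FALSE] else scored
  span_start <- if (nrow(kept)) min(anchor$model_start, kept$start) else anchor$model_start
  span_end <- if (nrow(kept)) max(anchor$model_end, kept$end) else anchor$model_end
  ext_left <- anchor$model_start - span_start
  ext_right <- span_end - anchor$model_end
  if (anchor$strand == "+") {
    e5 <- ext_left; e3 <- ext_right; resolved <- TRUE
  } else if (anchor$strand == "-") {
    e5 <- ext_right; e3 <- ext_left; resolved <- TRUE
  } else {
    e5 <- ext_left; e3 <- ext_right; resolved <- FALSE
  }
  structure(list(
    anchor = anchor,
    retained = kept,
    span_start = span_start,
    span_end = span_end,
    ext_left = ext_left,
    ext_right = ext_right,
    ext_5p = e5,
    ext_3p = e3,
    total_extension = ext_left + ext_right,
    full_length = span_end - span_start + 1,
    strand_resolved = resolved
  ), class = "extension_estimate")
}

#' @export
print.extension_estimate <- function(x, ...) {
  a <- x$anchor
  cat("Full-length span estimate\n")
  cat(sprintf("  anchor        %s:%s (%s)\n", a$chrom,
              format(a$center, big.mark = ","), a$strand))
  cat(sprintf("  model span    %s:%s-%s\n", a$chrom,
              format(a$model_start, big.mark = ","),
              format(a$model_end, big.mark = ",")))
  cat(sprintf("  retained      %d fragment(s)\n", nrow(x$retained)))
  cat(sprintf("  span          %s:%s-%s (%s bp)\n", a$chrom,
              format(x$span_start, big.mark = ","),
              format(x$span_end, big.mark = ","),
              format(x$full_length, big.mark = ",")))
  lab5 <- if (x$strand_resolved) "5' ext" else "left ext"
  lab3 <- if (x$strand_resolved) "3' ext" else "right ext"
  cat(sprintf("  %-13s %g bp\n", lab5, x$ext_5p))
  cat(sprintf("  %-13s %g bp\n", lab3, x$ext_3p))
  cat(sprintf("  total ext     %g bp\n", x$total_extension))
  invisible(x)
}

#' Extract the estimated span's genomic sequence
#'
#' @param genome FASTA path (or a `DNAStringSet`).
#' @param estimate An `extension_estimate`.
#' @return A `DNAStringSet` of length 1 named `chrom:start-end(strand)`,
#'   reverse-complemented on the minus strand.
#' @export
extract_span_sequence <- function(genome, estimate) {
  stopifnot(inherits(estimate, "extension_estimate"))
  seqs <- if (inherits(genome, "DNAStringSet")) genome else
    Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  a <- estimate$anchor
  if (!(a$chrom %in% names(seqs))) {
    stop("chromosome '", a$chrom, "' absent from genome")
  }
  chr <- seqs[[a$chrom]]
  if (estimate$span_end > length(chr) || estimate$span_start < 1) {
    stop("span ", estimate$span_start, "-", estimate$span_end,
         " outside chromosome bounds (1-", length(chr), ")")
  }
  s <- Biostrings::subseq(chr, estimate$span_start, estimate$span_end)
  if (a$strand == "-") s <- Biostrings::reverseComplement(s)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- sprintf("%s:%d-%d(%s)", a$chrom, estimate$span_start,
                        estimate$span_end, a$strand)
  out
}

#' Write the extension stage's outputs
#'
#' Emits the scored-fragment TSV, the estimate JSON, the span BED line and
#' (when a genome is given) the span FASTA into `outdir`.
#'
#' @param estimate An `extension_estimate`.
#' @param scored Scored fragment data.frame.
#' @param genome Optional genome FASTA path.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_extension_outputs <- function(estimate, scored, genome = NULL, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(scored, file.path(outdir, "fragments.tsv"))
  a <- estimate$anchor
  payload <- list(
    schema = "readbait/extension_estimate/1",
    chrom = a$chrom, anchor_center = a$center,
    model_start = a$model_start, model_end = a$model_end,
    strand = a$strand,
    span_start = estimate$span_start, span_end = estimate$span_end,
    n_retained = nrow(estimate$retained),
    ext_left = estimate$ext_left, ext_right = estimate$ext_right,
    ext_5p = estimate$ext_5p, ext_3p = estimate$ext_3p,
    strand_resolved = estimate$strand_resolved,
    total_extension = estimate$total_extension,
    full_length = estimate$full_length
  )
  jsonlite::write_json(payload, file.path(outdir, "extension.json"),
                       auto_unbox = TRUE, digits = NA)
  write_bed(data.frame(chrom = a$chrom, start = estimate$span_start,
                       end = estimate$span_end, name = "estimated_span",
                       score = 0,
                       strand = if (a$strand == "*") "." else a$strand),
            file.path(outdir, "span.bed"))
  if (!is.null(genome)) {
    Biostrings::writeXStringSet(extract_span_sequence(genome, estimate),
                                file.path(outdir, "span.fa"))
  }
  invisible(outdir)
}
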