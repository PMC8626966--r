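# Power-law model of transcript length and the fragment co-membership
# probability derived from it.

#' Extract transcript lengths from a GTF annotation
#'
#' Reads a GTF (GTF2.2 dialect) annotation and returns one length per
#' distinct transcript. When exon features are present for a transcript the
#' length is the sum of its exon spans (mature transcript length); otherwise
#' the span of the transcript feature itself is used.
#'
#' @param gtf Path to a GTF file (plain or gzip).
#' @param source_label Free-text label stored with the table; defaults to the
#'   file name.
#' @return A `transcript_lengths` object: a data.frame with columns
#'   `transcript_id` and `length` (bp), ordered by `transcript_id`, with
#'   attribute `source_label`.
#' @export
extract_transcript_lengths <- function(gtf, source_label = basename(gtf)) {
  if (!file.exists(gtf)) stop("GTF file not found: ", gtf)
  validate_gtf_lines(gtf)
  gr <- rtracklayer::import(gtf, format = "gtf")
  if (length(gr) == 0L) stop("annotation contains zero records: ", gtf)
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id)) {
    stop("annotation has no transcript_id attributes: ", gtf)
  }
  type <- as.character(meta$type)
  tid <- as.character(meta$transcript_id)
  w <- BiocGenerics::width(gr)

  is_exon <- type == "exon" & !is.na(tid)
  is_tx <- type == "transcript" & !is.na(tid)
  if (!any(is_exon) && !any(is_tx)) {
    stop("annotation contains no transcript or exon features: ", gtf)
  }
  exon_len <- tapply(w[is_exon], tid[is_exon], sum)
  tx_len <- tapply(w[is_tx], tid[is_tx], max)
  # exon-derived lengths take precedence over the transcript feature span
  only_tx <- setdiff(names(tx_len), names(exon_len))
  lengths <- c(exon_len, tx_len[only_tx])
  lengths <- lengths[order(names(lengths))]
  transcript_lengths(
    lengths = as.integer(lengths),
    transcript_id = names(lengths),
    source_label = source_label
  )
}

# Cheap structural validation so malformed lines are reported by number;
# rtracklayer's own errors do not carry line context.
validate_gtf_lines <- function(gtf) {
  lines <- readLines(gtf, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield < 9L]
  if (length(bad)) {
    stop("malformed GTF line ", bad[1L], " in ", gtf,
         ": expected 9 tab-separated fields, found ", nfield[match(bad[1L], which(body))])
  }
  invisible(TRUE)
}

#' Construct a transcript-length table
#'
#' @param lengths Positive integer lengths in bp, one per transcript.
#' @param transcript_id Optional transcript identifiers (recycled names are
#'   generated when absent).
#' @param source_label Free-text annotation label.
#' @return A `transcript_lengths` data.frame.
#' @export
transcript_lengths <- function(lengths, transcript_id = NULL,
                               source_label = "unknown") {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("all transcript lengths must be finite and >= 1 bp")
  }
  if (is.null(transcript_id)) {
    transcript_id <- sprintf("tx%06d", seq_along(lengths))
  }
  out <- data.frame(
    transcript_id = as.character(transcript_id),
    length = lengths,
    stringsAsFactors = FALSE
  )
  attr(out, "source_label") <- source_label
  class(out) <- c("transcript_lengths", "data.frame")
  out
}

#' Drop overlong transcripts above the sample median
#'
#' Transcripts strictly longer than the sample median are considered
#' overlong (long transcripts are over-represented in read counts relative
#' to short ones at equal expression) and removed before fitting.
#'
#' @param table A `transcript_lengths` object.
#' @param tie `"lower"` (default) takes the lower of the two central values
#'   as the median of an even-sized sample; `"mean"` takes their mean.
#' @return A list with `table` (retained lengths) and `median` (bp cutoff).
#' @export
filter_overlong <- function(table, tie = c("lower", "mean")) {
  tie <- match.arg(tie)
  x <- table$length
  if (length(x) == 0L) stop("cannot take the median of an empty length table")
  s <- sort(x)
  n <- length(s)
  med <- if (n %% 2L == 1L) {
    s[(n + 1L) %/% 2L]
  } else if (tie == "lower") {
    s[n %/% 2L]
  } else {
    (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
  }
  keep <- table[x <= med, , drop = FALSE]
  attr(keep, "source_label") <- attr(table, "source_label")
  class(keep) <- class(table)
  list(table = keep, median = med)
}

#' Bin transcript lengths at fixed width
#'
#' Bin with rank `k` covers lengths in `((k-1)*bin_width, k*bin_width]`, so a
#' length falling exactly on a bin boundary belongs to the lower bin.
#' Trailing empty bins are not emitted, interior zero-count bins are.
#'
#' @param table A `transcript_lengths` object.
#' @param bin_width Bin width in bp (default 100).
#' @return A `binned_frequency` data.frame with columns `rank` and `count`.
#' @export
bin_lengths <- function(table, bin_width = 100) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  x <- table$length
  if (length(x) == 0L) {
    out <- data.frame(rank = integer(), count = integer())
  } else {
    k <- as.integer(ceiling(x / bin_width))
    counts <- tabulate(k, nbins = max(k))
    out <- data.frame(rank = seq_len(max(k)), count = counts)
  }
  attr(out, "bin_width") <- bin_width
  class(out) <- c("binned_frequency", "data.frame")
  out
}

#' Fit a power law by log-log linear regression on binned frequencies
#'
#' Ordinary least squares of `ln(count)` on `ln(rank)` over the non-empty
#' bins. The exponent is the negated slope and the normalization constant is
#' `exp(intercept)`. Zero-count bins are dropped (their logarithm is
#' undefined), not smoothed.
#'
#' @param binned A `binned_frequency` object from [bin_lengths()].
#' @param x_min Lower support bound carried into the fit (bp, default 1).
#' @param x_max Upper support bound (bp); typically the median cutoff from
#'   [filter_overlong()]. Defaults to `bin_width * max(rank)`.
#' @return A `powerlaw_fit` list: `alpha`, `C`, `x_min`, `x_max`, `r2`,
#'   `adjusted_r2`, `slope_pvalue`, `n_bins_used`, `bin_width`.
#' @export
fit_loglog <- function(binned, x_min = 1, x_max = NULL) {
  used <- binned[binned$count > 0, , drop = FALSE]
  if (nrow(used) < 3L) {
    stop("need at least 3 non-empty bins to fit, got ", nrow(used))
  }
  if (length(unique(used$rank)) < 2L) {
    stop("degenerate regression: all counts fall in a single bin")
  }
  bin_width <- attr(binned, "bin_width")
  if (is.null(bin_width)) bin_width <- NA_real_
  if (is.null(x_max)) {
    x_max <- if (is.na(bin_width)) max(used$rank) else bin_width * max(binned$rank)
  }
  if (!(x_min < x_max)) stop("x_min must be strictly below x_max")

  # plain OLS of ln(count) on ln(rank); statistics computed directly so a
  # noiseless input (zero residual) stays exact and warning-free
  lx <- log(used$rank); ly <- log(used$count)
  n <- nrow(used)
  sxx <- sum((lx - mean(lx))^2)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sxx
  intercept <- mean(ly) - slope * mean(lx)
  res <- ly - (intercept + slope * lx)
  ss_res <- sum(res^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  se_slope <- sqrt(ss_res / (n - 2) / sxx)
  pval <- if (se_slope == 0) 0 else
    2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  structure(list(
    alpha = -slope,
    C = exp(intercept),
    x_min = x_min,
    x_max = x_max,
    r2 = r2,
    adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    slope_pvalue = pval,
    n_bins_used = n,
    bin_width = bin_width
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law fit (log-log binned OLS)\n")
  cat(sprintf("  alpha        %.6g\n", x$alpha))
  cat(sprintf("  C            %.6g\n", x$C))
  cat(sprintf("  support      [%g, %g] bp\n", x$x_min, x$x_max))
  cat(sprintf("  R^2          %.4f (adjusted %.4f)\n", x$r2, x$adjusted_r2))
  cat(sprintf("  slope p      %.3g\n", x$slope_pvalue))
  cat(sprintf("  bins used    %d (width %g bp)\n", x$n_bins_used, x$bin_width))
  invisible(x)
}

#' Build a fragment co-membership model
#'
#' Couples a power-law fit of transcript length with a retention threshold.
#' In `"truncated"` mode (default) the membership probability of a fragment
#' at center distance `x` from the model read is the upper-tail probability
#' of a power law with exponent `alpha` truncated to `[x_min, x_max]` -- a
#' proper distribution for every finite `alpha`, under which the
#' normalization constant cancels. `"literal"` mode instead evaluates
#' `1 - F(x)` with `F(x) = 1 - C/(alpha-1) * x^-(alpha-1)` using the stored
#' `C`, clamped into `[0, 1]` with a warning when clamping fires; this form
#' is improper for `alpha < 1` and is provided for audit only.
#'
#' @param fit A `powerlaw_fit`, or a list with at least `alpha`, `x_min`,
#'   `x_max` (and `C` for literal mode).
#' @param mode `"truncated"` or `"literal"`.
#' @param threshold Retention threshold in (0, 1); default 0.3. Fragments
#'   with probability strictly above it are retained.
#' @return A `membership_model` list.
#' @export
membership_model <- function(fit, mode = c("truncated", "literal"),
                             threshold = 0.3) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single probability in the open interval (0, 1)")
  }
  stopifnot(is.list(fit), !is.null(fit$alpha), !is.null(fit$x_min),
            !is.null(fit$x_max))
  if (!(fit$x_min < fit$x_max)) stop("fit must satisfy x_min < x_max")
  structure(list(fit = fit, mode = mode, threshold = threshold),
            class = "membership_model")
}

#' Upper-tail probability of a truncated power law
#'
#' `P(X >= x)` for a density proportional to `x^-alpha` on
#' `[x_min, x_max]`:
#' `(x_max^(1-alpha) - x^(1-alpha)) / (x_max^(1-alpha) - x_min^(1-alpha))`
#' for `alpha != 1`, and `log(x_max/x) / log(x_max/x_min)` at `alpha = 1`.
#' Values below `x_min` clamp to 1, above `x_max` to 0.
#'
#' @param x Distances / lengths (bp), strictly positive.
#' @param alpha Exponent.
#' @param x_min,x_max Support bounds, `0 < x_min < x_max`.
#' @return Probabilities in `[0, 1]`, vectorized over `x`.
#' @export
ptrunc_powerlaw <- function(x, alpha, x_min, x_max) {
  if (!(x_min > 0 && x_min < x_max)) stop("need 0 < x_min < x_max")
  if (any(x <= 0)) stop("x must be strictly positive")
  x <- pmin(pmax(x, x_min), x_max)
  if (abs(alpha - 1) < 1e-12) {
    log(x_max / x) / log(x_max / x_min)
  } else {
    b <- 1 - alpha
    (x_max^b - x^b) / (x_max^b - x_min^b)
  }
}

#' Quantile of the truncated power-law upper tail
#'
#' Inverse of [ptrunc_powerlaw()]: the distance `x` at which the upper-tail
#' probability equals `p`.
#'
#' @param p Upper-tail probabilities in `[0, 1]`.
#' @inheritParams ptrunc_powerlaw
#' @return Distances in `[x_min, x_max]`, vectorized over `p`.
#' @export
qtrunc_powerlaw <- function(p, alpha, x_min, x_max) {
  if (!(x_min > 0 && x_min < x_max)) stop("need 0 < x_min < x_max")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (abs(alpha - 1) < 1e-12) {
    x_max * (x_min / x_max)^p
  } else {
    b <- 1 - alpha
    (x_max^b - p * (x_max^b - x_min^b))^(1 / b)
  }
}

#' Co-membership probability of a fragment at distance x
#'
#' @param model A [membership_model()].
#' @param x Center-to-center distance(s) in bp, strictly positive.
#' @return Probabilities in `[0, 1]`, vectorized over `x`.
#' @export
membership_probability <- function(model, x) {
  stopifnot(inherits(model, "membership_model"))
  if (any(x <= 0)) stop("distance x must be strictly positive")
  fit <- model$fit
  if (model$mode == "truncated") {
    ptrunc_powerlaw(x, fit$alpha, fit$x_min, fit$x_max)
  } else {
    if (abs(fit$alpha - 1) < 1e-12) {
      stop("literal mode is undefined at alpha = 1 (division by zero)")
    }
    if (is.null(fit$C)) stop("literal mode requires a normalization constant C")
    p <- fit$C / (fit$alpha - 1) * x^(-(fit$alpha - 1))
    if (any(p < 0 | p > 1)) {
      warning("literal-mode probabilities clamped into [0, 1]")
      p <- pmin(pmax(p, 0), 1)
    }
    p
  }
}

#' Critical retention distance of a membership model
#'
#' The unique distance at which the truncated-mode membership probability
#' equals the model's threshold; fragments strictly closer are always
#' retained and strictly farther ones always dropped.
#'
#' @param model A [membership_model()] in truncated mode.
#' @return Distance in bp.
#' @export
critical_distance <- function(model) {
  stopifnot(inherits(model, "membership_model"))
  if (model$mode != "truncated") {
    stop("critical_distance is defined for truncated mode only")
  }
  qtrunc_powerlaw(model$threshold, model$fit$alpha,
                  model$fit$x_min, model$fit$x_max)
}

#' Serialize a power-law fit to JSON
#'
#' @param fit A `powerlaw_fit`.
#' @param path Output file; a sibling flat key-value `.txt` report is written
#'   alongside when `text_report = TRUE`.
#' @param median_cutoff Optional median cutoff (bp) recorded with the fit.
#' @param text_report Also write a plain-text report next to `path`.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, median_cutoff = NULL,
                           text_report = FALSE) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  payload <- unclass(fit)
  payload$median_cutoff <- median_cutoff
  payload$schema <- "readbait/powerlaw_fit/1"
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (text_report) {
    txt <- sub("\\.json$", ".txt", path)
    keys <- names(payload)
    writeLines(sprintf("%s\t%s", keys,
                       vapply(payload, function(v)
                         if (is.null(v)) "NA" else format(v, digits = 15),
                         character(1L))), txt)
  }
  invisible(path)
}

#' Read a power-law fit back from JSON
#'
#' @param path A file written by [write_fit_json()].
#' @return A `powerlaw_fit`.
#' @export
read_fit_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$schema <- NULL
  structure(payload, class = "powerlaw_fit")
}

#' Fit the full length-distribution pipeline from a GTF
#'
#' Convenience wrapper: extract lengths, drop overlong transcripts (above the
#' median), bin, and fit. The median cutoff becomes the fit's `x_max`.
#'
#' @inheritParams extract_transcript_lengths
#' @inheritParams bin_lengths
#' @inheritParams filter_overlong
#' @return A list with `fit` (`powerlaw_fit`), `median` (bp), and `table`
#'   (the retained `transcript_lengths`).
#' @export
fit_length_distribution <- function(gtf, bin_width = 100,
                                    tie = c("lower", "mean")) {
  tab <- extract_transcript_lengths(gtf)
  flt <- filter_overlong(tab, tie = match.arg(tie))
  binned <- bin_lengths(flt$table, bin_width = bin_width)
  fit <- fit_loglog(binned, x_min = 1, x_max = flt$median)
  list(fit = fit, median = flt$median, table = flt$table)
}
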