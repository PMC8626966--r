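# Independent oracles and small fixture builders used across the suite.

# upper-tail probability by numerical integration of x^-a, independent of
# the package's closed form
tail_integral_oracle <- function(x, alpha, x_min, x_max) {
  dens <- function(t) t^(-alpha)
  Z <- stats::integrate(dens, x_min, x_max, rel.tol = 1e-12)$value
  vapply(x, function(xi) {
    xi <- min(max(xi, x_min), x_max)
    stats::integrate(dens, xi, x_max, rel.tol = 1e-12)$value / Z
  }, numeric(1L))
}

# bisection on the integration oracle for the distance where the tail hits p
bisect_critical_oracle <- function(p, alpha, x_min, x_max, tol = 1e-9) {
  lo <- x_min; hi <- x_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tail_integral_oracle(mid, alpha, x_min, x_max) > p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# maximum-likelihood exponent of a truncated power law, by 1-D optimization
# of the exact log-likelihood on the raw samples
mle_truncated_alpha <- function(x, x_min, x_max) {
  nll <- function(a) {
    if (abs(a - 1) < 1e-9) a <- 1 + 1e-9
    b <- 1 - a
    a * mean(log(x)) + log((x_max^b - x_min^b) / b)
  }
  stats::optimize(nll, c(0.01, 10))$minimum
}

# character-by-character CIGAR walker, structured unlike the package's
# token-based implementation
naive_cigar_gaps <- function(cigar, pos) {
  num <- 0L
  ref <- pos
  out <- data.frame(gap_start = integer(), gap_end = integer(),
                    gap_length = integer(), cigar_op = character(),
                    stringsAsFactors = FALSE)
  for (ch in strsplit(cigar, "")[[1L]]) {
    if (ch %in% as.character(0:9)) {
      num <- num * 10L + as.integer(ch)
    } else {
      if (ch %in% c("N", "D")) {
        out <- rbind(out, data.frame(gap_start = ref, gap_end = ref + num - 1L,
                                     gap_length = num, cigar_op = ch,
                                     stringsAsFactors = FALSE))
      }
      if (ch %in% c("M", "=", "X", "D", "N")) ref <- ref + num
      num <- 0L
    }
  }
  out
}

# random valid CIGAR: alternates M blocks with I/D/N/S ops, M at both ends
random_cigar <- function() {
  n_mid <- sample(0:4, 1L)
  parts <- paste0(sample(1:150, 1L), "M")
  for (i in seq_len(n_mid)) {
    op <- sample(c("I", "D", "N"), 1L)
    parts <- c(parts, paste0(sample(1:60, 1L), op),
               paste0(sample(1:150, 1L), "M"))
  }
  paste(parts, collapse = "")
}

# hand-built GTF fixture writer
write_gtf_lines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start, end, tx = NULL, gene = "g1") {
  attrs <- sprintf('gene_id "%s";', gene)
  if (!is.null(tx)) attrs <- paste(attrs, sprintf('transcript_id "%s";', tx))
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t+\t.\t%s", chrom, type, start, end, attrs)
}

# minimal single/paired-record SAM writer for hand fixtures
write_mini_sam <- function(records, chrom = "chr1", chrom_len = 100000L,
                           path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
               records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos, cigar, rnext = "*",
                       pnext = 0L, tlen = 0L, seqlen = NULL) {
  if (is.null(seqlen)) {
    toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1L]]
    len <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    seqlen <- sum(len[op %in% c("M", "I", "S", "=", "X")])
  }
  paste(qname, flag, chrom, pos, 60L, cigar, rnext, pnext, tlen,
        strrep("A", seqlen), strrep("I", seqlen), sep = "\t")
}

# fixed-parameter membership model used repeatedly in tests
baseline_model <- function(threshold = 0.3, mode = "truncated") {
  fit <- structure(list(alpha = 0.594, C = 92637.295, x_min = 1,
                        x_max = 6932), class = "powerlaw_fit")
  membership_model(fit, mode = mode, threshold = threshold)
}
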