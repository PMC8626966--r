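# Fragment collection, scoring and span estimation around the model-read
# anchor.

test_that("paired alignments merge into one template fragment", {
  sam <- write_mini_sam(c(
    sam_record("pairA", 99L, "chr1", 9800L, "150M", "=", 10050L, 400L),
    sam_record("pairA", 147L, "chr1", 10050L, "150M", "=", 9800L, -400L)
  ))
  anchor <- anchor_point("chr1", 10000, 9990, 10010)
  fr <- collect_fragments(sam, anchor, window = 5000)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 9800L)
  expect_equal(fr$end, 10199L)
  expect_equal(fr$center, 9999)   # floor midpoint
  expect_equal(fr$distance_x, 1)
})

test_that("fragment collection respects flags, chromosome and window", {
  sam <- write_mini_sam(c(
    sam_record("single", 0L, "chr1", 9000L, "100M"),
    sam_record("secondary", 256L, "chr1", 9100L, "100M"),
    sam_record("supplementary", 2048L, "chr1", 9200L, "100M"),
    sam_record("far", 0L, "chr1", 50000L, "100M")
  ))
  anchor <- anchor_point("chr1", 10000, 9990, 10010)
  fr <- collect_fragments(sam, anchor, window = 2000)
  expect_equal(fr$name, "single")

  expect_error(collect_fragments(sam, anchor_point("chrX", 10, 5, 15), 100),
               "absent from alignment header")

  empty <- write_mini_sam(character())
  expect_equal(nrow(collect_fragments(empty, anchor, 1000)), 0L)
})

test_that("BED input yields the same fragments as SAM pairs", {
  loc <- make_planted_locus(sim_config(seed = 5, fragment_count = 25L),
                            tempfile())
  tr <- loc$truth
  anchor <- anchor_point(tr$chrom, tr$anchor_center, tr$model_start,
                         tr$model_end, "+")
  a <- collect_fragments(loc$paths$fragments_sam, anchor, window = 6932)
  b <- collect_fragments(loc$paths$fragments_bed, anchor, window = 6932)
  a <- a[order(a$name), ]; b <- b[order(b$name), ]
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$distance_x, b$distance_x)
})

test_that("scoring applies the tail probability and strict threshold", {
  m <- baseline_model()
  fr <- data.frame(name = c("near", "far", "onAnchor"),
                   chrom = "chr1",
                   start = c(1, 1, 1), end = c(10, 10, 10),
                   center = c(0, 0, 0),
                   distance_x = c(1117, 5000, 0))
  sc <- score_fragments(fr, m)
  expect_true(sc$retained[sc$name == "near"])     # tail ~ 0.538 > 0.3
  expect_false(sc$retained[sc$name == "far"])     # tail ~ 0.128 < 0.3
  expect_equal(sc$probability[sc$name == "onAnchor"], 1)  # clamped to x_min
  expect_equal(sc$probability[sc$name == "near"], 0.5382826607,
               tolerance = 1e-7)

  near_one <- baseline_model(threshold = 1 - 1e-9)
  sc2 <- score_fragments(fr, near_one)
  expect_equal(sc2$retained, c(FALSE, FALSE, TRUE))
})

test_that("equidistant fragments on opposite sides score identically", {
  m <- baseline_model()
  anchor <- anchor_point("chr1", 10000, 9990, 10010)
  fr <- data.frame(name = c("left", "right"), chrom = "chr1",
                   start = c(8800, 11000), end = c(9000, 11200),
                   center = c(8900, 11100),
                   distance_x = c(1100, 1100))
  sc <- score_fragments(fr, m)
  expect_equal(sc$probability[1], sc$probability[2])
  expect_equal(sc$retained[1], sc$retained[2])
})

test_that("span estimation performs the interval arithmetic by hand", {
  anchor <- anchor_point("chr1", 9999, 9925, 10073, "+")
  sc <- data.frame(name = c("a", "b"), chrom = "chr1",
                   start = c(9000, 10200), end = c(9150, 10336),
                   center = c(9075, 10268), distance_x = c(924, 269),
                   probability = c(0.6, 0.9), retained = c(TRUE, TRUE))
  est <- estimate_extension(anchor, sc)
  expect_equal(est$span_start, 9000)
  expect_equal(est$span_end, 10336)
  expect_equal(est$ext_left, 925)
  expect_equal(est$ext_right, 263)
  expect_equal(est$total_extension, 1188)
  expect_equal(est$full_length, 1337)
  expect_equal(est$ext_5p, 925)   # plus strand: 5' is left
  expect_equal(est$ext_3p, 263)

  minus <- estimate_extension(anchor_point("chr1", 9999, 9925, 10073, "-"), sc)
  expect_equal(minus$ext_5p, 263)
  expect_equal(minus$ext_3p, 925)
  expect_true(minus$strand_resolved)

  unk <- estimate_extension(anchor_point("chr1", 9999, 9925, 10073, "*"), sc)
  expect_false(unk$strand_resolved)

  none <- estimate_extension(anchor, sc[0, ])
  expect_equal(none$full_length, 10073 - 9925 + 1)
  expect_equal(none$total_extension, 0)
})

test_that("span always contains the model span and extensions stay non-negative", {
  set.seed(31)
  m <- baseline_model()
  for (i in 1:25) {
    ms <- sample(5000:6000, 1); me <- ms + sample(100:300, 1)
    anchor <- anchor_point("chr1", floor((ms + me) / 2), ms, me,
                           sample(c("+", "-", "*"), 1))
    n <- sample(0:15, 1)
    st <- sample(1:12000, n)
    fr <- data.frame(name = sprintf("f%d", seq_len(n)),
                     chrom = rep("chr1", n),
                     start = st, end = st + sample(50:400, n, replace = TRUE))
    fr$center <- floor((fr$start + fr$end) / 2)
    fr$distance_x <- abs(fr$center - anchor$center)
    est <- estimate_extension(anchor, score_fragments(fr, m))
    expect_lte(est$span_start, anchor$model_start)
    expect_gte(est$span_end, anchor$model_end)
    expect_gte(est$ext_left, 0)
    expect_gte(est$ext_right, 0)
    expect_equal(est$total_extension, est$ext_left + est$ext_right)
    expect_equal(est$full_length, est$span_end - est$span_start + 1)
  }
})

test_that("tightening the threshold shrinks the retained set and the span", {
  set.seed(77)
  anchor <- anchor_point("chr1", 10000, 9950, 10050)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    st <- sample(3000:17000, n)
    fr <- data.frame(name = sprintf("f%d", seq_len(n)), chrom = "chr1",
                     start = st, end = st + sample(50:300, n, replace = TRUE))
    fr$center <- floor((fr$start + fr$end) / 2)
    fr$distance_x <- abs(fr$center - anchor$center)
    t1 <- runif(1, 0.05, 0.5); t2 <- runif(1, t1, 0.95)
    s1 <- score_fragments(fr, baseline_model(threshold = t1))
    s2 <- score_fragments(fr, baseline_model(threshold = t2))
    expect_true(all(s2$name[s2$retained] %in% s1$name[s1$retained]))
    e1 <- estimate_extension(anchor, s1)
    e2 <- estimate_extension(anchor, s2)
    expect_lte(e2$full_length, e1$full_length)
  }
})

test_that("retention and span match an exhaustive per-fragment recomputation", {
  set.seed(53)
  m <- baseline_model()
  anchor <- anchor_point("chr1", 10000, 9950, 10050)
  n <- 20
  st <- sample(4000:16000, n)
  fr <- data.frame(name = sprintf("f%d", seq_len(n)), chrom = "chr1",
                   start = st, end = st + sample(50:300, n, replace = TRUE))
  fr$center <- floor((fr$start + fr$end) / 2)
  fr$distance_x <- abs(fr$center - anchor$center)
  sc <- score_fragments(fr, m)
  # oracle: evaluate the integration tail per fragment independently
  keep <- vapply(seq_len(n), function(i) {
    x <- max(fr$distance_x[i], 1)
    tail_integral_oracle(x, 0.594, 1, 6932) > 0.3
  }, logical(1L))
  expect_equal(sc$retained, keep)
  est <- estimate_extension(anchor, sc)
  expect_equal(est$span_start, min(c(9950, fr$start[keep])))
  expect_equal(est$span_end, max(c(10050, fr$end[keep])))
})

test_that("span sequences are extracted and strand-resolved", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrM", "ACGTTTAGGA"), fa)
  est <- structure(list(
    anchor = anchor_point("chrM", 2, 1, 4, "+"),
    span_start = 1, span_end = 4), class = "extension_estimate")
  s <- extract_span_sequence(fa, est)
  expect_equal(as.character(s[[1L]]), "ACGT")
  expect_equal(names(s), "chrM:1-4(+)")

  est$anchor <- anchor_point("chrM", 2, 1, 4, "-")
  expect_equal(as.character(extract_span_sequence(fa, est)[[1L]]), "ACGT")

  est$span_end <- 999
  expect_error(extract_span_sequence(fa, est), "outside chromosome bounds")
})

test_that("the planted transcript's length is recovered within one fragment length", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, decoy_count = 10L)
    loc <- make_planted_locus(cfg, tempfile())
    tr <- loc$truth
    anchor <- anchor_point(tr$chrom, tr$anchor_center, tr$model_start,
                           tr$model_end, "+")
    m <- baseline_model()
    sc <- score_fragments(
      collect_fragments(loc$paths$fragments_sam, anchor, window = 2 * 6932), m)
    est <- estimate_extension(anchor, sc)
    expect_lt(abs(est$full_length - tr$transcript_length),
              cfg$fragment_length_mean)
    # decoys sit beyond the model support and must all be dropped
    expect_equal(sum(sc$retained), cfg$fragment_count)
    expect_true(all(grepl("^decoy", sc$name[!sc$retained])))
    expect_true(all(sc$probability[!sc$retained] == 0))
    # the extracted sequence is exactly the planted genomic subsequence
    genome <- Biostrings::readDNAStringSet(loc$paths$genome)
    expected <- Biostrings::subseq(genome[[1L]], est$span_start, est$span_end)
    got <- extract_span_sequence(loc$paths$genome, est)
    expect_equal(as.character(got[[1L]]), as.character(expected))
  }
})
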