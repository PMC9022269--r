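make_hit <- function(qstart, qend, sstart = 1L, sseqid = "locus",
                     minus = FALSE) {
  data.frame(
    qseqid = "q", sseqid = sseqid, pident = 100, length = qend - qstart + 1L,
    mismatch = 0L, gapopen = 0L, qstart = qstart, qend = qend,
    sstart = sstart, send = sstart + (qend - qstart), score = 2 * (qend - qstart + 1L),
    minus = minus, stringsAsFactors = FALSE
  )
}

test_that("anchoring filters implement the 10-bp tether-tail and subject-head windows", {
  tf <- tf_like_model()
  q <- build_extended_query(tf, 11)
  lq <- nchar(q$sequence)
  cfg <- filter_config()

  # ideal full-length locus
  f <- filter_hits(make_hit(100L, lq, sstart = 1L), q, cfg)
  expect_true(f$pass)
  # boundary: the last 10 bases are positions lq-9 ... lq
  expect_true(filter_hits(make_hit(100L, lq - 9L), q, cfg)$pass)
  f2 <- filter_hits(make_hit(100L, lq - 10L), q, cfg)
  expect_false(f2$pass)
  expect_equal(f2$reason, "tether-3'-truncated")
  # subject head window: sstart 10 passes, 11 fails
  expect_true(filter_hits(make_hit(100L, lq, sstart = 10L), q, cfg)$pass)
  f3 <- filter_hits(make_hit(100L, lq, sstart = 11L), q, cfg)
  expect_false(f3$pass)
  expect_equal(f3$reason, "not-5'-anchored")
  # minus orientation rejected outright
  f4 <- filter_hits(make_hit(100L, lq, minus = TRUE), q, cfg)
  expect_equal(f4$reason, "minus-orientation")
})

test_that("shrinking either window never admits a previously rejected hit", {
  tf <- tf_like_model()
  q <- build_extended_query(tf, 11)
  lq <- nchar(q$sequence)
  set.seed(12)
  hits <- do.call(rbind, lapply(1:50, function(i) {
    make_hit(
      sample(lq - 30L, 1), sample((lq - 30L):lq, 1),
      sstart = sample(1:30, 1), sseqid = sprintf("l%d", i)
    )
  }))
  wide <- filter_hits(hits, q, filter_config(10, 10))
  for (w in c(1, 3, 7)) {
    narrow <- filter_hits(hits, q, filter_config(w, w))
    expect_true(all(!wide$pass | !narrow$pass | narrow$pass))
    expect_true(all(narrow$pass <= wide$pass)) # narrowing only removes
  }
})

test_that("start calls bin loci and compute fractional monomer counts", {
  tf <- tf_like_model() # M3 is 212 bp in the extended query
  q <- build_extended_query(tf, 11)
  lq <- nchar(q$sequence)
  p_m3 <- query_position(q, "M3", 1L)
  hits <- rbind(
    make_hit(p_m3, lq, sseqid = "full_m3"),
    make_hit(p_m3 + 82L, lq, sseqid = "hotspot83"),
    make_hit(query_position(q, "T", 3L), lq, sseqid = "tether_start"),
    make_hit(query_position(q, "M11", 5L), lq, sseqid = "deep")
  )
  hits <- filter_hits(hits, q, filter_config())
  calls <- call_start(hits, q)
  expect_equal(calls$bin, c("M3", "M3", "T", "M11+"))
  expect_equal(calls$offset, c(1L, 83L, 3L, 5L))
  expect_equal(calls$monomer_count[1], 3.0)
  expect_equal(calls$monomer_count[2], 2 + (212 - 83 + 1) / 212) # 2.613
  expect_equal(calls$monomer_count[3], 0)
  expect_gt(calls$monomer_count[4], 10)
  expect_equal(calls$averaged, c(TRUE, TRUE, FALSE, FALSE))

  unfiltered <- make_hit(p_m3, lq)
  expect_error(call_start(unfiltered, q), "contract violation")
})

test_that("pattern deduplication keeps each locus under the highest-precedence pattern", {
  call_row <- function(id, pattern) {
    data.frame(
      locus_id = id, pattern_id = pattern, bin = "M2", offset = 1L,
      monomer_count = 2, averaged = TRUE, stringsAsFactors = FALSE
    )
  }
  calls <- rbind(
    call_row("a", "I"), call_row("a", "II"),
    call_row("b", "IV"),
    call_row("c", "I"), call_row("c", "II"), call_row("c", "IV")
  )
  dd <- dedup_patterns(calls, precedence = c("II", "I", "IV"))
  expect_equal(nrow(dd), 3L)
  expect_equal(dd$pattern_id[dd$locus_id == "a"], "II")
  expect_equal(dd$pattern_id[dd$locus_id == "b"], "IV")
  expect_equal(dd$pattern_id[dd$locus_id == "c"], "II")
  expect_error(dedup_patterns(calls, precedence = c("II", "I")), "invalid config")
})

test_that("census partitions loci over bins, applies exclusions and builds histograms", {
  call_row <- function(id, bin, offset, count, averaged = TRUE) {
    data.frame(
      locus_id = id, pattern_id = "default", bin = bin, offset = offset,
      monomer_count = count, averaged = averaged, stringsAsFactors = FALSE
    )
  }
  calls <- rbind(
    call_row("a", "M2", 1L, 2.0),
    call_row("b", "M3", 83L, 2.61),
    call_row("c", "M3", 83L, 2.61),
    call_row("d", "T", 5L, 0, averaged = FALSE),
    call_row("e", "M11+", 2L, 10.99, averaged = FALSE)
  )
  cen <- census(calls, "Sim")
  expect_equal(cen$total, 5L)
  expect_equal(sum(cen$bin_table$count), cen$total) # partition
  expect_equal(cen$bin_table$count[cen$bin_table$bin == "M3"], 2L)
  # average excludes T and M11+
  expect_equal(cen$avg_monomers, mean(c(2.0, 2.61, 2.61)))
  expect_equal(cen$n_excluded, 2L)
  # >= 2 intact monomers: a (offset 1 of M2), b, c, e
  expect_equal(cen$cumulative$count[cen$cumulative$k == 2], 4L)
  expect_equal(cen$cumulative$pct[cen$cumulative$k == 2], 80.0)
  expect_equal(as.integer(cen$offset_hist$M3["83"]), 2L)

  single <- census(call_row("z", "M2", 1L, 2.0), "One")
  expect_equal(single$avg_monomers, 2.0)
  expect_equal(single$bin_table$pct[single$bin_table$bin == "M2"], 100.0)

  empty <- census(calls[0, , drop = FALSE], "Empty")
  expect_equal(empty$total, 0L)
  expect_true(all(is.na(empty$bin_table$pct)))
})

test_that("percentages are rounded half away from zero to one decimal", {
  expect_equal(percent(3515, 5765), 61.0)
  expect_equal(percent(26, 157), 16.6)
  expect_equal(percent(0, 100), 0.0)
  expect_equal(percent(1, 1600), 0.1) # 0.0625 -> 0.1
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_error(percent(1, 0), "denominator")
})

test_that("pairwise identity counts identical columns over all columns", {
  a50 <- random_seq(50)
  expect_equal(pairwise_identity(a50, a50)$percent, 100.0)
  # 180 identical of 208 columns -> 86.5
  a <- paste(rep("A", 208), collapse = "")
  b <- paste(c(rep("A", 180), rep("C", 20), rep("-", 8)), collapse = "")
  id <- pairwise_identity(a, b)
  expect_equal(id$identical, 180L)
  expect_equal(id$columns, 208L)
  expect_equal(id$percent, 86.5)
  # gap columns compare but never match, even gap-vs-gap
  expect_equal(pairwise_identity("A-G", "A-G")$identical, 2L)
  expect_error(pairwise_identity("ACGT", "ACG"), "equal length")
})

test_that("age regression matches the closed-form normal-equations oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    x <- sort(runif(n, 0.1, 3))
    y <- 4 - x + rnorm(n, 0, 0.3)
    got <- age_regression(x, y)
    ref <- ols_oracle(x, y)
    expect_equal(got$slope, ref$slope)
    expect_equal(got$intercept, ref$intercept)
    expect_equal(got$r, ref$r)
    expect_equal(got$p, ref$p)
    # p is consistent with t = r*sqrt(n-2)/sqrt(1-r^2)
    tstat <- got$r * sqrt(n - 2) / sqrt(1 - got$r^2)
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2))
  }
  # perfectly collinear decreasing points (lm warns about the exact fit)
  col <- suppressWarnings(age_regression(c(1, 2, 3, 4), c(8, 6, 4, 2)))
  expect_equal(col$r, -1)
  expect_lt(col$p, 1e-12)
  expect_error(age_regression(c(1, 2), c(1, 2)), "insufficient")
  expect_error(age_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})
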