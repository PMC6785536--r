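write_probe_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  base <- data.frame(
    ProbeName = sprintf("P%03d", seq_len(nrow(df))),
    SystematicName = sprintf("%s:%d-%d", df$chrom, df$start, df$end),
    LogRatio = df$LogRatio,
    gIsFeatNonUnifOL = df$g1 %||% 0L, rIsFeatNonUnifOL = df$g2 %||% 0L,
    gIsSaturated = df$g3 %||% 0L, rIsSaturated = df$g4 %||% 0L)
  write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("probe loading converts log ratios and applies QC removal", {
  df <- data.frame(chrom = "chr1", start = (1:5) * 1000L,
                   end = (1:5) * 1000L + 59L,
                   LogRatio = c(0.30103, -0.30103, 0, 0.1, 0.2),
                   g1 = c(0L, 0L, 0L, 1L, 0L))
  ps <- load_probes(write_probe_tsv(df))
  # raw log10(ref/tumor) 0.30103 -> log2(tumor/ref) = -1; flagged and
  # zero-ratio probes are gone
  expect_equal(nrow(ps), 3)
  expect_equal(ps$log2ratio[1], -1, tolerance = 1e-5)
  expect_equal(ps$log2ratio[2], 1, tolerance = 1e-5)
  expect_false(any(ps$start == 4000))

  # 100 probes, 7 flagged -> 93 retained
  withr::with_seed(3, {
    df2 <- data.frame(chrom = "chr1", start = (1:100) * 1000L,
                      end = (1:100) * 1000L + 59L,
                      LogRatio = rnorm(100, 0, 0.1),
                      g1 = as.integer(seq_len(100) %in% sample(100, 7)))
  })
  expect_equal(nrow(load_probes(write_probe_tsv(df2))), 93)

  bad <- write_probe_tsv(df)
  tab <- readLines(bad)
  writeLines(sub("0.30103", "abc", tab, fixed = TRUE), bad)
  expect_error(load_probes(bad), "line 2")
  p3 <- tempfile(); writeLines("ProbeName\tLogRatio", p3)
  expect_error(load_probes(p3), "missing columns")
})

test_that("DLRS recovers iid noise and scales correctly", {
  expect_equal(dlrs(rep(0.3, 100)), 0)
  expect_error(dlrs(c(1, 2)), "at least 3")
  withr::with_seed(11, x <- rnorm(1e5, 0, 0.2))
  expect_equal(dlrs(x), 0.2, tolerance = 0.02)
  expect_equal(dlrs(2 * x), 2 * dlrs(x), tolerance = 1e-12)
  expect_equal(dlrs(-x), dlrs(x), tolerance = 1e-12)
  # ProbeSet method: probe-count-weighted median over chromosomes
  ps <- level_probes(list(chr1 = rep(0, 200), chr2 = rep(0, 50)),
                     noise_sd = 0.1, seed = 4)
  d <- dlrs(ps)
  expect_equal(d, 0.1, tolerance = 0.25)
})

test_that("UNDO.SD ties the undo threshold to the 0.25 cutoff", {
  withr::with_seed(11, x <- rnorm(1e5, 0, 0.2))
  expect_equal(undo_sd_param(x), 0.25 / dlrs(x))
  expect_error(undo_sd_param(rep(0, 10)), "zero")
})

test_that("all three segmenters recover a noiseless step exactly", {
  ps <- level_probes(list(chr1 = rep(c(0, 1), each = 50)))
  for (seg in list(segment_cbs(ps, seed = 1), segment_haar(ps),
                   segment_dp(ps))) {
    expect_equal(nrow(seg), 2)
    expect_equal(seg$last[1], 50)
    expect_equal(seg$mean, c(0, 1))
  }
})

test_that("constant signal yields a single segment per chromosome", {
  ps <- level_probes(list(chr1 = rep(0.1, 60), chr2 = rep(-0.2, 40)))
  for (seg in list(segment_cbs(ps, seed = 1), segment_haar(ps),
                   segment_dp(ps))) {
    expect_equal(nrow(seg), 2)
    expect_equal(seg$chrom, c("chr1", "chr2"))
  }
  # dp with infinite penalty degenerates to one segment regardless of signal
  ps2 <- level_probes(list(chr1 = rep(c(0, 1), each = 30)))
  expect_equal(nrow(segment_dp(ps2, penalty = 1e9)), 1)
})

test_that("segmentations partition probes and report member means", {
  ps <- level_probes(list(chr1 = rep(c(0, 0.6, 0), c(30, 10, 30)),
                          chr2 = rep(0, 25)), noise_sd = 0.15, seed = 8)
  for (seg in list(segment_cbs(ps, seed = 2), segment_haar(ps),
                   segment_dp(ps))) {
    covered <- unlist(mapply(seq.int, seg$first, seg$last, SIMPLIFY = FALSE))
    expect_equal(sort(covered), seq_len(nrow(ps)))
    for (i in seq_len(nrow(seg))) {
      expect_equal(seg$mean[i],
                   mean(ps$log2ratio[seg$first[i]:seg$last[i]]),
                   tolerance = 1e-12)
    }
  }
  expect_error(segmentation("x", c(1, 10), c(8, 65), ps), "partition")
})

test_that("the consensus rule enforces probes, threshold and support", {
  # 4-probe event at +0.50 with all methods agreeing: still normal
  ps1 <- level_probes(list(chr1 = rep(c(0, 0.5, 0), c(13, 4, 13))))
  s_all <- seg_from_breaks(ps1, c(13, 17))
  cc1 <- consensus_calls(s_all, s_all, s_all, ps1)
  expect_true(all(cc1$status == "normal"))

  # 10 probes at +0.30 supported by 2 of 3 methods: gain
  ps2 <- level_probes(list(chr1 = rep(c(0.30, 0), c(10, 15))))
  s_a <- seg_from_breaks(ps2, 10)
  s_none <- seg_from_breaks(ps2, integer(0))
  cc2 <- consensus_calls(s_a, s_a, s_none, ps2)
  expect_equal(cc2$status[1], "gain")
  expect_equal(cc2$support[1], "manual,manual")

  # 10 probes at -0.26 supported by only 1 method: normal
  ps3 <- level_probes(list(chr1 = rep(c(0, -0.26, 0), c(15, 10, 15))))
  s_b <- seg_from_breaks(ps3, c(15, 25))
  cc3 <- consensus_calls(s_none2 <- seg_from_breaks(ps3, integer(0)),
                         s_none2, s_b, ps3)
  expect_true(all(cc3$status == "normal"))

  # mismatched probe universes are rejected
  expect_error(consensus_calls(s_a, s_a, s_b, ps2), "universe")
})

test_that("aberrant calls always satisfy the rule; support is monotone", {
  for (seed in 1:4) {
    ps <- level_probes(list(chr1 = rep(c(0, 0.6, 0, -0.7, 0),
                                       c(20, 8, 20, 12, 20))),
                       noise_sd = 0.15, seed = seed)
    cc <- consensus_calls(segment_cbs(ps, seed = seed), segment_haar(ps),
                          segment_dp(ps), ps)
    ab <- cc[cc$status != "normal", ]
    if (nrow(ab)) {
      expect_true(all(ab$n_probes >= 5))
      expect_true(all(abs(ab$mean_log2) > 0.25))
      expect_true(all(lengths(strsplit(ab$support, ",")) >= 2))
    }
    cc3 <- consensus_calls(segment_cbs(ps, seed = seed), segment_haar(ps),
                           segment_dp(ps), ps, min_support = 3)
    expect_lte(sum(cc3$status != "normal"), sum(cc$status != "normal"))
  }
})

test_that("reports annotate calls with overlapping genes", {
  ps <- level_probes(list(chr1 = rep(c(0, 0.6, 0, -0.7, 0),
                                     c(10, 8, 10, 8, 10))))
  s <- seg_from_breaks(ps, c(10, 18, 28, 36))
  cc <- consensus_calls(s, s, s, ps)
  genes <- transcript_annotation(data.frame(
    chrom = "chr1",
    start = c(500, 12000, 17500, 30500, 40000),
    end = c(900, 12800, 19000, 33000, 41000),
    gene = paste0("G", 1:5),
    strand = "+", stringsAsFactors = FALSE))
  rep1 <- report_calls(cc, genes)
  expect_equal(nrow(rep1), 2)
  # brute-force overlap oracle
  for (i in seq_len(nrow(rep1))) {
    expected <- sort(genes$gene[genes$start <= rep1$end[i] &
                                  genes$end >= rep1$start[i]])
    got <- strsplit(rep1$genes[i], ",")[[1]]
    expect_equal(got, expected)
  }
  # no aberrant regions -> empty report
  ps0 <- level_probes(list(chr1 = rep(0, 30)))
  s0 <- seg_from_breaks(ps0, integer(0))
  expect_equal(nrow(report_calls(consensus_calls(s0, s0, s0, ps0), genes)), 0)
})

test_that("penetrance fractions count samples per atomic interval", {
  gain <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                    status = "gain")
  # identical gain in 4/4 samples
  p4 <- penetrance(rep(list(gain(100, 200)), 4))
  expect_equal(p4$fraction, 1.0)
  # 1 of 4 samples
  p1 <- penetrance(c(list(gain(100, 200)), rep(list(gain(900, 950)), 3)))
  expect_equal(p1$fraction[p1$start == 100], 0.25)
  # half-overlapping gains in 2 samples -> 50/100/50
  p2 <- penetrance(list(gain(100, 200), gain(150, 250)))
  expect_equal(p2$start, c(100, 150, 201))
  expect_equal(p2$end, c(149, 200, 250))
  expect_equal(p2$fraction, c(0.5, 1.0, 0.5))
  # fractions are always multiples of 1/n
  expect_true(all(abs(p1$fraction * 4 - round(p1$fraction * 4)) < 1e-12))
})
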