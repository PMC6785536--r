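test_that("trinucleotide context follows the pyrimidine convention", {
  g <- genome_sequence(c(chr1 = "AACAA", chr2 = "AAGTA"))
  # pyrimidine reference reported as-is
  r1 <- trinucleotide_context(g, "chr1", 3, "C", "A")
  expect_equal(r1$class, "C>A")
  expect_equal(r1$context, "ACA")
  # purine reference reverse-complemented: G>T in AGT -> C>A in ACT
  r2 <- trinucleotide_context(g, "chr2", 3, "G", "T")
  expect_equal(r2$class, "C>A")
  expect_equal(r2$context, "ACT")
  # N flank is skipped with a warning
  gn <- genome_sequence(c(chr1 = "ANCAA"))
  expect_warning(rn <- trinucleotide_context(gn, "chr1", 3, "C", "A"),
                 "skipped")
  expect_false(rn$ok)
  # genuine reference mismatch aborts
  expect_error(trinucleotide_context(g, "chr1", 3, "T", "A"), "mismatch")
})

test_that("profiles put unit mass in the right category and skip non-SBS", {
  g <- genome_sequence(c(chr1 = "AACAA"))
  p <- build_profile96(quick_catalog("chr1", 3, "C", "A"), g)
  expect_equal(p$n, 1)
  expect_equal(unname(p$counts[["A[C>A]A"]]), 1L)
  expect_equal(sum(profile_fractions(p)), 1)
  # indel-only catalog: all-zero profile
  p0 <- build_profile96(quick_catalog("chr1", 3, "C", "-"), g)
  expect_equal(p0$n, 0)
  expect_true(all(p0$counts == 0))
})

test_that("profiles are invariant to opposite-strand representation", {
  sim <- test_sim()
  cat1 <- sample_mutation_catalog(sim$genome, cisplatin_like_spectrum(),
                                  300, seed = 17)
  p1 <- build_profile96(cat1, sim$genome)
  flipped <- variant_catalog(within(as.data.frame(cat1), {
    ref <- comp(ref); alt <- comp(alt)
  }), sample_id = "flipped")
  p2 <- build_profile96(flipped, sim$genome)
  expect_identical(p1$counts, p2$counts)
})

test_that("cosine similarity matches its definition and invariants", {
  sim <- test_sim()
  cat1 <- sample_mutation_catalog(sim$genome, cisplatin_like_spectrum(),
                                  200, seed = 5)
  p <- build_profile96(cat1, sim$genome)
  expect_equal(cosine_similarity(p, p), 1.0)
  a <- c(1, 0, 0); b <- c(0, 1, 1)
  expect_equal(cosine_similarity(a, b), 0)
  expect_error(cosine_similarity(a, c(0, 0, 0)), "zero")
  # scale invariance
  q <- profile96(p$counts * 7L)
  expect_equal(cosine_similarity(p, q), 1.0)
  # 100 random pairs against the direct dot-product/norm formula
  withr::with_seed(12, {
    for (i in 1:100) {
      x <- rexp(96); y <- rexp(96)
      direct <- sum(x * y) / (sqrt(sum(x * x)) * sqrt(sum(y * y)))
      expect_equal(cosine_similarity(x, y), direct, tolerance = 1e-12)
      expect_gte(cosine_similarity(x, y), 0)
      expect_lte(cosine_similarity(x, y), 1)
    }
  })
})

test_that("class counts are the context marginal of the 96 profile", {
  ct <- quick_catalog("chr1", 3, "C", "T")
  expect_equal(unname(class_counts(ct)), c(0L, 0L, 1L, 0L, 0L, 0L))
  sim <- test_sim()
  cat1 <- sample_mutation_catalog(sim$genome, cisplatin_like_spectrum(),
                                  250, seed = 9)
  p <- build_profile96(cat1, sim$genome)
  marg <- vapply(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), function(cl)
    sum(p$counts[grepl(cl, names(p$counts), fixed = TRUE)]), integer(1))
  expect_equal(class_counts(cat1), marg)
  expect_equal(sum(class_counts(cat1)), sum(cat1$var_type == "SBS"))
})

test_that("strand assignment puts the pyrimidine on the template strand", {
  ann <- transcript_annotation(data.frame(
    chrom = "chr1", start = 100, end = 200, gene = "G1", strand = "+",
    stringsAsFactors = FALSE))
  v <- quick_catalog("chr1", 150, "C", "T")
  # gene on +: template strand is -, pyrimidine sits on + -> nontranscribed
  sc <- stranded_class_counts(v, ann)
  expect_equal(unname(sc$counts["C>T", "nontranscribed"]), 1L)
  expect_equal(sum(sc$counts), 1L)
  # gene on -: same variant is on the template -> transcribed
  ann2 <- transcript_annotation(transform(as.data.frame(ann), strand = "-"))
  sc2 <- stranded_class_counts(v, ann2)
  expect_equal(unname(sc2$counts["C>T", "transcribed"]), 1L)
  # overlapping genes on opposite strands -> excluded
  ann3 <- transcript_annotation(data.frame(
    chrom = "chr1", start = c(100, 120), end = c(200, 220),
    gene = c("G1", "G2"), strand = c("+", "-"), stringsAsFactors = FALSE))
  sc3 <- stranded_class_counts(v, ann3)
  expect_equal(sc3$excluded, 1L)
  expect_equal(sum(sc3$counts), 0L)
  # intergenic -> excluded; totals always reconcile
  v2 <- quick_catalog("chr1", c(150, 500), c("C", "G"), c("T", "A"))
  sc4 <- stranded_class_counts(v2, ann)
  expect_equal(sum(sc4$counts) + sc4$excluded, 2L)
})

test_that("single-base deletion flanks are recorded as unordered pairs", {
  #          123456789012345
  g <- genome_sequence(c(chr1 = "AGACGTCCGTACGCA"))
  # deletions at pos with flanks: 3(G,C) 6(G,C) 8(C,G) 11(T,C) 13(C,C) 5(C,T)
  d <- quick_catalog("chr1", c(3, 6, 8, 11, 13, 5),
                     substring("AGACGTCCGTACGCA", c(3, 6, 8, 11, 13, 5),
                               c(3, 6, 8, 11, 13, 5)),
                     rep("-", 6))
  fc <- deletion_flank_counts(d, g)
  expect_equal(fc$total, 6)
  expect_equal(unname(fc$counts[["C/G"]]), 3L)
  expect_equal(unname(fc$counts[["C/T"]]), 2L)
  expect_equal(unname(fc$counts[["C/C"]]), 1L)
  # only single-base deletions count; flankless positions are skipped
  g2 <- genome_sequence(c(chr1 = "ACGT"))
  d2 <- quick_catalog("chr1", c(1, 3), c("A", "G"), c("-", "-"))
  expect_warning(fc2 <- deletion_flank_counts(d2, g2), "skipped")
  expect_equal(fc2$total, 1)
})

test_that("profile TSV round trip preserves counts", {
  sim <- test_sim()
  p <- build_profile96(sample_mutation_catalog(sim$genome,
                                               cisplatin_like_spectrum(),
                                               150, seed = 2), sim$genome)
  f <- tempfile(fileext = ".tsv")
  write_profile96(p, f)
  back <- read_profile96(f)
  expect_equal(as.numeric(back$counts), as.numeric(p$counts))
  expect_equal(cosine_similarity(p, back), 1.0)
})
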