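test_that("ANNOVAR-style tables are read, normalized and typed", {
  cat12 <- read_variants(fixture_annovar_path(), dialect = "annovar_tsv")
  expect_s3_class(cat12, "VariantCatalog")
  expect_equal(nrow(cat12), 12)
  # positional order within and across chromosomes
  expect_equal(order(chrom_rank(cat12$chrom), cat12$pos), seq_len(12))
  expect_equal(as.vector(table(cat12$var_type)[c("SBS", "DBS", "INS", "DEL")]),
               c(7L, 1L, 2L, 2L))
  expect_equal(cat12$func_class[cat12$chrom == "chr1" & cat12$pos == 100],
               "nonsynonymous")
  expect_equal(cat12$func_class[cat12$chrom == "chr2" & cat12$pos == 150],
               "intronic")
  expect_equal(cat12$func_class[cat12$chrom == "chr2" & cat12$pos == 100],
               "UTR")
})

test_that("header-only input yields an empty catalog; bad input errors", {
  p <- tempfile()
  writeLines("Chr\tStart\tEnd\tRef\tAlt", p)
  expect_equal(nrow(read_variants(p, "annovar_tsv")), 0)
  writeLines(c("Chr\tStart\tEnd\tRef\tAlt", "chr1\toops\t5\tA\tC"), p)
  expect_error(read_variants(p, "annovar_tsv"), "line 2")
  expect_error(read_variants(tempfile(), "annovar_tsv"), "no such file")
})

test_that("VCF records are split, trimmed and validated", {
  cat3 <- read_variants(fixture_vcf_path(), dialect = "vcf")
  expect_equal(nrow(cat3), 4)  # one multi-allelic record split in two
  expect_equal(cat3$vaf[cat3$pos == 200], c(0.4, 0.2))
  del <- cat3[cat3$var_type == "DEL", ]
  # anchored "AT>A" becomes a pure single-base deletion at the T
  expect_equal(del$pos, 301)
  expect_equal(del$ref, "T")
  expect_equal(del$alt, "-")
  expect_equal(cat3$gene[cat3$pos == 100], "G1")
  bad <- fixture_vcf_path(extra = "chr1\t400\t.\tA\tA\t.\t.\tAF=0.2")
  expect_error(read_variants(bad, "vcf"), "ref == alt")
})

test_that("indels left-align against a reference genome", {
  g <- genome_sequence(c(chr1 = "ACGTTTTTACGT"))
  # deleting any T of the homopolymer normalizes to the leftmost T
  cat_del <- variant_catalog(
    data.frame(chrom = "chr1", pos = 7, ref = "T", alt = "-", vaf = 1),
    genome = g)
  expect_equal(cat_del$pos, 4)
  cat_ins <- variant_catalog(
    data.frame(chrom = "chr1", pos = 8, ref = "-", alt = "T", vaf = 1),
    genome = g)
  expect_equal(cat_ins$pos, 4)
})

test_that("parental subtraction returns exactly the unshared keys", {
  treated <- quick_catalog("chr1", c(10, 20, 30, 40, 50),
                           c("A", "C", "G", "T", "A"),
                           c("T", "G", "A", "C", "G"))
  parental <- quick_catalog("chr1", c(20, 40, 99),
                            c("C", "T", "A"), c("G", "C", "T"))
  out <- subtract_parental(treated, parental)
  expect_equal(out$pos, c(10, 30, 50))
  expect_equal(nrow(subtract_parental(treated, treated)), 0)
  empty <- quick_catalog(character(0), integer(0), character(0), character(0),
                         vaf = numeric(0))
  expect_equal(as.data.frame(subtract_parental(treated, empty)),
               as.data.frame(treated))
})

test_that("subtraction partitions the treated catalog (property)", {
  sim <- test_sim()
  for (seed in 1:3) {
    pair <- make_parental_pair(sim$genome, 60, flat_spectrum(), 25, seed = seed)
    novel <- subtract_parental(pair$treated, pair$parental)
    shared_keys <- intersect(
      with(pair$treated, paste(chrom, pos, ref, alt, sep = ":")),
      with(pair$parental, paste(chrom, pos, ref, alt, sep = ":")))
    reunion <- sort(c(with(novel, paste(chrom, pos, ref, alt, sep = ":")),
                      shared_keys))
    expect_equal(reunion,
                 sort(with(pair$treated, paste(chrom, pos, ref, alt, sep = ":"))))
  }
})

test_that("VAF filter is boundary-inclusive, idempotent and monotone", {
  cat10 <- quick_catalog("chr1", 1:10, rep("A", 10), rep("C", 10),
                         vaf = c(0.09, 0.10, 0.05, 0.5, 0.02, 0.8,
                                 0.099, 0.3, 1.0, 0.11))
  kept <- filter_min_vaf(cat10)
  expect_equal(nrow(kept), 6)
  expect_true(all(kept$vaf >= 0.10))
  expect_equal(as.data.frame(filter_min_vaf(kept)), as.data.frame(kept))
  # monotone: a higher threshold keeps a subset
  k2 <- filter_min_vaf(cat10, 0.3)
  expect_true(all(k2$pos %in% kept$pos))
  # empty in, empty out
  empty <- quick_catalog(character(0), integer(0), character(0), character(0),
                         vaf = numeric(0))
  expect_equal(nrow(filter_min_vaf(empty)), 0)
  # missing VAF is an error naming the key
  na_cat <- quick_catalog("chr1", 5, "A", "C", vaf = NA_real_)
  expect_error(filter_min_vaf(na_cat), "chr1:5:A:C")
})

test_that("adjacent SNVs merge into DBS/MBS under the VAF tolerance", {
  cat_dbs <- quick_catalog("chr1", c(100, 101), c("A", "C"), c("T", "G"),
                           vaf = c(0.50, 0.52))
  m <- merge_adjacent_snvs(cat_dbs)
  expect_equal(nrow(m), 1)
  expect_equal(m$var_type, "DBS")
  expect_equal(m$pos, 100)
  expect_equal(m$ref, "AC")
  expect_equal(m$vaf, 0.51)

  cat_gap <- quick_catalog("chr1", c(100, 103), c("A", "C"), c("T", "G"))
  expect_equal(as.data.frame(merge_adjacent_snvs(cat_gap)),
               as.data.frame(cat_gap))

  cat_mbs <- quick_catalog("chr1", c(100, 101, 102), c("A", "C", "G"),
                           c("T", "G", "A"), vaf = c(0.5, 0.52, 0.49))
  m3 <- merge_adjacent_snvs(cat_mbs)
  expect_equal(m3$var_type, "MBS")
  expect_equal(nchar(m3$ref), 3)

  # VAFs too far apart: no merge
  cat_far <- quick_catalog("chr1", c(100, 101), c("A", "C"), c("T", "G"),
                           vaf = c(0.50, 0.70))
  expect_equal(nrow(merge_adjacent_snvs(cat_far)), 2)
})

test_that("catalog summary matches hand counts and conserves totals", {
  cat12 <- read_variants(fixture_annovar_path(), dialect = "annovar_tsv")
  s <- summarize_catalog(cat12)
  expect_equal(s$overall, 12)
  expect_equal(s$sbs, 7)
  expect_equal(s$dbs, 1)
  expect_equal(s$ins, 2)
  expect_equal(s$del, 2)
  expect_equal(s$single_base_del, 1)
  expect_equal(s$genes_hit, 6)
  expect_equal(s$nonsynonymous, 2)
  expect_equal(s$frameshift, 3)
  expect_equal(s$stopgain, 1)
  expect_equal(s$sbs + s$dbs + s$mbs + s$ins + s$del, s$overall)
  # conservation on random catalogs
  sim <- test_sim()
  for (seed in 1:3) {
    rc <- sample_mutation_catalog(sim$genome, flat_spectrum(), 80, seed = seed)
    ss <- summarize_catalog(rc)
    expect_equal(ss$sbs + ss$dbs + ss$mbs + ss$ins + ss$del, ss$overall)
    expect_lte(ss$genes_hit, ss$overall)
  }
  # empty catalog: all zeros
  s0 <- summarize_catalog(quick_catalog(character(0), integer(0),
                                        character(0), character(0),
                                        vaf = numeric(0)))
  expect_true(all(unlist(s0) == 0))
})

test_that("gene extraction honours the functional-impact filter", {
  cat3 <- quick_catalog("chr1", c(1, 2, 3), c("A", "C", "G"),
                        c("T", "G", "A"),
                        gene = c("A", "B", "B"),
                        func_class = c("synonymous", "nonsynonymous",
                                       "frameshift"))
  expect_equal(genes_with_mutations(cat3), c("A", "B"))
  expect_equal(genes_with_mutations(cat3, functional_only = TRUE), "B")
  syn <- quick_catalog("chr1", 1, "A", "T", gene = "A",
                       func_class = "synonymous")
  expect_equal(genes_with_mutations(syn, functional_only = TRUE), character(0))
})

test_that("Venn region counts agree with a brute-force oracle", {
  four <- replicate(4, paste0("G", 1:10), simplify = FALSE)
  names(four) <- paste0("L", 1:4)
  vc <- intersect_gene_sets(four)
  expect_equal(vc$count[vc$degree == 4], 10)
  expect_true(all(vc$count[vc$degree < 4] == 0))

  withr::with_seed(99, {
    universe <- paste0("G", 1:200)
    sets <- replicate(4, sample(universe, 50), simplify = FALSE)
  })
  names(sets) <- paste0("S", 1:4)
  vc <- intersect_gene_sets(sets)
  # oracle: per-gene membership patterns tabulated directly
  union_genes <- unique(unlist(sets))
  oracle <- table(vapply(union_genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
          collapse = "&")
  }, ""))
  for (i in seq_len(nrow(vc))) {
    expected <- if (vc$region[i] %in% names(oracle))
      as.integer(oracle[[vc$region[i]]]) else 0L
    expect_equal(vc$count[i], expected)
  }
  expect_equal(sum(vc$count), length(union_genes))
  expect_error(intersect_gene_sets(sets[1]), "between 2 and 6")
})

test_that("VAF histograms capture clonal structure", {
  clonal <- quick_catalog("chr1", 1:5, rep("A", 5), rep("C", 5), vaf = 1.0)
  vm <- vaf_matrix(list(clonal))
  expect_equal(unname(vm$counts[1, 10]), 5)
  expect_equal(unname(vm$clonal_fraction), 1.0)

  empty <- quick_catalog(character(0), integer(0), character(0), character(0),
                         vaf = numeric(0))
  vm0 <- vaf_matrix(list(empty))
  expect_true(all(vm0$counts == 0))

  # uniform VAFs land in each decile within a 99% multinomial band
  withr::with_seed(7, {
    u <- quick_catalog("chr1", 1:10000, rep("A", 10000), rep("C", 10000),
                       vaf = runif(10000))
  })
  vmu <- vaf_matrix(list(u))
  expected <- 10000 / 10
  band <- 2.58 * sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(vmu$counts - expected) <= band))

  expect_error(vaf_matrix(list(clonal), bins = seq(0.2, 1, 0.1)),
               "cover")
})

test_that("write/read round trip preserves the catalog key-for-key", {
  cat12 <- read_variants(fixture_annovar_path(), dialect = "annovar_tsv")
  p <- tempfile(fileext = ".tsv")
  write_variants(cat12, p)
  back <- read_variants(p, dialect = "annovar_tsv")
  expect_equal(as.data.frame(back)[c("chrom", "pos", "ref", "alt", "vaf",
                                     "gene", "func_class", "var_type")],
               as.data.frame(cat12)[c("chrom", "pos", "ref", "alt", "vaf",
                                      "gene", "func_class", "var_type")])
})
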