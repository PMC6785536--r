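# Fixtures are built in code at test time; nothing is read from disk that a
# test did not itself write.

comp <- function(x) chartr("ACGTN", "TGCAN", x)

# 12-record ANNOVAR-style table: 7 SBS, 1 DBS, 2 INS, 2 DEL (1 single-base)
fixture_annovar_lines <- function() {
  c("Chr\tStart\tEnd\tRef\tAlt\tFunc\tGene\tExonicFunc\tVAF\tDepth",
    "chr1\t100\t100\tA\tT\texonic\tGENE1\tnonsynonymous SNV\t0.95\t100",
    "chr1\t205\t205\tC\tG\texonic\tGENE1\tsynonymous SNV\t0.5\t80",
    "chr1\t300\t301\tAT\tGC\texonic\tGENE2\tunknown\t0.4\t70",
    "chr1\t400\t400\tG\t-\texonic\tGENE2\tframeshift deletion\t0.3\t60",
    "chr1\t500\t501\tCA\t-\texonic\tGENE3\tnonframeshift deletion\t0.9\t50",
    "chr1\t600\t600\t-\tTT\texonic\tGENE3\tframeshift insertion\t0.2\t40",
    "chr2\t100\t100\tT\tC\tUTR3\tGENE4\t.\t0.85\t90",
    "chr2\t150\t150\tG\tA\tintronic\tGENE4\t.\t0.15\t100",
    "chr2\t200\t200\tC\tA\texonic\tGENE5\tstopgain\t0.77\t110",
    "chr2\t250\t250\tT\tG\t.\t\t.\t0.06\t30",
    "chr2\t300\t300\t-\tG\texonic\tGENE5\tframeshift insertion\t0.55\t65",
    "chr2\t350\t350\tA\tC\texonic\tGENE6\tnonsynonymous SNV\t0.45\t75")
}

fixture_annovar_path <- function() {
  p <- tempfile(fileext = ".tsv")
  writeLines(fixture_annovar_lines(), p)
  p
}

fixture_vcf_path <- function(extra = character(0)) {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t.\t.\tAF=0.5;DP=80;GENE=G1;FUNC=nonsynonymous",
    "chr1\t200\t.\tG\tC,T\t.\t.\tAF=0.4,0.2;DP=100",
    "chr1\t300\t.\tAT\tA\t.\t.\tAF=1.0",
    extra), p)
  p
}

# small deterministic catalog built directly from fields
quick_catalog <- function(chrom, pos, ref, alt, vaf = 0.5, ...,
                          sample_id = "test") {
  variant_catalog(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                             vaf = vaf, ..., stringsAsFactors = FALSE),
                  sample_id = sample_id)
}

flat_spectrum <- function() profile96(rep(1, 96), label = "flat")

# shared small genome + annotation for spectrum tests
test_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_genome(sim_config(seed = 424, contigs = c(chr1 = 150000L,
                                                               chr2 = 80000L),
                                       n_genes = 8))
    }
    cache
  }
})

# probe set with per-chromosome piecewise-constant levels (1 kb spacing)
level_probes <- function(levels_by_chrom, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(names(levels_by_chrom), function(ch) {
      lv <- levels_by_chrom[[ch]]
      n <- length(lv)
      data.frame(chrom = ch, start = seq_len(n) * 1000L,
                 end = seq_len(n) * 1000L + 59L,
                 log2 = lv + rnorm(n, 0, noise_sd))
    })
    df <- do.call(rbind, rows)
    probe_set(df$chrom, df$start, df$end, df$log2)
  })
}

# segmentation from global break indices (last probe of each left segment)
seg_from_breaks <- function(probes, breaks, method = "manual") {
  cr <- mutsigcnv:::chrom_ranges(probes)
  breaks <- sort(unique(c(breaks, cr$last)))
  first <- c(1L, head(breaks, -1) + 1L)
  segmentation(method, first, breaks, probes)
}

# breakpoints (last index of left segment) of a Segmentation, per chromosome
breaks_of <- function(seg, probes) {
  cr <- mutsigcnv:::chrom_ranges(probes)
  setdiff(seg$last, cr$last)
}
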