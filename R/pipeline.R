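# Workflow wrappers: spectrum workflow (subtract -> filter -> merge ->
# summarize -> profile -> cosine), CNV workflow (load -> DLRS -> three
# segmentations -> consensus -> report -> penetrance) and simulation
# bundle writing. These compose the exported stage functions and write
# deterministic outputs; a thin command-line wrapper lives in
# inst/cli/mutsigcnv.R.

msg <- function(..., quiet = FALSE) if (!quiet) message("[mutsigcnv] ", ...)

#' Run the mutational-spectrum workflow
#'
#' Reads a treated (and optionally parental) variant table, subtracts
#' parental variants, applies the minimum-VAF filter, merges adjacent SNVs
#' into DBS/MBS events, summarizes the catalog, builds the 96-category
#' profile and, when a reference profile is given, reports the cosine
#' similarity to it. Writes `summary.tsv`, `summary.json`, `profile96.tsv`
#' and `spectrum.pdf` into `out_dir`.
#'
#' @param treated path to the treated line's variant table.
#' @param genome path to the reference FASTA, or a
#'   [GenomeSequence][read_genome].
#' @param parental optional path to the parental table; when omitted the
#'   treated catalog is taken as already subtracted (with a warning).
#' @param dialect variant-table dialect, see [read_variants()].
#' @param out_dir output directory (created if needed).
#' @param min_vaf inclusive VAF cutoff, default 0.10.
#' @param vaf_tol adjacent-SNV merging tolerance, default 0.05.
#' @param reference_profile optional path to a 96-row profile TSV (or a
#'   [profile96()]) to compare against.
#' @param quiet suppress progress messages.
#' @return list with `catalog`, `summary`, `profile`, `cosine` (or `NA`).
#' @export
run_spectrum <- function(treated, genome, parental = NULL,
                         dialect = "annovar_tsv", out_dir = ".",
                         min_vaf = 0.10, vaf_tol = 0.05,
                         reference_profile = NULL, quiet = FALSE) {
  for (p in c(treated, parental)) {
    if (is.character(p) && !file.exists(p)) stop("missing input: ", p)
  }
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("missing input: ", genome)
    genome <- read_genome(genome)
  }
  treated_cat <- read_variants(treated, dialect = dialect, genome = genome)
  if (!is.null(parental)) {
    parental_cat <- read_variants(parental, dialect = dialect, genome = genome)
    novel <- subtract_parental(treated_cat, parental_cat)
    msg(sprintf("subtracted parental: %d -> %d novel variants",
                nrow(treated_cat), nrow(novel)), quiet = quiet)
  } else {
    warning("no parental catalog supplied; treating input as already subtracted")
    novel <- treated_cat
  }
  novel <- filter_min_vaf(novel, min_vaf)
  novel <- merge_adjacent_snvs(novel, vaf_tol)
  summ <- summarize_catalog(novel)
  prof <- build_profile96(novel, genome)
  cosine <- NA_real_
  if (!is.null(reference_profile)) {
    ref <- if (inherits(reference_profile, "Profile96")) reference_profile
           else read_profile96(reference_profile)
    cosine <- cosine_similarity(prof, ref)
    msg(sprintf("cosine to reference profile '%s': %.4f", ref$label, cosine),
        quiet = quiet)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(summ), file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(unclass(summ), list(cosine_to_reference = cosine)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_profile96(prof, file.path(out_dir, "profile96.tsv"))
  grDevices::pdf(file.path(out_dir, "spectrum.pdf"), width = 10, height = 4)
  print(plot_profile96(prof))
  grDevices::dev.off()
  invisible(list(catalog = novel, summary = summ, profile = prof,
                 cosine = cosine))
}

#' Run the copy-number workflow
#'
#' For each probe file: load and QC-filter probes, estimate the DLRS, run
#' the three breakpoint detectors (CBS with `UNDO.SD = 0.25/DLRS`,
#' Haar-wavelet, penalized partitioning) and call consensus gains/losses.
#' With more than one sample, computes the cross-sample penetrance table
#' (probe universes must match). Writes `<sample>_calls.tsv` (BED-style)
#' and `cnv_report.json` per run, plus `penetrance.tsv` for multi-sample
#' runs.
#'
#' @param probe_paths character vector (ideally named by sample) of probe
#'   TSVs in the Agilent-subset dialect.
#' @param out_dir output directory.
#' @param genes optional gene annotation (BED path or
#'   [transcript_annotation()]).
#' @param min_probes,threshold,min_support consensus rule, see
#'   [consensus_calls()].
#' @param alpha,nperm CBS parameters.
#' @param fdr_q Haar FDR level.
#' @param penalty optional partitioning penalty override.
#' @param seed integer seed driving the CBS permutations.
#' @param quiet suppress progress messages.
#' @return list with per-sample `calls`/`reports`, `dlrs` values and
#'   `penetrance` (or `NULL`).
#' @export
run_cnv <- function(probe_paths, out_dir = ".", genes = NULL,
                    min_probes = 5, threshold = 0.25, min_support = 2,
                    alpha = 0.01, nperm = 1000, fdr_q = 0.001,
                    penalty = NULL, seed = 1L, quiet = FALSE) {
  missing <- probe_paths[!file.exists(probe_paths)]
  if (length(missing)) stop("missing input: ", paste(missing, collapse = ", "))
  nm <- names(probe_paths) %||%
    sub("\\.[^.]*$", "", basename(probe_paths))
  if (is.null(names(probe_paths))) names(probe_paths) <- nm
  if (is.character(genes)) genes <- read_gene_bed(genes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- list(); reports <- list(); dl <- numeric(0)
  for (s in names(probe_paths)) {
    probes <- load_probes(probe_paths[[s]])
    d <- dlrs(probes)
    dl[s] <- d
    msg(sprintf("%s: %d probes, DLRS %.4f", s, nrow(probes), d), quiet = quiet)
    seg1 <- segment_cbs(probes, alpha = alpha, nperm = nperm,
                        seed = seed + match(s, names(probe_paths)))
    seg2 <- segment_haar(probes, fdr_q = fdr_q)
    seg3 <- segment_dp(probes, penalty = penalty)
    cc <- consensus_calls(seg1, seg2, seg3, probes,
                          min_probes = min_probes, threshold = threshold,
                          min_support = min_support)
    rep <- report_calls(cc, genes)
    calls[[s]] <- cc
    reports[[s]] <- rep
    write_calls_bed(rep, file.path(out_dir, paste0(s, "_calls.tsv")))
    msg(sprintf("%s: %d aberrant region(s)", s, nrow(rep)), quiet = quiet)
  }
  pen <- NULL
  if (length(probe_paths) > 1) {
    sigs <- vapply(calls, attr, "", "probe_sig")
    if (length(unique(sigs)) != 1)
      stop("probe universes differ across samples; cannot compute penetrance")
    pen <- penetrance(calls)
    write.table(as.data.frame(pen), file.path(out_dir, "penetrance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(samples = names(probe_paths), dlrs = as.list(dl),
         n_aberrant = lapply(reports, nrow)),
    file.path(out_dir, "cnv_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(calls = calls, reports = reports, dlrs = dl,
                 penetrance = pen))
}

#' Simulate a full input bundle on disk
#'
#' Writes genome FASTA, gene BED, parental/treated variant TSVs, probe
#' TSVs (one per requested sample) and a JSON truth file, plus a manifest
#' with the seed and per-file MD5 checksums. Identical configuration
#' yields identical checksums.
#'
#' @param out_dir output directory; must be empty unless `force`.
#' @param config a [sim_config()].
#' @param spectrum novel-variant spectrum, default
#'   [cisplatin_like_spectrum()].
#' @param background_n,novel_n catalog pair sizes, see
#'   [make_parental_pair()].
#' @param truth a [segment_truth()], default [default_segment_truth()].
#' @param n_arrays number of probe arrays to simulate (same truth,
#'   different noise seeds).
#' @param noise_sd,outlier_rate,flag_rate see [make_acgh()].
#' @param force overwrite a non-empty `out_dir`.
#' @param quiet suppress progress messages.
#' @return invisible list of written paths (`manifest`).
#' @export
run_simulate <- function(out_dir, config = sim_config(),
                         spectrum = cisplatin_like_spectrum(),
                         background_n = 100, novel_n = 40,
                         truth = default_segment_truth(), n_arrays = 1,
                         noise_sd = 0.15, outlier_rate = 0.01,
                         flag_rate = 0.02, force = FALSE, quiet = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_genome(config)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             genes = file.path(out_dir, "genes.bed"),
             parental = file.path(out_dir, "parental.tsv"),
             treated = file.path(out_dir, "treated.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_genome(gen$genome, paths[["genome"]])
  write_gene_bed(gen$genes, paths[["genes"]])
  pair <- make_parental_pair(gen$genome, background_n, spectrum, novel_n,
                             seed = config$seed, ann = gen$genes)
  write_variants(pair$parental, paths[["parental"]])
  write_variants(pair$treated, paths[["treated"]])
  arrays <- list()
  for (a in seq_len(n_arrays)) {
    acgh <- make_acgh(truth, config, noise_sd = noise_sd,
                      outlier_rate = outlier_rate, flag_rate = flag_rate,
                      seed = config$seed + 100L + a)
    p <- file.path(out_dir, sprintf("probes_%02d.tsv", a))
    write_probes_agilent(acgh$probes, p)
    paths[[sprintf("probes_%02d", a)]] <- p
    arrays[[sprintf("array_%02d", a)]] <- acgh$truth$segments
  }
  jsonlite::write_json(
    list(seed = config$seed, novel_keys = pair$novel_keys,
         acgh_truth = arrays),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  msg(sprintf("wrote %d files to %s", nrow(manifest) + 1L, out_dir),
      quiet = quiet)
  invisible(list(paths = paths, manifest = manifest, pair = pair))
}
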