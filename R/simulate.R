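# Seeded synthetic-data generators: genomes with gene annotation,
# mutation catalogs drawn from a 96-category spectrum with clonal/subclonal
# VAF structure, parental/treated pairs with recoverable novel variants,
# and aCGH probe arrays with planted segmental truth.

#' Simulation configuration
#'
#' @param seed integer seed; every generator is a pure function of its
#'   arguments including the seed.
#' @param contigs named integer vector of contig lengths (bases).
#' @param gc_content fraction in (0, 1), default 0.41 (human-like).
#' @param n_genes non-overlapping gene intervals to place.
#' @param probe_spacing array probe spacing in bases, default 13000
#'   (median spacing of a 60mer oligo aCGH design).
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, contigs = c(chr1 = 500000L, chr2 = 300000L),
                       gc_content = 0.41, n_genes = 20L,
                       probe_spacing = 13000L) {
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be named")
  if (any(contigs <= 0)) stop("contig lengths must be positive")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)")
  if (probe_spacing <= 0) stop("probe_spacing must be positive")
  structure(list(seed = as.integer(seed), contigs = contigs,
                 gc_content = gc_content, n_genes = as.integer(n_genes),
                 probe_spacing = as.integer(probe_spacing)),
            class = "SimConfig")
}

#' Generate a random genome with gene annotation
#'
#' Draws a seeded random nucleotide sequence per contig at the requested GC
#' content and places `n_genes` non-overlapping strand-labelled gene
#' intervals (lengths 2-20 kb, clipped to the contig). The same config
#' yields byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [GenomeSequence][genome_sequence]) and
#'   `genes` (a [transcript_annotation()]).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, {
    probs <- c((1 - config$gc_content) / 2, config$gc_content / 2,
               config$gc_content / 2, (1 - config$gc_content) / 2)
    contigs <- lapply(config$contigs, function(len) {
      paste(sample(BASES, len, replace = TRUE, prob = probs), collapse = "")
    })
    genome <- genome_sequence(contigs)
    genes <- place_genes(config)
    list(genome = genome, genes = genes)
  })
}

place_genes <- function(config) {
  n <- config$n_genes
  empty <- transcript_annotation(data.frame(
    chrom = character(), start = integer(), end = integer(),
    gene = character(), strand = character(), stringsAsFactors = FALSE))
  if (n == 0) return(empty)
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  rows <- list()
  tries <- 0L
  max_tries <- 200L * n
  chrom_w <- config$contigs / sum(config$contigs)
  while (length(rows) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " non-overlapping genes at this density")
    ch <- sample(names(config$contigs), 1, prob = chrom_w)
    len <- min(sample(2000:20000, 1), config$contigs[[ch]])
    if (config$contigs[[ch]] <= len) next
    start <- sample.int(config$contigs[[ch]] - len, 1)
    end <- start + len - 1L
    clash <- any(placed$chrom == ch & placed$start <= end & placed$end >= start)
    if (clash) next
    placed <- rbind(placed, data.frame(chrom = ch, start = start, end = end,
                                       stringsAsFactors = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch, start = start, end = end,
      gene = sprintf("GENE%04d", length(rows) + 1L),
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  transcript_annotation(do.call(rbind, rows))
}

#' Write gene annotation as BED6
#'
#' @param ann a [transcript_annotation()].
#' @param path output BED file (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(ann, path) {
  stopifnot(inherits(ann, "TranscriptAnnotation"))
  bed <- data.frame(ann$chrom, ann$start - 1L, ann$end, ann$gene, 0L,
                    ann$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' A cisplatin-like 96-category spectrum fixture
#'
#' Illustrative spectrum concentrating weight where platinum mutagenesis is
#' reported to act: C>A transversions preferentially in ACC/GCC context,
#' C>T transitions preferentially in CCC/CCT (less in CCA), C>G mostly in
#' GCC, and T>A with a preceding C, over a small uniform background. The
#' exact weights are fixture choices for simulation and testing, not
#' measured values.
#'
#' @return a [profile96()] of unnormalized weights.
#' @export
cisplatin_like_spectrum <- function() {
  w <- setNames(rep(1, 96), profile96_categories())
  w["A[C>A]C"] <- 60; w["G[C>A]C"] <- 60
  w["C[C>T]C"] <- 50; w["C[C>T]T"] <- 50; w["C[C>T]A"] <- 20
  w["G[C>G]C"] <- 25
  w[sprintf("C[T>A]%s", BASES)] <- 15
  profile96(w, label = "cisplatin-like")
}

base_code <- function(b) match(b, BASES) - 1L  # A=0 C=1 G=2 T=3

# index genome positions by pyrimidine-normalized trinucleotide context
# code = 16*five + 4*center + three (center always C or T after flipping)
context_site_index <- function(genome) {
  out <- list()
  for (ch in names(genome)) {
    b <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    code <- base_code(b)
    L <- length(code)
    if (L < 3) next
    p <- 2:(L - 1)
    prev <- code[p - 1]; cen <- code[p]; nxt <- code[p + 1]
    valid <- !is.na(prev) & !is.na(cen) & !is.na(nxt)
    pyr <- cen %in% c(1L, 3L)
    ctx <- ifelse(pyr,
                  16L * prev + 4L * cen + nxt,
                  16L * (3L - nxt) + 4L * (3L - cen) + (3L - prev))
    ctx[!valid] <- NA_integer_
    sites <- split(p[valid], ctx[valid])
    out[[ch]] <- sites
  }
  out
}

category_parts <- function(labels) {
  data.frame(
    five = substr(labels, 1, 1),
    ref = substr(labels, 3, 3),
    alt = substr(labels, 5, 5),
    three = substr(labels, 7, 7),
    stringsAsFactors = FALSE
  )
}

#' Sample a mutation catalog from a 96-category spectrum
#'
#' Draws exactly `n` single-base substitutions whose pyrimidine-normalized
#' class/context matches a multinomial draw from `spec`, placing each at a
#' uniformly chosen eligible genome site (without replacement). VAFs follow
#' a two-component clonal/subclonal mixture: with probability
#' `vaf_model$clonal_weight` a near-homozygous clonal value (Normal,
#' truncated to `(clonal_min, 1]`), otherwise a subclonal value uniform on
#' `(sub_min, sub_max)` - the allele-frequency structure of a drug-selected
#' clone that keeps acquiring mutations during expansion.
#'
#' @param genome a [GenomeSequence][genome_sequence].
#' @param spec a [profile96()] of category weights.
#' @param n number of SBS to draw.
#' @param vaf_model list of mixture parameters; defaults
#'   `clonal_weight = 0.6`, `clonal_mean = 0.98`, `clonal_sd = 0.02`,
#'   `clonal_min = 0.95`, `sub_min = 0.1`, `sub_max = 0.6`. The clonal
#'   truncation bound coincides with the 0.95 near-homozygous clonality
#'   cutoff (see [vaf_matrix()]) so the planted clonal weight is directly
#'   recoverable from the generated VAFs.
#' @param seed integer seed.
#' @param sample_id catalog label.
#' @param ann optional [transcript_annotation()] used to fill gene symbols
#'   and draw plausible functional classes for in-gene variants.
#' @param exclude_pos optional data frame `chrom`/`pos` of sites to avoid.
#' @return a [variant_catalog()] of exactly `n` SBS.
#' @export
sample_mutation_catalog <- function(genome, spec, n,
                                    vaf_model = list(), seed = 1L,
                                    sample_id = "sim", ann = NULL,
                                    exclude_pos = NULL) {
  stopifnot(inherits(genome, "GenomeSequence"), inherits(spec, "Profile96"))
  vm <- utils::modifyList(list(clonal_weight = 0.6, clonal_mean = 0.98,
                               clonal_sd = 0.02, clonal_min = 0.95,
                               sub_min = 0.1, sub_max = 0.6), vaf_model)
  labels <- profile96_categories()
  parts <- category_parts(labels)
  ctx_code <- 16L * base_code(parts$five) + 4L * base_code(parts$ref) +
    base_code(parts$three)
  idx <- context_site_index(genome)
  if (n == 0) {
    return(variant_catalog(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      vaf = numeric(), stringsAsFactors = FALSE),
                           sample_id = sample_id))
  }
  withr::with_seed(seed, {
    w <- as.numeric(spec$counts)
    if (all(w <= 0)) stop("spectrum has no positive weight")
    draws <- as.integer(rmultinom(1, n, w))
    # pool eligible sites per needed context across all contigs
    rows <- list()
    for (code in unique(ctx_code[draws > 0])) {
      cat_ids <- which(ctx_code == code & draws > 0)
      need <- sum(draws[cat_ids])
      pool_ch <- character(0); pool_pos <- integer(0)
      for (ch in names(idx)) {
        s <- idx[[ch]][[as.character(code)]]
        if (!is.null(s)) {
          pool_ch <- c(pool_ch, rep(ch, length(s)))
          pool_pos <- c(pool_pos, s)
        }
      }
      if (!is.null(exclude_pos) && length(pool_pos)) {
        drop <- paste(pool_ch, pool_pos) %in%
          paste(exclude_pos$chrom, exclude_pos$pos)
        pool_ch <- pool_ch[!drop]; pool_pos <- pool_pos[!drop]
      }
      if (length(pool_pos) < need) {
        stop("no (or too few) eligible genome sites for category ",
             labels[cat_ids[1]])
      }
      pick <- sample.int(length(pool_pos), need)
      off <- 0L
      for (ci in cat_ids) {
        k <- draws[ci]
        if (!k) next
        sel <- pick[(off + 1):(off + k)]
        off <- off + k
        ch_sel <- pool_ch[sel]; pos_sel <- pool_pos[sel]
        center <- vapply(seq_along(sel), function(m)
          substr(genome[[ch_sel[m]]], pos_sel[m], pos_sel[m]), "")
        pyr <- center %in% c("C", "T")
        ref <- center
        alt <- ifelse(pyr, parts$alt[ci], comp_base(parts$alt[ci]))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch_sel, pos = pos_sel, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
    }
    v <- do.call(rbind, rows)
    nv <- nrow(v)
    clonal <- runif(nv) < vm$clonal_weight
    vaf <- numeric(nv)
    ncl <- sum(clonal)
    if (ncl) {
      cv <- rnorm(ncl, vm$clonal_mean, vm$clonal_sd)
      cv <- pmin(pmax(cv, vm$clonal_min + 1e-6), 1)
      vaf[clonal] <- cv
    }
    vaf[!clonal] <- runif(nv - ncl, vm$sub_min, vm$sub_max)
    v$vaf <- vaf
    v$depth <- pmax(30L, as.integer(round(rnorm(nv, 100, 15))))
    v$gene <- ""
    v$func_class <- "unknown"
    if (!is.null(ann) && nrow(ann)) {
      vg <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
      hits <- GenomicRanges::findOverlaps(vg, annotation_granges(ann),
                                          ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      keepfirst <- !duplicated(qh)
      v$gene[qh[keepfirst]] <- ann$gene[sh[keepfirst]]
      ing <- v$gene != ""
      v$func_class[ing] <- sample(
        c("synonymous", "nonsynonymous", "stopgain", "intronic", "UTR"),
        sum(ing), replace = TRUE, prob = c(0.2, 0.4, 0.05, 0.25, 0.1))
    }
    variant_catalog(v, sample_id = sample_id)
  })
}

#' Sample single-base deletions
#'
#' Uniformly placed one-base deletions, useful for exercising deletion
#' flank analysis.
#'
#' @param genome a [GenomeSequence][genome_sequence].
#' @param n number of deletions.
#' @param seed integer seed.
#' @param sample_id catalog label.
#' @return a [variant_catalog()] of `n` DEL records.
#' @export
sample_deletion_catalog <- function(genome, n, seed = 1L, sample_id = "dels") {
  withr::with_seed(seed, {
    lens <- vapply(genome, nchar, 0)
    ch <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
    pos <- vapply(ch, function(c0) sample(2:(lens[[c0]] - 1), 1), 0)
    keys <- paste(ch, pos)
    while (anyDuplicated(keys)) {
      dup <- duplicated(keys)
      pos[dup] <- vapply(ch[dup], function(c0) sample(2:(lens[[c0]] - 1), 1), 0)
      keys <- paste(ch, pos)
    }
    ref <- vapply(seq_len(n), function(i) substr(genome[[ch[i]]], pos[i], pos[i]), "")
    variant_catalog(data.frame(chrom = ch, pos = as.integer(pos), ref = ref,
                               alt = "-", vaf = runif(n, 0.2, 1),
                               stringsAsFactors = FALSE),
                    sample_id = sample_id)
  })
}

#' Generate a parental/treated catalog pair with planted novel variants
#'
#' The parental catalog holds `background_n` shared variants (uniform random
#' SBS); the treated catalog holds the same background plus `novel_n`
#' variants drawn from `spec` via [sample_mutation_catalog()], at disjoint
#' sites, so that [subtract_parental()] recovers exactly the planted novel
#' set.
#'
#' @param genome a [GenomeSequence][genome_sequence].
#' @param background_n shared background variants.
#' @param spec a [profile96()] for the novel variants.
#' @param novel_n planted treatment-specific variants.
#' @param seed integer seed.
#' @param sample_id base label (`<id>` and `<id>-treated`).
#' @param vaf_model,ann passed to [sample_mutation_catalog()].
#' @param maintenance_conc metadata for the treated catalog (µM).
#' @return list with `parental`, `treated` and `novel_keys`
#'   (`chrom:pos:ref:alt` of the planted novel variants).
#' @export
make_parental_pair <- function(genome, background_n, spec, novel_n,
                               seed = 1L, sample_id = "line",
                               vaf_model = list(), ann = NULL,
                               maintenance_conc = NA_real_) {
  novel <- sample_mutation_catalog(genome, spec, novel_n,
                                   vaf_model = vaf_model, seed = seed,
                                   sample_id = paste0(sample_id, "-novel"),
                                   ann = ann)
  bg <- sample_background_catalog(
    genome, background_n, seed = seed + 1L,
    sample_id = sample_id,
    exclude = data.frame(chrom = novel$chrom, pos = novel$pos))
  treated_df <- rbind(
    as.data.frame(bg)[, c("chrom", "pos", "ref", "alt", "vaf", "depth",
                          "gene", "func_class")],
    as.data.frame(novel)[, c("chrom", "pos", "ref", "alt", "vaf", "depth",
                             "gene", "func_class")])
  treated <- variant_catalog(treated_df,
                             sample_id = paste0(sample_id, "-treated"),
                             maintenance_conc = maintenance_conc)
  list(parental = bg, treated = treated, novel_keys = variant_key(novel))
}

# uniform background SBS at sites disjoint from `exclude`
sample_background_catalog <- function(genome, n, seed, sample_id = "parental",
                                      exclude = NULL) {
  if (n == 0) {
    return(variant_catalog(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      vaf = numeric(), stringsAsFactors = FALSE),
                           sample_id = sample_id))
  }
  withr::with_seed(seed, {
    lens <- vapply(genome, nchar, 0)
    excl <- if (is.null(exclude)) character(0) else
      paste(exclude$chrom, exclude$pos)
    ch <- character(0); pos <- integer(0)
    tries <- 0L
    while (length(pos) < n) {
      tries <- tries + 1L
      if (tries > 50L) stop("site collision persisted after bounded retries")
      need <- n - length(pos)
      ch_new <- sample(names(genome), need, replace = TRUE,
                       prob = lens / sum(lens))
      pos_new <- vapply(ch_new, function(c0) sample(2:(lens[[c0]] - 1), 1), 0)
      keys <- paste(ch_new, pos_new)
      ok <- !keys %in% excl & !duplicated(keys) &
        !keys %in% paste(ch, pos)
      base_ok <- vapply(which(ok), function(i)
        substr(genome[[ch_new[i]]], pos_new[i], pos_new[i]) != "N", TRUE)
      ok[which(ok)[!base_ok]] <- FALSE
      ch <- c(ch, ch_new[ok]); pos <- c(pos, as.integer(pos_new[ok]))
    }
    ref <- vapply(seq_len(n), function(i) substr(genome[[ch[i]]], pos[i], pos[i]), "")
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
    variant_catalog(data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                               vaf = runif(n, 0.3, 1),
                               depth = pmax(30L, as.integer(round(rnorm(n, 100, 15)))),
                               stringsAsFactors = FALSE),
                    sample_id = sample_id)
  })
}

#' Define planted segmental truth for an aCGH simulation
#'
#' @param spans_by_chrom named list: per chromosome, a data frame with
#'   columns `span` (number of probes) and `level` (true log2 ratio).
#' @return a `SegmentTruth` list.
#' @export
segment_truth <- function(spans_by_chrom) {
  for (tr in spans_by_chrom) {
    stopifnot(all(c("span", "level") %in% names(tr)),
              all(tr$span >= 1), all(is.finite(tr$level)))
  }
  structure(spans_by_chrom, class = "SegmentTruth")
}

#' Default planted truth used in examples and validation
#'
#' Two chromosomes with a mixture of focal (5-10 probes) and broader
#' (20-30 probes) gains and losses at |log2| 0.6-1.0 on a neutral
#' background - the planted-truth layout used throughout the package's
#' validation runs.
#'
#' @return a [segment_truth()].
#' @export
default_segment_truth <- function() {
  segment_truth(list(
    chr1 = data.frame(span = c(60, 10, 80, 20, 60, 5, 65),
                      level = c(0, 0.8, 0, -0.8, 0, 0.6, 0)),
    chr2 = data.frame(span = c(50, 30, 70, 8, 42),
                      level = c(0, -0.6, 0, 1.0, 0))
  ))
}

#' Simulate an aCGH probe array with planted truth
#'
#' Tiles probes at the configured spacing along each chromosome, assigns
#' each probe its truth segment's log2 level plus Gaussian noise, replaces
#' an `outlier_rate` fraction by heavy-tailed values (t with 3 df), and
#' marks a `flag_rate` fraction with a QC flag so the loading step's
#' filtering is exercised. Probes are emitted in both the tumor/reference
#' log2 convention and the raw reference/tumor log10 dialect (column
#' `LogRatio`) that [load_probes()] expects.
#'
#' @param truth a [segment_truth()]; per chromosome the spans must sum to
#'   the number of probes the spacing implies.
#' @param config a [sim_config()] whose contigs cover the tiled probes.
#' @param noise_sd Gaussian probe noise on the log2 scale, default 0.15.
#' @param outlier_rate fraction of probes replaced by heavy-tailed values,
#'   default 0.01.
#' @param flag_rate fraction of probes QC-flagged, default 0.02.
#' @param seed integer seed.
#' @return list with `probes` (raw data frame in the Agilent-subset dialect
#'   plus `chrom`/`start`/`end`/`log2ratio`/`true_level` columns) and
#'   `truth` (list: `segments` data frame with genomic spans, probe spans
#'   and status at the 0.25 cutoff; `probe_level` per-probe true levels).
#' @export
make_acgh <- function(truth, config, noise_sd = 0.15, outlier_rate = 0.01,
                      flag_rate = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "SegmentTruth"), inherits(config, "SimConfig"))
  if (noise_sd < 0 || outlier_rate < 0 || outlier_rate > 1 ||
      flag_rate < 0 || flag_rate > 1)
    stop("invalid rate parameter")
  probe_len <- 60L
  withr::with_seed(seed, {
    rows <- list(); seg_rows <- list()
    for (ch in names(truth)) {
      len <- config$contigs[[ch]]
      if (is.null(len)) stop("truth names a contig absent from config: ", ch)
      starts <- seq.int(1L, len - probe_len + 1L, by = config$probe_spacing)
      tr <- truth[[ch]]
      if (sum(tr$span) != length(starts))
        stop("truth spans for ", ch, " must sum to ", length(starts),
             " probes at this spacing")
      level <- rep(tr$level, tr$span)
      val <- level + rnorm(length(starts), 0, noise_sd)
      out <- runif(length(starts)) < outlier_rate
      val[out] <- level[out] + stats::rt(sum(out), df = 3)
      flag <- runif(length(starts)) < flag_rate
      rows[[ch]] <- data.frame(
        chrom = ch, start = starts, end = starts + probe_len - 1L,
        log2ratio = val, true_level = level, flagged = flag,
        stringsAsFactors = FALSE)
      ends_idx <- cumsum(tr$span)
      starts_idx <- c(1L, head(ends_idx, -1) + 1L)
      seg_rows[[ch]] <- data.frame(
        chrom = ch,
        start = starts[starts_idx], end = starts[ends_idx] + probe_len - 1L,
        first_probe = starts_idx, last_probe = ends_idx,
        n_probes = tr$span, level = tr$level,
        status = ifelse(tr$level > 0.25, "gain",
                 ifelse(tr$level < -0.25, "loss", "normal")),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df$ProbeName <- sprintf("P%06d", seq_len(nrow(df)))
    df$SystematicName <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
    df$LogRatio <- -df$log2ratio * log10(2)
    df$gIsFeatNonUnifOL <- as.integer(df$flagged)
    df$rIsFeatNonUnifOL <- 0L
    df$gIsSaturated <- 0L
    df$rIsSaturated <- 0L
    segs <- do.call(rbind, seg_rows)
    rownames(segs) <- NULL
    list(probes = df,
         truth = list(segments = segs, probe_level = df$true_level))
  })
}

#' Write simulated probes in the Agilent-subset dialect
#'
#' @param probes the `probes` data frame from [make_acgh()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_probes_agilent <- function(probes, path) {
  cols <- c("ProbeName", "SystematicName", "LogRatio", PROBE_FLAGS)
  miss <- setdiff(cols, names(probes))
  if (length(miss)) stop("missing probe columns: ", paste(miss, collapse = ", "))
  write.table(probes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
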