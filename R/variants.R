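# Variant catalogs: reading, normalization, subtraction, filtering,
# adjacent-SNV merging, summaries, gene sets and VAF structure.

FUNC_CLASSES <- c("synonymous", "nonsynonymous", "stopgain", "frameshift",
                  "nonframeshift", "UTR", "intronic", "exonic_unclassified",
                  "unknown")

ALLELE_RE <- "^([ACGT]+|-)$"

#' Construct a variant catalog
#'
#' A `VariantCatalog` is a data frame of normalized sequence variants for one
#' sample, sorted by genomic position, with a unique `(chrom, pos, ref, alt)`
#' key per record. Alleles use uppercase A/C/G/T; a pure insertion has
#' `ref == "-"` and a pure deletion `alt == "-"` (positions are 1-based; for a
#' deletion `pos` is the first removed base, for an insertion the base before
#' which the sequence is inserted). The variant type (`SBS`, `DBS`, `MBS`,
#' `INS`, `DEL`) is derived from the allele lengths.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `vaf` (variant-allele fraction in `[0, 1]`), `depth`, `gene`,
#'   `func_class` (one of `r paste(FUNC_CLASSES, collapse = ", ")`).
#' @param sample_id sample label.
#' @param maintenance_conc optional drug maintenance concentration (µM),
#'   carried as metadata.
#' @param genome optional [GenomeSequence][read_genome] used to left-align
#'   indels during normalization.
#' @return a `VariantCatalog` (data frame subclass) with a derived
#'   `var_type` column.
#' @export
variant_catalog <- function(variants, sample_id = "sample",
                            maintenance_conc = NA_real_, genome = NULL) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("missing variant columns: ", paste(miss, collapse = ", "))
  nr <- nrow(variants)
  v <- data.frame(
    chrom = as.character(variants$chrom),
    pos = as.integer(variants$pos),
    ref = toupper(as.character(variants$ref)),
    alt = toupper(as.character(variants$alt)),
    vaf = if ("vaf" %in% names(variants)) as.numeric(variants$vaf)
          else rep(NA_real_, nr),
    depth = if ("depth" %in% names(variants)) as.integer(variants$depth)
            else rep(NA_integer_, nr),
    gene = if ("gene" %in% names(variants)) as.character(variants$gene)
           else rep("", nr),
    func_class = if ("func_class" %in% names(variants))
      as.character(variants$func_class) else rep("unknown", nr),
    stringsAsFactors = FALSE
  )
  v$gene[is.na(v$gene)] <- ""
  v$func_class[is.na(v$func_class) | v$func_class == ""] <- "unknown"
  bad_fc <- !v$func_class %in% FUNC_CLASSES
  if (any(bad_fc)) stop("unknown func_class: ",
                        paste(unique(v$func_class[bad_fc]), collapse = ", "))
  if (nrow(v)) {
    norm <- normalize_alleles(v$pos, v$ref, v$alt, v$chrom, genome)
    v$pos <- norm$pos; v$ref <- norm$ref; v$alt <- norm$alt
  }
  validate_variants(v)
  v$var_type <- variant_type(v$ref, v$alt)
  v <- v[genomic_order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  k <- variant_key(v)
  if (anyDuplicated(k)) stop("duplicate variant keys after normalization: ",
                             paste(unique(k[duplicated(k)]), collapse = ", "))
  structure(v,
            class = c("VariantCatalog", "data.frame"),
            sample_id = sample_id,
            maintenance_conc = maintenance_conc)
}

validate_variants <- function(v) {
  if (!nrow(v)) return(invisible(v))
  if (anyNA(v$pos) || any(v$pos < 1)) stop("variant positions must be integers >= 1")
  if (any(!grepl(ALLELE_RE, v$ref)) || any(!grepl(ALLELE_RE, v$alt)))
    stop("alleles must be drawn from {A,C,G,T,-}")
  same <- v$ref == v$alt
  if (any(same)) stop("ref == alt violates the variant invariant at ",
                      paste(variant_key(v)[same], collapse = ", "))
  bad_vaf <- !is.na(v$vaf) & (v$vaf < 0 | v$vaf > 1)
  if (any(bad_vaf)) stop("vaf outside [0, 1] at ",
                         paste(variant_key(v)[bad_vaf], collapse = ", "))
  invisible(v)
}

#' Variant type from allele lengths
#'
#' `SBS`/`DBS`/`MBS` for 1/2/3+ substituted bases, `INS` for pure insertions
#' (`ref == "-"`), `DEL` for pure deletions (`alt == "-"`). Length-discordant
#' complex substitutions are classed `MBS`.
#'
#' @param ref,alt normalized allele strings.
#' @return character vector of types.
#' @export
variant_type <- function(ref, alt) {
  type <- rep("MBS", length(ref))
  type[ref == "-"] <- "INS"
  type[alt == "-"] <- "DEL"
  eq <- ref != "-" & alt != "-" & nchar(ref) == nchar(alt)
  type[eq & nchar(ref) == 1] <- "SBS"
  type[eq & nchar(ref) == 2] <- "DBS"
  type
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

# Trim shared suffix then prefix; optionally left-align pure indels against
# the reference genome (shift through repeat tracts).
normalize_alleles <- function(pos, ref, alt, chrom = NULL, genome = NULL) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    if (r == "-") r <- ""
    if (a == "-") a <- ""
    if (r == a) stop("ref == alt for record ", i)
    while (nchar(r) > 0 && nchar(a) > 0 && (nchar(r) > 1 || nchar(a) > 1) &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 0 && nchar(a) > 0 && (nchar(r) > 1 || nchar(a) > 1) &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    if (!is.null(genome) && !is.null(chrom) && xor(nchar(r) == 0, nchar(a) == 0)) {
      seqc <- genome[[chrom[i]]]
      if (!is.null(seqc)) {
        if (nchar(a) == 0) {            # deletion: shift left through repeats
          while (p > 1 &&
                 substr(seqc, p - 1, p - 1) == substr(r, nchar(r), nchar(r))) {
            r <- paste0(substr(seqc, p - 1, p - 1), substr(r, 1, nchar(r) - 1))
            p <- p - 1L
          }
        } else {                        # insertion: rotate left through repeats
          while (p > 1 &&
                 substr(seqc, p - 1, p - 1) == substr(a, nchar(a), nchar(a))) {
            a <- paste0(substr(a, nchar(a), nchar(a)), substr(a, 1, nchar(a) - 1))
            p <- p - 1L
          }
        }
      }
    }
    ref[i] <- if (nchar(r)) r else "-"
    alt[i] <- if (nchar(a)) a else "-"
    pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' @export
print.VariantCatalog <- function(x, ...) {
  cat(sprintf("VariantCatalog '%s': %d variants", attr(x, "sample_id"), nrow(x)))
  mc <- attr(x, "maintenance_conc")
  if (!is.na(mc)) cat(sprintf(" (maintenance %.1f uM)", mc))
  cat("\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

map_func_class <- function(func, exonic_func) {
  func <- tolower(ifelse(is.na(func), "", func))
  ef <- tolower(ifelse(is.na(exonic_func), "", exonic_func))
  out <- rep("unknown", length(func))
  out[grepl("nonsynonymous", ef)] <- "nonsynonymous"
  out[grepl("^synonymous|[^n]synonymous", ef) & !grepl("nonsynonymous", ef)] <- "synonymous"
  out[grepl("stopgain|stop-gain|stop_gain", ef)] <- "stopgain"
  out[grepl("nonframeshift", ef)] <- "nonframeshift"
  out[grepl("frameshift", ef) & !grepl("nonframeshift", ef)] <- "frameshift"
  rest <- out == "unknown"
  out[rest & grepl("intronic", func)] <- "intronic"
  out[rest & grepl("utr", func)] <- "UTR"
  out[out == "unknown" & grepl("exonic", func)] <- "exonic_unclassified"
  out
}

#' Read a variant table
#'
#' Reads either an ANNOVAR-style TSV (columns `Chr`, `Start`, `End`, `Ref`,
#' `Alt` and optionally `Func`, `Gene`, `ExonicFunc`, `VAF`, `Depth`) or a
#' VCF 4.2 file. Records are normalized (uppercase alleles, shared
#' prefix/suffix trimmed, indels left-aligned when a genome is supplied) and
#' multi-allelic VCF records are split into one variant per alternate allele.
#' For VCF input the variant-allele fraction is taken from the `AF` INFO key
#' (or per-sample `AF` FORMAT field), depth from `DP`, gene from a `GENE`
#' INFO key when present.
#'
#' @param path input file.
#' @param dialect `"annovar_tsv"` or `"vcf"`.
#' @param sample_id label for the catalog (defaults to the file stem; for VCF
#'   also selects the genotype column when FORMAT fields are used).
#' @param genome optional [GenomeSequence][read_genome] for indel left-alignment.
#' @param maintenance_conc optional metadata, see [variant_catalog()].
#' @return a [variant_catalog()].
#' @export
read_variants <- function(path, dialect = c("annovar_tsv", "vcf"),
                          sample_id = NULL, genome = NULL,
                          maintenance_conc = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- switch(dialect,
               annovar_tsv = read_annovar_tsv(path),
               vcf = read_vcf_variants(path, sample_id))
  variant_catalog(df, sample_id = sample_id,
                  maintenance_conc = maintenance_conc, genome = genome)
}

read_annovar_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Chr", "Start", "End", "Ref", "Alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$Start))
  if (nrow(tab) && anyNA(pos)) {
    stop("unparseable Start field at line ",
         which(is.na(pos))[1] + 1L, " of ", path)
  }
  nr <- nrow(tab)
  data.frame(
    chrom = as.character(tab$Chr),
    pos = pos,
    ref = as.character(tab$Ref),
    alt = as.character(tab$Alt),
    vaf = if ("VAF" %in% names(tab)) suppressWarnings(as.numeric(tab$VAF))
          else rep(NA_real_, nr),
    depth = if ("Depth" %in% names(tab)) suppressWarnings(as.integer(tab$Depth))
            else rep(NA_integer_, nr),
    gene = if ("Gene" %in% names(tab)) as.character(tab$Gene) else rep("", nr),
    func_class = map_func_class(
      if ("Func" %in% names(tab)) tab$Func else rep("", nrow(tab)),
      if ("ExonicFunc" %in% names(tab)) tab$ExonicFunc else rep("", nrow(tab))),
    stringsAsFactors = FALSE
  )
}

read_vcf_variants <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(), depth = integer(),
                      gene = character(), func_class = character(),
                      stringsAsFactors = FALSE))
  }
  info_field <- function(key) {
    m <- regmatches(vcf@fix[, "INFO"],
                    regexpr(paste0("(^|;)", key, "=[^;]*"), vcf@fix[, "INFO"]))
    vals <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), vcf@fix[, "INFO"])
    vals[hit] <- sub(paste0("^(;)?", key, "="), "", m)
    vals
  }
  af <- info_field("AF")
  dp <- info_field("DP")
  gene <- info_field("GENE")
  func <- info_field("FUNC")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (is.na(af[i])) rep(NA_real_, length(alts)) else
      suppressWarnings(as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]]))
    if (length(afs) < length(alts)) afs <- rep(afs[1], length(alts))
    out[[i]] <- data.frame(
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = alts,
      vaf = afs,
      depth = suppressWarnings(as.integer(dp[i])),
      gene = if (is.na(gene[i])) "" else gene[i],
      func_class = if (is.na(func[i]) || !func[i] %in% FUNC_CLASSES)
        "unknown" else func[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Write a variant catalog as ANNOVAR-style TSV
#'
#' Inverse of [read_variants()] for the `annovar_tsv` dialect: a
#' write/read round trip reproduces the catalog key-for-key.
#'
#' @param cat a [variant_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(cat, path) {
  stopifnot(inherits(cat, "VariantCatalog"))
  exonic <- c(synonymous = "synonymous SNV", nonsynonymous = "nonsynonymous SNV",
              stopgain = "stopgain", frameshift = "frameshift substitution",
              nonframeshift = "nonframeshift substitution")
  func <- ifelse(cat$func_class %in% names(exonic), "exonic",
          ifelse(cat$func_class == "UTR", "UTR3",
          ifelse(cat$func_class == "intronic", "intronic",
          ifelse(cat$func_class == "exonic_unclassified", "exonic", "."))))
  ef <- ifelse(cat$func_class %in% names(exonic), exonic[cat$func_class],
        ifelse(cat$func_class == "exonic_unclassified", "unknown", "."))
  reflen <- ifelse(cat$ref == "-", 1L, nchar(cat$ref))
  out <- data.frame(Chr = cat$chrom, Start = cat$pos,
                    End = cat$pos + reflen - 1L,
                    Ref = cat$ref, Alt = cat$alt,
                    Func = func, Gene = cat$gene, ExonicFunc = ef,
                    VAF = cat$vaf, Depth = cat$depth,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Novel variants of a treated line relative to its parental line
#'
#' Returns exactly the treated variants whose `(chrom, pos, ref, alt)` key is
#' absent from the parental catalog; VAFs and annotations are carried
#' unchanged. This is the subtraction used to isolate treatment-acquired
#' mutations before spectrum construction.
#'
#' @param treated,parental [variant_catalog()]s on the same reference.
#' @return a `VariantCatalog` of treated-only variants.
#' @export
subtract_parental <- function(treated, parental) {
  stopifnot(inherits(treated, "VariantCatalog"),
            inherits(parental, "VariantCatalog"))
  keep <- !variant_key(treated) %in% variant_key(parental)
  subset_catalog(treated, keep)
}

subset_catalog <- function(cat, keep) {
  out <- as.data.frame(cat)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(cat),
            sample_id = attr(cat, "sample_id"),
            maintenance_conc = attr(cat, "maintenance_conc"))
}

#' Drop low-frequency variants
#'
#' Keeps variants with `vaf >= threshold` (boundary inclusive): a 10%
#' read-fraction cutoff excludes variants seen in fewer than 10% of reads.
#'
#' @param cat a [variant_catalog()]; every variant must carry a VAF.
#' @param threshold inclusive lower bound, default 0.10.
#' @return filtered `VariantCatalog`.
#' @export
filter_min_vaf <- function(cat, threshold = 0.10) {
  stopifnot(inherits(cat, "VariantCatalog"))
  if (anyNA(cat$vaf)) {
    stop("missing vaf for: ",
         paste(variant_key(cat)[is.na(cat$vaf)], collapse = ", "))
  }
  subset_catalog(cat, cat$vaf >= threshold)
}

#' Merge adjacent single-base substitutions into multi-base events
#'
#' Maximal runs of SBS at strictly consecutive positions on one chromosome
#' whose VAFs agree pairwise within `vaf_tol` are replaced by a single
#' multi-base substitution: runs of length 2 become a double-base
#' substitution (DBS), longer runs an MBS. The merged VAF is the mean over
#' members; the gene symbol is kept when all members agree.
#'
#' @param cat a sorted [variant_catalog()].
#' @param vaf_tol maximum pairwise VAF difference within a run, default 0.05.
#' @return `VariantCatalog` with merged events.
#' @export
merge_adjacent_snvs <- function(cat, vaf_tol = 0.05) {
  stopifnot(inherits(cat, "VariantCatalog"))
  if (nrow(cat) < 2) return(cat)
  v <- as.data.frame(cat)
  is_sbs <- v$var_type == "SBS"
  runs <- list()
  i <- 1
  n <- nrow(v)
  while (i <= n) {
    if (!is_sbs[i]) { i <- i + 1; next }
    j <- i
    lo <- hi <- v$vaf[i]
    while (j < n && is_sbs[j + 1] &&
           v$chrom[j + 1] == v$chrom[j] &&
           v$pos[j + 1] == v$pos[j] + 1L) {
      nlo <- min(lo, v$vaf[j + 1], na.rm = TRUE)
      nhi <- max(hi, v$vaf[j + 1], na.rm = TRUE)
      if (!is.na(nhi - nlo) && nhi - nlo > vaf_tol) break
      lo <- nlo; hi <- nhi
      j <- j + 1
    }
    if (j > i) runs[[length(runs) + 1]] <- i:j
    i <- j + 1
  }
  if (!length(runs)) return(cat)
  drop <- unlist(runs)
  merged <- lapply(runs, function(idx) {
    g <- unique(v$gene[idx])
    data.frame(chrom = v$chrom[idx[1]], pos = v$pos[idx[1]],
               ref = paste(v$ref[idx], collapse = ""),
               alt = paste(v$alt[idx], collapse = ""),
               vaf = mean(v$vaf[idx]),
               depth = as.integer(round(mean(v$depth[idx]))),
               gene = if (length(g) == 1) g else "",
               func_class = if (length(unique(v$func_class[idx])) == 1)
                 v$func_class[idx[1]] else "unknown",
               stringsAsFactors = FALSE)
  })
  keep <- v[-drop, c("chrom", "pos", "ref", "alt", "vaf", "depth",
                     "gene", "func_class")]
  variant_catalog(rbind(keep, do.call(rbind, merged)),
                  sample_id = attr(cat, "sample_id"),
                  maintenance_conc = attr(cat, "maintenance_conc"))
}

#' Summarize a variant catalog
#'
#' Tallies the catalog the way an exome study reports it: overall mutations,
#' distinct genes hit, counts by variant type (SBS, DBS, MBS, insertions,
#' deletions, single-base deletions) and by functional class. The type counts
#' always satisfy `SBS + DBS + MBS + INS + DEL == overall`.
#'
#' @param cat a [variant_catalog()] (apply [merge_adjacent_snvs()] first if
#'   DBS counts are wanted).
#' @return a `CatalogSummary` (named list).
#' @export
summarize_catalog <- function(cat) {
  stopifnot(inherits(cat, "VariantCatalog"))
  tt <- table(factor(cat$var_type, levels = c("SBS", "DBS", "MBS", "INS", "DEL")))
  fc <- table(factor(cat$func_class, levels = FUNC_CLASSES))
  out <- c(list(
    overall = nrow(cat),
    genes_hit = length(unique(cat$gene[cat$gene != ""])),
    sbs = unname(tt[["SBS"]]), dbs = unname(tt[["DBS"]]),
    mbs = unname(tt[["MBS"]]), ins = unname(tt[["INS"]]),
    del = unname(tt[["DEL"]]),
    single_base_del = sum(cat$var_type == "DEL" & nchar(cat$ref) == 1)
  ), as.list(as.integer(fc)))
  names(out)[9:length(out)] <- FUNC_CLASSES
  structure(out, class = "CatalogSummary", sample_id = attr(cat, "sample_id"))
}

#' @export
summary.VariantCatalog <- function(object, ...) summarize_catalog(object)

#' @export
print.CatalogSummary <- function(x, ...) {
  cat(sprintf("Catalog summary for '%s'\n", attr(x, "sample_id")))
  df <- data.frame(count = unlist(x))
  print(df)
  invisible(x)
}

#' @export
as.data.frame.CatalogSummary <- function(x, ...) {
  data.frame(metric = names(unclass(x)), count = unlist(x, use.names = FALSE))
}

#' Genes carrying mutations
#'
#' Distinct non-empty gene symbols in a catalog; with `functional_only` the
#' catalog is first restricted to variants likely to alter protein function
#' (nonsynonymous, stop-gain or frameshift).
#'
#' @param cat a [variant_catalog()].
#' @param functional_only logical.
#' @return character vector of gene symbols (sorted).
#' @export
genes_with_mutations <- function(cat, functional_only = FALSE) {
  stopifnot(inherits(cat, "VariantCatalog"))
  v <- as.data.frame(cat)
  if (functional_only) {
    v <- v[v$func_class %in% c("nonsynonymous", "stopgain", "frameshift"), ]
  }
  sort(unique(v$gene[v$gene != ""]))
}

#' Venn region counts for gene sets
#'
#' For `k` gene sets (2 to 6), counts every one of the `2^k - 1` nonempty
#' membership regions by brute-force membership over the union, e.g. the
#' genes mutated in all input lines are the count of the full-intersection
#' region.
#'
#' @param sets named list of character vectors.
#' @return a `VennCounts` data frame with columns `region` (set names joined
#'   by `&`), `degree` and `count`; region counts sum to the union size.
#' @export
intersect_gene_sets <- function(sets) {
  stopifnot(is.list(sets))
  k <- length(sets)
  if (k < 2 || k > 6) stop("need between 2 and 6 gene sets")
  nm <- names(sets) %||% paste0("set", seq_len(k))
  nm[nm == ""] <- paste0("set", which(nm == ""))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(which(r), collapse = ","))
  regions <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  counts <- vapply(regions, function(idx) {
    sum(pattern == paste(idx, collapse = ","))
  }, integer(1))
  out <- data.frame(
    region = vapply(regions, function(idx) paste(nm[idx], collapse = "&"), ""),
    degree = lengths(regions),
    count = counts,
    stringsAsFactors = FALSE
  )
  structure(out[order(out$degree, out$region), ],
            class = c("VennCounts", "data.frame"), set_names = nm,
            union_size = length(universe))
}

#' Allele-frequency histograms and clonality across samples
#'
#' Bins each catalog's VAFs over `[0, 1]` and reports, per sample, the
#' fraction of variants at near-homozygous clonal frequency
#' (`vaf >= clonal_cutoff`), the population a drug-selected clone leaves at
#' VAF close to 1.
#'
#' @param cats list of [variant_catalog()]s.
#' @param bins increasing bin edges; must cover `[0, 1]`.
#' @param clonal_cutoff default 0.95.
#' @return list with `counts` (samples x bins matrix) and `clonal_fraction`.
#' @export
vaf_matrix <- function(cats, bins = seq(0, 1, by = 0.1), clonal_cutoff = 0.95) {
  stopifnot(is.list(cats), all(vapply(cats, inherits, TRUE, "VariantCatalog")))
  bins <- sort(bins)
  if (bins[1] > 0 || bins[length(bins)] < 1)
    stop("bins must cover [0, 1]")
  nb <- length(bins) - 1
  labs <- paste0("[", format(bins[-length(bins)]), ",", format(bins[-1]),
                 c(rep(")", nb - 1), "]"))
  counts <- t(vapply(cats, function(cc) {
    v <- cc$vaf[!is.na(cc$vaf)]
    idx <- findInterval(v, bins, rightmost.closed = TRUE)
    tabulate(idx, nbins = nb)
  }, integer(nb)))
  rownames(counts) <- vapply(cats, attr, "", "sample_id")
  colnames(counts) <- labs
  clonal <- vapply(cats, function(cc) {
    v <- cc$vaf[!is.na(cc$vaf)]
    if (!length(v)) return(NA_real_)
    mean(v >= clonal_cutoff)
  }, numeric(1))
  names(clonal) <- rownames(counts)
  list(counts = counts, clonal_fraction = clonal, bins = bins,
       clonal_cutoff = clonal_cutoff)
}
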