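# 96-category mutational spectra under the pyrimidine convention,
# stranded 12-class tallies, deletion flank context and cosine comparison.

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The fixed 96-category labels
#'
#' Six pyrimidine-referenced substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G), each split into 16 flanking-base contexts ordered by 5' then 3'
#' base (A, C, G, T). Labels use the conventional `A[C>A]A` layout.
#'
#' @return character vector of length 96.
#' @export
profile96_categories <- function() {
  unlist(lapply(SBS_CLASSES, function(cl) {
    as.vector(t(outer(BASES, BASES, function(f, t3)
      sprintf("%s[%s]%s", f, cl, t3))))
  }))
}

#' Read a genome from FASTA
#'
#' Loads contigs into an in-memory `GenomeSequence`: a named list of
#' uppercase nucleotide strings (alphabet A/C/G/T/N). Contig names are
#' truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return a `GenomeSequence`.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- as.list(toupper(as.character(ss)))
  names(g) <- sub("\\s.*$", "", names(ss))
  genome_sequence(g)
}

#' Construct a GenomeSequence from character strings
#'
#' @param contigs named list (or named character vector) of nucleotide
#'   strings.
#' @return a `GenomeSequence`.
#' @export
genome_sequence <- function(contigs) {
  g <- lapply(as.list(contigs), function(s) toupper(as.character(s)))
  if (is.null(names(g)) || any(names(g) == ""))
    stop("contigs must be named")
  bad <- vapply(g, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) stop("contig alphabet must be A/C/G/T/N: ",
                     paste(names(g)[bad], collapse = ", "))
  structure(g, class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence: %d contig(s), %s bases\n", length(x),
              format(sum(vapply(x, nchar, 0)), big.mark = ",")))
  invisible(x)
}

#' Write a GenomeSequence to FASTA
#'
#' @param genome a `GenomeSequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Core classifier. Returns class/context under the pyrimidine convention,
# with ok = FALSE (and a reason) for skippable sites. A variant whose ref
# equals the complement of the genome base is interpreted as a minus-strand
# representation and flipped; a genuine mismatch is an error unless
# on_mismatch = "skip".
classify_sbs <- function(genome, chrom, pos, ref, alt,
                         on_mismatch = c("error", "skip")) {
  on_mismatch <- match.arg(on_mismatch)
  n <- length(pos)
  cls <- ctx <- rep(NA_character_, n)
  ok <- rep(FALSE, n)
  reason <- rep("", n)
  for (ch in unique(chrom)) {
    seqc <- genome[[ch]]
    if (is.null(seqc)) stop("contig not in genome: ", ch)
    len <- nchar(seqc)
    i <- which(chrom == ch)
    p <- pos[i]
    if (any(p < 1 | p > len)) stop("position outside contig ", ch)
    edge <- p == 1 | p == len
    center <- substr(rep(seqc, length(p)), p, p)
    r <- ref[i]; a <- alt[i]
    flip <- center != r & comp_base(center) == r
    r[flip] <- comp_base(r[flip])
    a[flip] <- comp_base(a[flip])
    mism <- center != r
    if (any(mism) && on_mismatch == "error") {
      stop("reference allele mismatch with genome at ",
           paste0(ch, ":", p[mism][1], " (genome ", center[mism][1],
                  ", variant ", ref[i][mism][1], ")"))
    }
    tri <- substring(seqc, pmax(p - 1, 1), pmin(p + 1, len))
    pur <- r %in% c("A", "G")
    ctx_i <- ifelse(pur, revcomp3(tri), tri)
    r_p <- ifelse(pur, comp_base(r), r)
    a_p <- ifelse(pur, comp_base(a), a)
    cls_i <- paste0(r_p, ">", a_p)
    hasN <- grepl("N", ctx_i, fixed = TRUE)
    good <- !edge & !mism & !hasN
    cls[i] <- ifelse(good, cls_i, NA)
    ctx[i] <- ifelse(good, ctx_i, NA)
    ok[i] <- good
    reason[i] <- ifelse(mism, "ref_mismatch",
                 ifelse(edge, "contig_edge",
                 ifelse(hasN, "ambiguous_flank", "")))
  }
  list(class = cls, context = ctx, ok = ok, reason = reason)
}

#' Substitution class and trinucleotide context of an SBS
#'
#' Reports each single-base substitution by the pyrimidine of the mutated
#' base pair: when the reference allele is a purine, class and context are
#' reverse-complemented so the reported 3-mer is centred on C or T. Variants
#' at a contig edge or with an N flank are skipped with a warning.
#'
#' @param genome a [GenomeSequence][read_genome].
#' @param chrom,pos,ref,alt parallel vectors describing SBS records.
#' @param on_mismatch `"error"` (default) aborts when the reference allele
#'   disagrees with the genome (likely a genome-build mismatch); `"skip"`
#'   drops such sites instead.
#' @return data frame with columns `class`, `context`, `ok`, `reason`.
#' @export
trinucleotide_context <- function(genome, chrom, pos, ref, alt,
                                  on_mismatch = c("error", "skip")) {
  res <- classify_sbs(genome, chrom, pos, ref, alt, on_mismatch)
  if (any(!res$ok)) {
    warning(sum(!res$ok), " site(s) skipped (",
            paste(unique(res$reason[!res$ok]), collapse = ", "), ")")
  }
  data.frame(class = res$class, context = res$context, ok = res$ok,
             reason = res$reason, stringsAsFactors = FALSE)
}

#' Build a 96-category mutational profile
#'
#' Counts a catalog's single-base substitutions over the fixed 96
#' class-by-context categories (see [profile96_categories()]). Double- and
#' multi-base substitutions and indels are excluded; unclassifiable SBS
#' (contig edge, N flank) are tallied in `skipped`.
#'
#' @param cat a [variant_catalog()], typically after parental subtraction and
#'   VAF filtering.
#' @param genome a [GenomeSequence][read_genome].
#' @param on_mismatch see [trinucleotide_context()].
#' @param label profile label (defaults to the catalog's sample id).
#' @return a `Profile96`: list with `counts` (named integer vector of length
#'   96), `n` (classified SBS) and `skipped`.
#' @export
build_profile96 <- function(cat, genome, on_mismatch = c("error", "skip"),
                            label = NULL) {
  stopifnot(inherits(cat, "VariantCatalog"))
  label <- label %||% attr(cat, "sample_id")
  sbs <- as.data.frame(cat)[cat$var_type == "SBS", , drop = FALSE]
  cats96 <- profile96_categories()
  counts <- setNames(integer(96), cats96)
  skipped <- 0L
  if (nrow(sbs)) {
    res <- classify_sbs(genome, sbs$chrom, sbs$pos, sbs$ref, sbs$alt,
                        on_mismatch)
    skipped <- sum(!res$ok)
    lab <- sprintf("%s[%s]%s",
                   substr(res$context[res$ok], 1, 1),
                   res$class[res$ok],
                   substr(res$context[res$ok], 3, 3))
    tt <- table(factor(lab, levels = cats96))
    counts <- setNames(as.integer(tt), cats96)
  }
  profile96(counts, label = label, skipped = skipped)
}

#' Construct a Profile96 from counts or weights
#'
#' @param counts numeric vector of length 96 in the fixed category order
#'   (optionally named by [profile96_categories()]).
#' @param label profile label.
#' @param skipped number of unclassifiable SBS, bookkeeping only.
#' @return a `Profile96`.
#' @export
profile96 <- function(counts, label = "profile", skipped = 0L) {
  cats96 <- profile96_categories()
  if (length(counts) != 96) stop("a Profile96 has exactly 96 categories")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), cats96)) stop("unknown category names")
    counts <- counts[cats96]
  } else {
    names(counts) <- cats96
  }
  structure(list(counts = counts, n = sum(counts), skipped = skipped,
                 label = label),
            class = "Profile96")
}

#' @export
print.Profile96 <- function(x, ...) {
  cat(sprintf("Profile96 '%s': n = %s classified SBS (%d skipped)\n",
              x$label, format(x$n, big.mark = ","), x$skipped))
  top <- sort(profile_fractions(x), decreasing = TRUE)[1:5]
  if (x$n > 0)
    cat("top categories:",
        paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Category fractions of a profile
#'
#' @param p a [profile96()].
#' @return numeric vector of length 96 summing to 1 (all zero when `n = 0`).
#' @export
profile_fractions <- function(p) {
  stopifnot(inherits(p, "Profile96"))
  if (p$n == 0) return(setNames(numeric(96), names(p$counts)))
  p$counts / p$n
}

#' Cosine similarity between two mutational profiles
#'
#' `dot(p, q) / (||p|| * ||q||)` on the category fractions; symmetric,
#' scale-invariant and in `[0, 1]` for nonnegative profiles.
#'
#' @param p,q [profile96()] objects or bare nonnegative numeric vectors of
#'   equal length.
#' @return similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(p, q) {
  pv <- if (inherits(p, "Profile96")) as.numeric(p$counts) else as.numeric(p)
  qv <- if (inherits(q, "Profile96")) as.numeric(q$counts) else as.numeric(q)
  if (length(pv) != length(qv)) stop("profiles have different lengths")
  np <- sqrt(sum(pv^2)); nq <- sqrt(sum(qv^2))
  if (np == 0 || nq == 0) stop("cosine similarity undefined for a zero profile")
  sum(pv * qv) / (np * nq)
}

#' Six-class substitution counts
#'
#' Marginal of the 96-category profile over contexts: counts of C>A, C>G,
#' C>T, T>A, T>C, T>G among a catalog's single-base substitutions (purine
#' references are complemented first).
#'
#' @param cat a [variant_catalog()].
#' @return named integer vector of length 6.
#' @export
class_counts <- function(cat) {
  stopifnot(inherits(cat, "VariantCatalog"))
  sbs <- as.data.frame(cat)[cat$var_type == "SBS", , drop = FALSE]
  r <- sbs$ref; a <- sbs$alt
  pur <- r %in% c("A", "G")
  r[pur] <- comp_base(r[pur]); a[pur] <- comp_base(a[pur])
  tt <- table(factor(paste0(r, ">", a), levels = SBS_CLASSES))
  setNames(as.integer(tt), SBS_CLASSES)
}

#' Read gene annotation from BED6
#'
#' Imports a BED file (0-based half-open, strand column required) into the
#' 1-based inclusive annotation table used for strand assignment and call
#' reporting.
#'
#' @param path BED file.
#' @return a `TranscriptAnnotation` data frame with columns `chrom`, `start`,
#'   `end`, `gene`, `strand`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  transcript_annotation(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("feature", seq_along(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Construct a transcript annotation table
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `strand` (`+` or `-`), 1-based inclusive.
#' @return a `TranscriptAnnotation`.
#' @export
transcript_annotation <- function(df) {
  need <- c("chrom", "start", "end", "gene", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing annotation columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$start > df$end)) stop("annotation start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[genomic_order(df$chrom, df$start), need, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("TranscriptAnnotation", "data.frame"))
}

annotation_granges <- function(ann) {
  GenomicRanges::GRanges(ann$chrom,
                         IRanges::IRanges(ann$start, ann$end),
                         strand = ann$strand, gene = ann$gene)
}

#' Stranded substitution counts (12 classes)
#'
#' Splits the six substitution classes by whether the pyrimidine of the
#' mutated base pair lies on the transcribed (template) strand of the
#' covering gene or on the nontranscribed strand. SBS outside any gene
#' footprint, or covered by genes on conflicting strands, are counted as
#' `excluded`; the invariant `transcribed + nontranscribed + excluded ==
#' number of SBS` always holds.
#'
#' @param cat a [variant_catalog()].
#' @param ann a [transcript_annotation()] (or BED via [read_gene_bed()]).
#' @return list with `counts` (6 x 2 matrix) and `excluded`.
#' @export
stranded_class_counts <- function(cat, ann) {
  stopifnot(inherits(cat, "VariantCatalog"),
            inherits(ann, "TranscriptAnnotation"))
  sbs <- as.data.frame(cat)[cat$var_type == "SBS", , drop = FALSE]
  counts <- matrix(0L, nrow = 6, ncol = 2,
                   dimnames = list(SBS_CLASSES,
                                   c("transcribed", "nontranscribed")))
  excluded <- 0L
  if (!nrow(sbs)) return(list(counts = counts, excluded = excluded))
  vg <- GenomicRanges::GRanges(sbs$chrom, IRanges::IRanges(sbs$pos, sbs$pos))
  ag <- annotation_granges(ann)
  hits <- GenomicRanges::findOverlaps(vg, ag, ignore.strand = TRUE)
  strands <- split(ann$strand[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
  r <- sbs$ref; a <- sbs$alt
  pur <- r %in% c("A", "G")
  cls <- paste0(ifelse(pur, comp_base(r), r), ">",
                ifelse(pur, comp_base(a), a))
  pyr_strand <- ifelse(pur, "-", "+")
  for (i in seq_len(nrow(sbs))) {
    st <- unique(strands[[as.character(i)]])
    if (is.null(st) || length(st) != 1) {
      excluded <- excluded + 1L
      next
    }
    template <- if (st == "+") "-" else "+"
    col <- if (pyr_strand[i] == template) "transcribed" else "nontranscribed"
    counts[cls[i], col] <- counts[cls[i], col] + 1L
  }
  list(counts = counts, excluded = excluded)
}

DEL_FLANK_PAIRS <- c("A/A", "A/C", "A/G", "A/T", "C/C", "C/G", "C/T",
                     "G/G", "G/T", "T/T")

#' Flanking-base context of single-base deletions
#'
#' For each single-base deletion (normalized and left-aligned), records the
#' unordered pair of reference bases immediately 5' and 3' of the deleted
#' base. Deletions at contig edges or with an N flank are skipped with a
#' warning.
#'
#' @param cat a [variant_catalog()].
#' @param genome a [GenomeSequence][read_genome].
#' @return list with `counts` (the 10 unordered base pairs), `total` and
#'   `skipped`.
#' @export
deletion_flank_counts <- function(cat, genome) {
  stopifnot(inherits(cat, "VariantCatalog"))
  d <- as.data.frame(cat)
  d <- d[d$var_type == "DEL" & nchar(d$ref) == 1 & d$ref != "-", , drop = FALSE]
  counts <- setNames(integer(10), DEL_FLANK_PAIRS)
  skipped <- 0L
  for (i in seq_len(nrow(d))) {
    seqc <- genome[[d$chrom[i]]]
    if (is.null(seqc)) stop("contig not in genome: ", d$chrom[i])
    p <- d$pos[i]
    if (p <= 1 || p >= nchar(seqc)) { skipped <- skipped + 1L; next }
    five <- substr(seqc, p - 1, p - 1)
    three <- substr(seqc, p + 1, p + 1)
    if (five == "N" || three == "N") { skipped <- skipped + 1L; next }
    pair <- paste(sort(c(five, three)), collapse = "/")
    counts[pair] <- counts[pair] + 1L
  }
  if (skipped) warning(skipped, " deletion(s) skipped (no usable flank)")
  list(counts = counts, total = sum(counts), skipped = skipped)
}

#' Write / read a 96-category profile as TSV
#'
#' Three columns: category label, count, fraction; compatible with common
#' signature-tool layouts. `read_profile96` accepts any table whose first
#' column holds the 96 labels and a numeric column of counts or fractions.
#'
#' @param p a [profile96()].
#' @param path TSV file.
#' @return `path` (write) or a `Profile96` (read).
#' @export
write_profile96 <- function(p, path) {
  stopifnot(inherits(p, "Profile96"))
  df <- data.frame(category = names(p$counts),
                   count = as.integer(p$counts),
                   fraction = profile_fractions(p))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile96
#' @param label profile label for the read object.
#' @export
read_profile96 <- function(path, label = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least two columns")
  if (!setequal(df[[1]], profile96_categories()))
    stop("first column must hold the 96 category labels")
  val_col <- if ("count" %in% names(df)) "count" else names(df)[2]
  w <- setNames(as.numeric(df[[val_col]]), df[[1]])
  profile96(w, label = label %||% sub("\\.[^.]*$", "", basename(path)))
}
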