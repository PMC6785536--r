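# Consensus gain/loss calling from three segmentations, call reporting
# with gene overlap, and cross-sample penetrance.

#' Consensus copy-number calls from three segmentations
#'
#' The genome is partitioned into atomic regions at the union of all three
#' methods' breakpoints. Each atomic region receives the mean log2 ratio of
#' its member probes; a method supports the region in a direction when its
#' covering segment's mean crosses the same threshold in that direction. A
#' region is called a gain (dually a loss) only if it spans at least
#' `min_probes` probes, its average log2 ratio exceeds `threshold`
#' (strictly; `< -threshold` for losses) and at least `min_support` of the
#' three methods support it. Adjacent regions with the same status are then
#' merged (supporting methods are unioned).
#'
#' @param seg_cbs,seg_haar,seg_dp [segmentation()]s over the same probes.
#' @param probes the common [probe_set()].
#' @param min_probes minimum probes ("oligos") per aberrant region, default 5.
#' @param threshold log2-ratio cutoff, default 0.25.
#' @param min_support minimum supporting methods, default 2 of 3.
#' @return a `ConsensusRegions` data frame: `chrom`, `start`, `end` (genomic
#'   span of member probes), `first`, `last` (probe indices), `n_probes`,
#'   `mean_log2`, `status` (`gain`/`loss`/`normal`), `support`
#'   (comma-separated method names).
#' @export
consensus_calls <- function(seg_cbs, seg_haar, seg_dp, probes,
                            min_probes = 5, threshold = 0.25,
                            min_support = 2) {
  segs <- list(seg_cbs, seg_haar, seg_dp)
  stopifnot(all(vapply(segs, inherits, TRUE, "Segmentation")),
            inherits(probes, "ProbeSet"))
  sig <- probe_signature(probes)
  if (!all(vapply(segs, attr, "", "probe_sig") == sig))
    stop("segmentations refer to a different probe universe")
  methods <- vapply(segs, attr, "", "method")
  cr <- chrom_ranges(probes)
  out <- list()
  for (ci in seq_len(nrow(cr))) {
    lo <- cr$first[ci]; hi <- cr$last[ci]
    cuts <- sort(unique(unlist(lapply(segs, function(s) {
      s$last[s$chrom == cr$chrom[ci] & s$last < hi]
    }))))
    starts <- c(lo, cuts + 1L)
    ends <- c(cuts, hi)
    for (k in seq_along(starts)) {
      f <- starts[k]; l <- ends[k]
      m <- mean(probes$log2ratio[f:l])
      sup_gain <- sup_loss <- character(0)
      for (si in seq_along(segs)) {
        s <- segs[[si]]
        row <- which(s$first <= f & s$last >= l)
        sm <- s$mean[row[1]]
        if (sm > threshold) sup_gain <- c(sup_gain, methods[si])
        if (sm < -threshold) sup_loss <- c(sup_loss, methods[si])
      }
      np <- l - f + 1L
      status <- "normal"
      support <- character(0)
      if (np >= min_probes && m > threshold && length(sup_gain) >= min_support) {
        status <- "gain"; support <- sup_gain
      } else if (np >= min_probes && m < -threshold &&
                 length(sup_loss) >= min_support) {
        status <- "loss"; support <- sup_loss
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = cr$chrom[ci], first = f, last = l, status = status,
        support = paste(support, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  # merge adjacent same-status regions within a chromosome
  merged <- list()
  for (r in seq_len(nrow(out))) {
    prev <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(prev) && prev$chrom == out$chrom[r] &&
        prev$status == out$status[r] && prev$last + 1L == out$first[r]) {
      prev$last <- out$last[r]
      sup <- union(strsplit(prev$support, ",")[[1]],
                   strsplit(out$support[r], ",")[[1]])
      prev$support <- paste(sup[sup != ""], collapse = ",")
      merged[[length(merged)]] <- prev
    } else {
      merged[[length(merged) + 1]] <- out[r, , drop = FALSE]
    }
  }
  res <- do.call(rbind, merged)
  res$start <- probes$start[res$first]
  res$end <- probes$end[res$last]
  res$n_probes <- res$last - res$first + 1L
  res$mean_log2 <- vapply(seq_len(nrow(res)), function(i)
    mean(probes$log2ratio[res$first[i]:res$last[i]]), numeric(1))
  res <- res[, c("chrom", "start", "end", "first", "last", "n_probes",
                 "mean_log2", "status", "support")]
  rownames(res) <- NULL
  structure(res, class = c("ConsensusRegions", "data.frame"),
            probe_sig = sig,
            params = list(min_probes = min_probes, threshold = threshold,
                          min_support = min_support))
}

#' @export
print.ConsensusRegions <- function(x, ...) {
  ab <- sum(x$status != "normal")
  cat(sprintf("ConsensusRegions: %d region(s), %d aberrant\n", nrow(x), ab))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Report aberrant consensus calls
#'
#' One row per gain/loss region with position, size, probe count, mean
#' log2 ratio, supporting methods and (when an annotation is supplied) the
#' overlapping gene symbols.
#'
#' @param regions a [consensus_calls()] result.
#' @param genes optional [transcript_annotation()].
#' @return data frame of aberrant regions (possibly empty).
#' @export
report_calls <- function(regions, genes = NULL) {
  stopifnot(inherits(regions, "ConsensusRegions"))
  ab <- as.data.frame(regions)[regions$status != "normal", , drop = FALSE]
  rownames(ab) <- NULL
  ab$size <- integer(nrow(ab)) + (ab$end - ab$start + 1L)
  ab$genes <- character(nrow(ab))
  if (!is.null(genes) && nrow(ab)) {
    stopifnot(inherits(genes, "TranscriptAnnotation"))
    rg <- GenomicRanges::GRanges(ab$chrom, IRanges::IRanges(ab$start, ab$end))
    gg <- annotation_granges(genes)
    hits <- GenomicRanges::findOverlaps(rg, gg, ignore.strand = TRUE)
    gl <- split(genes$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (i in names(gl)) {
      ab$genes[as.integer(i)] <- paste(sort(unique(gl[[i]])), collapse = ",")
    }
  }
  ab[, c("chrom", "start", "end", "size", "n_probes", "mean_log2",
         "status", "support", "genes")]
}

#' Write consensus calls as BED-compatible TSV
#'
#' Converts the 1-based inclusive call coordinates to BED's 0-based
#' half-open convention.
#'
#' @param report a [report_calls()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(report, path) {
  bed <- data.frame(chrom = report$chrom,
                    start = report$start - 1L,
                    end = report$end,
                    name = report$status,
                    score = round(report$mean_log2, 4),
                    strand = rep(".", nrow(report)),
                    n_probes = report$n_probes,
                    support = report$support,
                    genes = report$genes)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-sample penetrance of copy-number aberrations
#'
#' Partitions the genome at the union of all samples' aberrant-region
#' boundaries; for each atomic interval and direction the penetrance is the
#' fraction of samples calling that direction there (`k/n` for `n`
#' samples; 100% denotes a change shared by all samples).
#'
#' @param call_sets list (ideally named by sample) of [consensus_calls()]
#'   results or [report_calls()] data frames on a common coordinate system.
#' @return a `PenetranceTable` data frame: `chrom`, `start`, `end`,
#'   `direction`, `n_samples`, `k`, `fraction`.
#' @export
penetrance <- function(call_sets) {
  stopifnot(is.list(call_sets), length(call_sets) >= 2)
  nsamp <- length(call_sets)
  ab <- lapply(call_sets, function(cs) {
    df <- as.data.frame(cs)
    df[df$status %in% c("gain", "loss"),
       c("chrom", "start", "end", "status"), drop = FALSE]
  })
  all_ab <- do.call(rbind, ab)
  if (!nrow(all_ab)) {
    return(structure(data.frame(chrom = character(), start = integer(),
                                end = integer(), direction = character(),
                                n_samples = integer(), k = integer(),
                                fraction = numeric()),
                     class = c("PenetranceTable", "data.frame")))
  }
  out <- list()
  for (ch in unique(all_ab$chrom)) {
    sub <- all_ab[all_ab$chrom == ch, , drop = FALSE]
    pts <- sort(unique(c(sub$start, sub$end + 1L)))
    starts <- head(pts, -1); ends <- tail(pts, -1) - 1L
    for (k in seq_along(starts)) {
      for (dir in c("gain", "loss")) {
        cov <- vapply(ab, function(df) {
          any(df$chrom == ch & df$status == dir &
                df$start <= starts[k] & df$end >= ends[k])
        }, logical(1))
        if (any(cov)) {
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = starts[k], end = ends[k], direction = dir,
            n_samples = nsamp, k = sum(cov), fraction = sum(cov) / nsamp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[genomic_order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("PenetranceTable", "data.frame"))
}

#' Score consensus calls against planted truth
#'
#' Matches calls to true aberrant segments on genomic coordinates with the
#' same direction. A true segment counts as recovered when calls of its
#' direction cover at least `min_overlap` of its length; a call counts as
#' correct when at least `min_overlap` of its length lies inside true
#' segments of its direction.
#'
#' @param calls a [consensus_calls()] result or [report_calls()] frame.
#' @param truth data frame with `chrom`, `start`, `end`, `status`
#'   (gain/loss/normal), e.g. the `truth$segments` of [make_acgh()].
#' @param min_overlap covered-length fraction, default 0.5.
#' @return list with `recall`, `precision`, `n_true`, `n_calls`,
#'   `true_recovered`, `calls_correct`.
#' @export
score_consensus <- function(calls, truth, min_overlap = 0.5) {
  cdf <- as.data.frame(calls)
  cdf <- cdf[cdf$status %in% c("gain", "loss"), , drop = FALSE]
  tdf <- as.data.frame(truth)
  tdf <- tdf[tdf$status %in% c("gain", "loss"), , drop = FALSE]
  ovl <- function(a_start, a_end, b) {
    if (!nrow(b)) return(0L)
    sum(pmax(0L, pmin(a_end, b$end) - pmax(a_start, b$start) + 1L))
  }
  rec <- vapply(seq_len(nrow(tdf)), function(i) {
    b <- cdf[cdf$chrom == tdf$chrom[i] & cdf$status == tdf$status[i], ]
    ovl(tdf$start[i], tdf$end[i], b) >=
      min_overlap * (tdf$end[i] - tdf$start[i] + 1L)
  }, logical(1))
  cor <- vapply(seq_len(nrow(cdf)), function(i) {
    b <- tdf[tdf$chrom == cdf$chrom[i] & tdf$status == cdf$status[i], ]
    ovl(cdf$start[i], cdf$end[i], b) >=
      min_overlap * (cdf$end[i] - cdf$start[i] + 1L)
  }, logical(1))
  list(recall = if (nrow(tdf)) mean(rec) else 1,
       precision = if (nrow(cdf)) mean(cor) else 1,
       n_true = nrow(tdf), n_calls = nrow(cdf),
       true_recovered = sum(rec), calls_correct = sum(cor))
}
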