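# aCGH probe handling: Agilent-style input, QC filtering, log-ratio
# conversion and the derivative log ratio spread (DLRS) noise estimate.

PROBE_FLAGS <- c("gIsFeatNonUnifOL", "rIsFeatNonUnifOL",
                 "gIsSaturated", "rIsSaturated")

#' Construct a ProbeSet
#'
#' An ordered table of array probes with tumor/reference log2 ratios.
#' Probes are sorted by genomic position; duplicate spans are an error.
#'
#' @param chrom,start,end probe spans (1-based inclusive).
#' @param log2ratio finite tumor/reference log2 values.
#' @return a `ProbeSet` data frame.
#' @export
probe_set <- function(chrom, start, end = start, log2ratio) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), log2ratio = as.numeric(log2ratio),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("probe start > end")
  if (any(!is.finite(df$log2ratio))) stop("log2 ratios must be finite")
  df <- df[genomic_order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("chrom", "start", "end")]))
    stop("duplicate probe spans")
  structure(df, class = c("ProbeSet", "data.frame"))
}

#' @export
print.ProbeSet <- function(x, ...) {
  cat(sprintf("ProbeSet: %d probes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

# signature used to check that segmentations/calls refer to the same probes
probe_signature <- function(probes) {
  paste(nrow(probes), sum(as.numeric(probes$start)) %% 2^31,
        length(unique(probes$chrom)), sep = "/")
}

# per-chromosome global index ranges, in probe order
chrom_ranges <- function(probes) {
  ch <- probes$chrom
  n <- length(ch)
  if (!n) return(data.frame(chrom = character(), first = integer(),
                            last = integer(), stringsAsFactors = FALSE))
  brk <- which(ch[-n] != ch[-1])
  last <- c(brk, n)
  first <- c(1L, brk + 1L)
  data.frame(chrom = ch[last], first = first, last = last,
             stringsAsFactors = FALSE)
}

#' Load aCGH probes from an Agilent Feature-Extraction subset TSV
#'
#' Expects tab-separated columns `ProbeName`, `SystematicName`
#' (`chrN:start-end`), `LogRatio` (the reference/tumor log10 ratio written
#' by the feature-extraction software) and the four QC flag columns
#' `gIsFeatNonUnifOL`, `rIsFeatNonUnifOL`, `gIsSaturated`, `rIsSaturated`.
#' Processing follows the array pipeline's first two steps: the
#' reference/tumor log10 ratio is converted to a tumor/reference log2 ratio
#' (`log2(t/r) = -log10(r/t) / log10(2)`), and improper probes - any QC flag
#' set, or a raw log-ratio of exactly zero (undersaturated or otherwise
#' nonsensical spots are zeroed upstream) - are removed.
#'
#' @param path probe TSV.
#' @return a [probe_set()].
#' @export
load_probes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ProbeName", "SystematicName", "LogRatio", PROBE_FLAGS)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  raw <- suppressWarnings(as.numeric(tab$LogRatio))
  if (anyNA(raw)) {
    stop("non-numeric LogRatio at line ", which(is.na(raw))[1] + 1L,
         " of ", path)
  }
  m <- regmatches(tab$SystematicName,
                  regexec("^(\\S+?):(\\d+)-(\\d+)$", tab$SystematicName))
  bad <- vapply(m, length, 0L) != 4
  if (any(bad)) stop("unparseable SystematicName at line ", which(bad)[1] + 1L)
  chrom <- vapply(m, `[`, "", 2)
  start <- as.integer(vapply(m, `[`, "", 3))
  end <- as.integer(vapply(m, `[`, "", 4))
  flagged <- Reduce(`|`, lapply(PROBE_FLAGS, function(f) tab[[f]] == 1))
  keep <- !flagged & raw != 0
  probe_set(chrom[keep], start[keep], end[keep],
            log2ratio = -raw[keep] / log10(2))
}

#' Derivative log ratio spread
#'
#' Robust estimate of probe-level noise: the interquartile range of
#' consecutive-probe log-ratio differences scaled to a standard deviation,
#' `IQR(diff(x)) / (1.349 * sqrt(2))`. For a [probe_set()] the DLRS is
#' computed per chromosome and combined as the probe-count-weighted median,
#' which keeps genuine breakpoints from inflating the estimate.
#'
#' @param x ordered numeric log2 ratios of one chromosome (at least 3
#'   values), or a `ProbeSet`.
#' @param ... unused.
#' @return nonnegative spread estimate on the log2 scale.
#' @export
dlrs <- function(x, ...) UseMethod("dlrs")

#' @rdname dlrs
#' @export
dlrs.default <- function(x, ...) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("dlrs needs at least 3 values")
  IQR(diff(x)) / (1.349 * sqrt(2))
}

#' @rdname dlrs
#' @export
dlrs.ProbeSet <- function(x, ...) {
  cr <- chrom_ranges(x)
  cr <- cr[cr$last - cr$first + 1 >= 3, , drop = FALSE]
  if (!nrow(cr)) stop("no chromosome with at least 3 probes")
  vals <- mapply(function(f, l) dlrs.default(x$log2ratio[f:l]),
                 cr$first, cr$last)
  weighted_median(vals, cr$last - cr$first + 1)
}

#' Segmentation undo parameter from the array's noise level
#'
#' The minimum between-segment mean difference used to undo spurious splits
#' is tied to the calling cutoff: `UNDO.SD = 0.25 / DLRS`, so that the undo
#' threshold in noise-SD units corresponds to a 0.25 log2-ratio difference.
#'
#' @param probes a [probe_set()], or a numeric vector of log2 ratios.
#' @return positive scalar.
#' @export
undo_sd_param <- function(probes) {
  d <- if (inherits(probes, "ProbeSet")) dlrs(probes) else dlrs.default(probes)
  if (d <= 0) stop("DLRS is zero (noiseless input); bypass the undo step")
  0.25 / d
}
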