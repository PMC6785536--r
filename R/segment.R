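# Three independent breakpoint detectors over a ProbeSet:
#   - circular binary segmentation (CBS) with permutation p-values and
#     an undo step in noise-SD units,
#   - undecimated Haar-wavelet breakpoint detection with per-scale FDR
#     thresholding,
#   - penalized optimal partitioning by exact dynamic programming.
# Each returns a Segmentation: a partition of every chromosome's probe
# indices with per-segment means.

#' Construct a Segmentation
#'
#' @param method one of `"cbs"`, `"haar"`, `"dp"` (free text allowed for
#'   hand-built segmentations in tests).
#' @param first,last global probe indices (into `probes`) of each segment;
#'   segments must tile each chromosome with no gaps or overlaps.
#' @param probes the [probe_set()] the segmentation refers to.
#' @return a `Segmentation` data frame with columns `chrom`, `first`,
#'   `last`, `mean`.
#' @export
segmentation <- function(method, first, last, probes) {
  stopifnot(inherits(probes, "ProbeSet"), length(first) == length(last))
  o <- order(first)
  first <- as.integer(first[o]); last <- as.integer(last[o])
  if (any(first > last)) stop("segment first > last")
  cr <- chrom_ranges(probes)
  covered <- unlist(mapply(seq.int, first, last, SIMPLIFY = FALSE))
  if (length(covered) != nrow(probes) ||
      !identical(as.integer(covered), seq_len(nrow(probes))))
    stop("segments must partition the probe indices")
  cross <- vapply(seq_along(first), function(i) {
    ci <- findInterval(first[i], cr$first)
    last[i] > cr$last[ci]
  }, logical(1))
  if (any(cross)) stop("segment crosses a chromosome boundary")
  means <- vapply(seq_along(first), function(i)
    mean(probes$log2ratio[first[i]:last[i]]), numeric(1))
  structure(data.frame(
    chrom = probes$chrom[first], first = first, last = last, mean = means,
    stringsAsFactors = FALSE),
    class = c("Segmentation", "data.frame"),
    method = method, probe_sig = probe_signature(probes))
}

#' @export
print.Segmentation <- function(x, ...) {
  cat(sprintf("Segmentation (%s): %d segment(s)\n", attr(x, "method"), nrow(x)))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

# build a Segmentation from per-chromosome local breakpoints
# breaks_by_chrom: list (by chrom-range row) of local "last index of left
# segment" positions
segmentation_from_local_breaks <- function(method, probes, breaks_by_chrom) {
  cr <- chrom_ranges(probes)
  first <- integer(0); last <- integer(0)
  for (ci in seq_len(nrow(cr))) {
    b <- sort(unique(breaks_by_chrom[[ci]]))
    n <- cr$last[ci] - cr$first[ci] + 1L
    b <- b[b >= 1 & b < n]
    starts <- c(1L, b + 1L)
    ends <- c(b, n)
    first <- c(first, cr$first[ci] + starts - 1L)
    last <- c(last, cr$first[ci] + ends - 1L)
  }
  segmentation(method, first, last, probes)
}

# Outlier smoothing ahead of CBS break detection (the usual companion step
# to CBS): values further than k noise-SDs from a running median are clamped
# to that distance. Detection runs on the smoothed values; segment means are
# always computed from the raw values.
smooth_outliers <- function(x, k = 4, window = 5) {
  if (length(x) < window) return(x)
  med <- stats::runmed(x, window, endrule = "median")
  sdv <- dlrs.default(x)
  if (sdv <= 0) return(x)
  pmin(pmax(x, med - k * sdv), med + k * sdv)
}

# undo: re-merge adjacent segments whose mean difference falls below
# undo * sd_resid, removing the weakest boundary first
undo_breaks <- function(x, breaks, undo, sd_resid) {
  if (is.null(undo) || !length(breaks) || undo <= 0 || sd_resid <= 0)
    return(breaks)
  repeat {
    if (!length(breaks)) return(breaks)
    bounds <- c(0L, sort(breaks), length(x))
    means <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    d <- abs(diff(means))
    if (all(d >= undo * sd_resid)) return(sort(breaks))
    breaks <- sort(breaks)[-which.min(d)]
  }
}

#' Circular binary segmentation
#'
#' Recursive change-point detection: on each interval the maximal circular
#' arc statistic (a two-sample contrast of the arc against its complement)
#' is located, and the split is accepted when its permutation p-value falls
#' below `alpha`. Accepted splits are then revisited by an "undo" step that
#' re-merges adjacent segments whose mean difference is smaller than
#' `undo` times the chromosome's residual noise SD (estimated by [dlrs()]),
#' tying the minimum retained between-segment difference to the calling
#' cutoff when `undo = 0.25 / DLRS` (the default, see [undo_sd_param()]).
#' Singleton outliers are clamped toward a running median before break
#' detection (the customary smoothing companion of CBS; without it a single
#' heavy-tailed probe dominates the permutation reference and masks real
#' breakpoints); segment means are always computed from the raw values.
#' Deterministic for a fixed seed.
#'
#' @param probes a [probe_set()].
#' @param alpha split significance level, default 0.01.
#' @param nperm permutations per split test, default 1000.
#' @param undo undo threshold in noise-SD units; `NULL` (default) uses
#'   `0.25 / DLRS`; `0` disables the undo step.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return a [segmentation()] with method `"cbs"`.
#' @export
segment_cbs <- function(probes, alpha = 0.01, nperm = 1000, undo = NULL,
                        seed = NULL) {
  stopifnot(inherits(probes, "ProbeSet"))
  run <- function() {
    cr <- chrom_ranges(probes)
    if (is.null(undo)) {
      d <- tryCatch(dlrs(probes), error = function(e) 0)
      undo <- if (d > 0) 0.25 / d else 0
    }
    breaks <- vector("list", nrow(cr))
    for (ci in seq_len(nrow(cr))) {
      x <- probes$log2ratio[cr$first[ci]:cr$last[ci]]
      xs <- smooth_outliers(x)
      b <- cbs_recurse(xs, 1L, length(xs), alpha, nperm)
      sd_resid <- if (length(x) >= 3) dlrs.default(x) else 0
      breaks[[ci]] <- undo_breaks(x, b, undo, sd_resid)
    }
    segmentation_from_local_breaks("cbs", probes, breaks)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# returns local break positions within x[lo:hi] (relative to x, i.e. global
# within the chromosome)
cbs_recurse <- function(x, lo, hi, alpha, nperm) {
  n <- hi - lo + 1L
  if (n < 4) return(integer(0))
  res <- cbs_scan(x[lo:hi], as.integer(nperm), alpha)
  if (res$p >= alpha) return(integer(0))
  i <- res$i; j <- res$j
  cuts <- integer(0)
  if (i > 0) cuts <- c(cuts, lo + i - 1L)
  if (j < n) cuts <- c(cuts, lo + j - 1L)
  if (!length(cuts)) return(integer(0))
  bounds <- c(lo - 1L, cuts, hi)
  out <- cuts
  for (k in seq_len(length(bounds) - 1)) {
    out <- c(out, cbs_recurse(x, bounds[k] + 1L, bounds[k + 1], alpha, nperm))
  }
  sort(unique(out))
}

#' Haar-wavelet breakpoint detection
#'
#' Undecimated Haar-wavelet transform across dyadic scales: at scale `s`
#' the coefficient at probe `k` contrasts the mean of the next `2^(s-1)`
#' probes with the mean of the previous `2^(s-1)`. Local maxima of the
#' absolute coefficients are tested against a Gaussian null whose SD is the
#' robust noise estimate `mad(diff(x)) / sqrt(2)`; within each scale the
#' peak p-values are thresholded by Benjamini-Hochberg FDR at `fdr_q`.
#' Significant peaks are unified across scales (strongest first, suppressing
#' neighbours within the peak's own half-window).
#'
#' @param probes a [probe_set()].
#' @param fdr_q FDR level for breakpoint acceptance, default 0.001.
#' @param max_scale largest dyadic scale (half-window `2^(max_scale-1)`);
#'   capped by the chromosome length.
#' @return a [segmentation()] with method `"haar"`.
#' @export
segment_haar <- function(probes, fdr_q = 0.001, max_scale = 6) {
  stopifnot(inherits(probes, "ProbeSet"))
  cr <- chrom_ranges(probes)
  breaks <- vector("list", nrow(cr))
  for (ci in seq_len(nrow(cr))) {
    x <- probes$log2ratio[cr$first[ci]:cr$last[ci]]
    breaks[[ci]] <- haar_breaks(x, fdr_q, max_scale)
  }
  segmentation_from_local_breaks("haar", probes, breaks)
}

haar_breaks <- function(x, fdr_q, max_scale) {
  n <- length(x)
  if (n < 4) return(integer(0))
  sigma <- mad(diff(x)) / sqrt(2)
  S <- c(0, cumsum(x))
  scales <- seq_len(max(1, min(max_scale, floor(log2(n)) - 1)))
  peaks <- list()
  for (s in scales) {
    h <- 2L^(s - 1L)
    if (2L * h > n) break
    k <- seq.int(h, n - h)
    w <- (S[k + h + 1] - S[k + 1]) - (S[k + 1] - S[k - h + 1])
    w <- w / sqrt(2 * h)
    aw <- abs(w)
    # non-maximum suppression within the half-window
    is_peak <- vapply(seq_along(k), function(m) {
      win <- seq(max(1, m - h), min(length(k), m + h))
      aw[m] > 0 && aw[m] == max(aw[win]) && match(max(aw[win]), aw[win]) ==
        which(win == m)
    }, logical(1))
    if (!any(is_peak)) next
    km <- k[is_peak]; am <- aw[is_peak]
    if (sigma < 1e-12) {
      keep <- am > 1e-12
    } else {
      pv <- 2 * pnorm(-am / sigma)
      keep <- p.adjust(pv, method = "BH") <= fdr_q
    }
    if (any(keep)) {
      peaks[[length(peaks) + 1]] <- data.frame(
        k = km[keep], z = if (sigma < 1e-12) Inf else am[keep] / sigma,
        h = h)
    }
  }
  if (!length(peaks)) return(integer(0))
  pk <- do.call(rbind, peaks)
  pk <- pk[order(-pk$z, pk$h), , drop = FALSE]
  accepted <- integer(0)
  radius <- integer(0)
  for (m in seq_len(nrow(pk))) {
    if (!length(accepted) ||
        all(abs(accepted - pk$k[m]) > pmax(radius, pk$h[m]))) {
      accepted <- c(accepted, pk$k[m])
      radius <- c(radius, pk$h[m])
    }
  }
  sort(accepted)
}

#' Penalized optimal partitioning
#'
#' Exact dynamic-programming minimization of the within-segment squared
#' error plus `penalty` per segment, the classical least-squares
#' change-point formulation. The default penalty is `2 * sigma^2 * log(n)`
#' per chromosome, with `sigma` the chromosome's [dlrs()] noise estimate
#' (floored at a small positive value so that noiseless input still favours
#' the most parsimonious exact fit). As `penalty -> Inf` the result
#' degenerates to a single segment per chromosome.
#'
#' @param probes a [probe_set()].
#' @param penalty positive model-selection constant; `NULL` for the default.
#' @return a [segmentation()] with method `"dp"`.
#' @export
segment_dp <- function(probes, penalty = NULL) {
  stopifnot(inherits(probes, "ProbeSet"))
  cr <- chrom_ranges(probes)
  breaks <- vector("list", nrow(cr))
  for (ci in seq_len(nrow(cr))) {
    x <- probes$log2ratio[cr$first[ci]:cr$last[ci]]
    pen <- penalty
    if (is.null(pen)) {
      sigma <- if (length(x) >= 3) max(dlrs.default(x), 1e-6) else 1e-6
      pen <- 2 * sigma^2 * log(length(x))
    }
    breaks[[ci]] <- dp_breaks(x, pen)
  }
  segmentation_from_local_breaks("dp", probes, breaks)
}

dp_breaks <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(integer(0))
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  # cost of segment (i+1)..j
  segcost <- function(i, j) S2[j + 1] - S2[i + 1] - (S[j + 1] - S[i + 1])^2 / (j - i)
  F <- c(-penalty, rep(NA_real_, n))
  prev <- integer(n)
  for (j in seq_len(n)) {
    i <- 0:(j - 1)
    cand <- F[i + 1] + (S2[j + 1] - S2[i + 1] -
                          (S[j + 1] - S[i + 1])^2 / (j - i)) + penalty
    best <- which.min(cand)
    F[j + 1] <- cand[best]
    prev[j] <- i[best]
  }
  breaks <- integer(0)
  j <- n
  while (j > 0) {
    i <- prev[j]
    if (i > 0) breaks <- c(i, breaks)
    j <- i
  }
  breaks
}
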