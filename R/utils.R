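# shared helpers: chromosome ordering, complements, weighted median

CHROM_CANONICAL <- c(as.character(1:22), "X", "Y")

#' Rank chromosomes in natural genomic order
#'
#' Orders 1..22, X, Y first (with or without a "chr" prefix); any other
#' contig follows lexicographically.
#'
#' @param chrom character vector of contig names.
#' @return integer rank usable with [order()].
#' @export
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", as.character(chrom))
  r <- match(base, CHROM_CANONICAL)
  unk <- is.na(r)
  if (any(unk)) {
    lev <- sort(unique(base[unk]))
    r[unk] <- length(CHROM_CANONICAL) + match(base[unk], lev)
  }
  r
}

genomic_order <- function(chrom, pos) {
  order(chrom_rank(chrom), pos)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# reverse-complement of 3-mers, vectorized
revcomp3 <- function(s) {
  m <- comp_base(s)
  paste0(substr(m, 3, 3), substr(m, 2, 2), substr(m, 1, 1))
}

weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
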