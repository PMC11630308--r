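#' @importFrom stats cor cor.test p.adjust phyper pchisq pnorm prcomp quantile
#'   rbinom rlnorm rnorm runif rpois setNames wilcox.test hclust cutree
#'   as.dist lm coef complete.cases median var sd
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a DNA string (first frame, trailing partial codon dropped;
#' ambiguous codons become X)
#' @keywords internal
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  aa <- Biostrings::GENETIC_CODE[substring(x, seq(1L, n, 3L), seq(3L, n, 3L))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## split a DNA string into codons
codons_of <- function(x) {
  stopifnot(nchar(x) %% 3L == 0L)
  substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
}

## uniform random DNA
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## 0-based half-open interval matrix constructor / validator
iv_mat <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (any(m[, "end"] <= m[, "start"])) stop("interval end must exceed start")
  if (any(m[, "start"] < 0L)) stop("interval start must be non-negative")
  m[order(m[, "start"]), , drop = FALSE]
}

## convert 0-based half-open matrix to IRanges (1-based closed)
iv_to_iranges <- function(m) IRanges::IRanges(start = m[, "start"] + 1L, end = m[, "end"])

## total bases covered by the union of 0-based half-open intervals
iv_union_width <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(iv_to_iranges(m))))
}

## overlap width between two interval sets (0-based half-open matrices)
iv_overlap_width <- function(a, b) {
  if (is.null(a) || nrow(a) == 0L || is.null(b) || nrow(b) == 0L) return(0L)
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(iv_to_iranges(a)),
                                        IRanges::reduce(iv_to_iranges(b)))))
}
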