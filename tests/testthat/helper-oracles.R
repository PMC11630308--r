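## Independent oracles, deliberately written with different algorithms than
## the implementations they check.

## BLOSUM62 with X scored 0, as the documented scoring convention
oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

## quadratic-space Gotoh local alignment (gap of length k costs open + k*ext)
sw_oracle <- function(a, b, open = 11, ext = 1) {
  sm <- oracle_blosum62()
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  n <- length(va); m <- length(vb)
  M <- Ix <- Iy <- matrix(-Inf, n + 1L, m + 1L)
  M[1L, ] <- 0
  M[, 1L] <- 0
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      Ix[i, j] <- max(M[i - 1L, j] - open - ext, Ix[i - 1L, j] - ext)
      Iy[i, j] <- max(M[i, j - 1L] - open - ext, Iy[i, j - 1L] - ext)
      M[i, j] <- max(0, max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                            Iy[i - 1L, j - 1L]) + sm[va[i - 1L], vb[j - 1L]])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

## hypergeometric upper tail by explicit summation
fisher_sum_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## hypergeometric upper tail by brute-force enumeration of all C(N, n) draws
fisher_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)   # items 1..K carry the term
}

## Pearson chi-square from the textbook formula
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

## Mann-Whitney U by exhaustive pair counting
mwu_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

## IUPAC motif count by per-offset letter-set checking (both strands)
motif_count_oracle <- function(promoter, iupac) {
  allowed <- lapply(strsplit(toupper(iupac), "")[[1L]], function(code)
    strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]])
  count_one <- function(seqstr) {
    v <- strsplit(seqstr, "")[[1L]]
    w <- length(allowed)
    if (length(v) < w) return(0L)
    ok <- rep(TRUE, length(v) - w + 1L)
    for (i in seq_len(w))
      ok <- ok & v[i:(length(v) - w + i)] %in% allowed[[i]]
    sum(ok)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(promoter)))
  count_one(promoter) + count_one(rc)
}

## union coverage of 0-based half-open intervals by per-base boolean OR
union_cov_oracle <- function(starts, ends, L) {
  covered <- rep(FALSE, L)
  for (i in seq_along(starts)) {
    lo <- max(0L, starts[i]) + 1L
    hi <- min(L, ends[i])
    if (hi >= lo) covered[lo:hi] <- TRUE
  }
  sum(covered) / L
}

## brute-force six-frame ORF peptides (start-to-stop), independent of the
## package's scanner: walks codons explicitly
orf_oracle <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  peps <- character(0)
  for (s in c(dna, rc)) {
    v <- strsplit(s, "")[[1L]]
    for (f in 0:2) {
      idx <- seq(f + 1L, length(v) - 2L, by = 3L)
      if (!length(idx)) next
      cods <- vapply(idx, function(i) paste(v[i:(i + 2L)], collapse = ""), "")
      aa <- unname(code[cods])
      aa[is.na(aa)] <- "X"
      i <- 1L
      while (i <= length(aa)) {
        if (aa[i] == "M") {
          j <- i
          while (j <= length(aa) && aa[j] != "*") j <- j + 1L
          if (j <= length(aa)) {
            peps <- c(peps, paste(aa[i:(j - 1L)], collapse = ""))
            i <- j   # first M per inter-stop segment only
          }
        }
        i <- i + 1L
      }
    }
  }
  peps
}
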