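## Protein-level homology search against relative proteomes.
##
## Local (Smith-Waterman) alignment with affine gaps; defaults BLOSUM62 with
## gap open 11 / extend 1, so a gap of length k costs 11 + k. Significance via
## the Karlin-Altschul formula E = K * m * n * exp(-lambda * S) with the
## published gapped BLOSUM62(11,1) constants lambda = 0.267, K = 0.041 and no
## edge-length correction. At desk scale the full dynamic program is run for
## every pair; no seeded heuristics.

#' Default protein scoring parameters
#'
#' BLOSUM62 with the X row/column zeroed (unknown residues score 0), affine
#' gap open 11 / extend 1, and the gapped Karlin-Altschul constants for that
#' scoring system.
#'
#' @return list(matrix, gap_open, gap_extend, lambda, K)
#' @export
protein_scoring <- function() {
  mat <- get_blosum62x()
  list(matrix = mat, gap_open = 11, gap_extend = 1, lambda = 0.267, K = 0.041)
}

get_blosum62x <- local({
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

#' Karlin-Altschul expectation for a raw local alignment score
#' @param S raw score
#' @param m,n lengths of the two unaligned peptides
#' @param lambda,K statistical constants for the scoring system
#' @return E-value
#' @export
karlin_evalue <- function(S, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * S)
}

#' Bit score of a raw local alignment score
#' @inheritParams karlin_evalue
#' @export
bit_score <- function(S, lambda = 0.267, K = 0.041) {
  (lambda * S - log(K)) / log(2)
}

#' Locally align two peptides
#'
#' Smith-Waterman with affine gaps. Returns the optimal local alignment with
#' its raw score, bit score, Karlin-Altschul E-value (m, n are the full
#' peptide lengths), identity over aligned columns, and the aligned spans on
#' both peptides (1-based inclusive).
#'
#' @param query,target peptide strings (20-letter alphabet, X tolerated)
#' @param scoring as \code{\link{protein_scoring}}
#' @return list with score, bitscore, evalue, identity, query_span, target_span
#' @export
align_protein <- function(query, target, scoring = protein_scoring()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty peptide sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  S <- Biostrings::score(pa)
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  cols <- strsplit(p, "")[[1L]] == strsplit(s, "")[[1L]]
  list(score = S,
       bitscore = bit_score(S, scoring$lambda, scoring$K),
       evalue = karlin_evalue(S, nchar(query), nchar(target),
                              scoring$lambda, scoring$K),
       identity = if (length(cols)) mean(cols) else 0,
       query_span = c(S4Vectors::start(Biostrings::pattern(pa)),
                      S4Vectors::end(Biostrings::pattern(pa))),
       target_span = c(S4Vectors::start(Biostrings::subject(pa)),
                       S4Vectors::end(Biostrings::subject(pa))))
}

#' All-vs-all local alignment scores between two proteomes
#'
#' @param queries,targets named character vectors or \code{AAStringSet}
#' @param scoring as \code{\link{protein_scoring}}
#' @return list(score, evalue): query x target matrices
#' @export
protein_search <- function(queries, targets, scoring = protein_scoring()) {
  q <- Biostrings::AAStringSet(queries)
  t <- Biostrings::AAStringSet(targets)
  S <- matrix(0, length(q), length(t), dimnames = list(names(q), names(t)))
  for (i in seq_along(q)) {
    S[i, ] <- Biostrings::pairwiseAlignment(
      t, q[[i]], type = "local", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE)
  }
  E <- scoring$K * outer(Biostrings::width(q), Biostrings::width(t)) *
    exp(-scoring$lambda * S)
  dimnames(E) <- dimnames(S)
  list(score = S, evalue = E)
}

## run protein_search focal vs every relative proteome (cached per call site)
search_all <- function(focal_proteome, relative_proteomes, scoring = protein_scoring()) {
  lapply(relative_proteomes, function(tp) protein_search(focal_proteome, tp, scoring))
}

#' Candidate de novo genes: no protein homolog in any relative
#'
#' A focal gene is a candidate iff it has no local alignment with
#' E <= \code{e_threshold} against any relative proteome.
#'
#' @param focal_proteome named peptides (character or AAStringSet)
#' @param relative_proteomes named list of peptide sets, one per relative
#'   genome (duplicated genome ids are collapsed)
#' @param e_threshold E-value cutoff (default 1e-5)
#' @param searches optional precomputed result of an internal search (one
#'   \code{\link{protein_search}} per relative), to avoid re-alignment
#' @return character vector of candidate gene ids
#' @export
candidate_filter <- function(focal_proteome, relative_proteomes, e_threshold = 1e-5,
                             searches = NULL) {
  relative_proteomes <- relative_proteomes[!duplicated(names(relative_proteomes))]
  if (is.null(searches)) searches <- search_all(focal_proteome, relative_proteomes)
  ids <- names(Biostrings::AAStringSet(focal_proteome))
  has_hit <- rep(FALSE, length(ids))
  for (sr in searches) {
    if (ncol(sr$evalue) == 0L) next
    has_hit <- has_hit | apply(sr$evalue <= e_threshold, 1L, any)
  }
  ids[!has_hit]
}

#' Conserved genes: one-to-one reciprocal best hit in every relative
#'
#' A focal gene is conserved iff in every relative proteome it has a unique
#' best-scoring hit with E <= threshold whose own unique best hit among the
#' focal proteins is that gene (reciprocal best hit; score ties disqualify).
#'
#' @inheritParams candidate_filter
#' @return character vector of conserved gene ids
#' @export
conserved_set <- function(focal_proteome, relative_proteomes, e_threshold = 1e-5,
                          searches = NULL) {
  relative_proteomes <- relative_proteomes[!duplicated(names(relative_proteomes))]
  if (is.null(searches)) searches <- search_all(focal_proteome, relative_proteomes)
  ids <- names(Biostrings::AAStringSet(focal_proteome))
  ok <- rep(TRUE, length(ids))
  names(ok) <- ids
  for (sr in searches) {
    S <- sr$score
    E <- sr$evalue
    if (ncol(S) == 0L) { ok[] <- FALSE; next }
    rbh <- vapply(seq_along(ids), function(i) {
      j <- unique_argmax(S[i, ])
      if (is.na(j) || E[i, j] > e_threshold) return(FALSE)
      i2 <- unique_argmax(S[, j])
      !is.na(i2) && i2 == i
    }, TRUE)
    ok <- ok & rbh
  }
  ids[ok]
}

## index of a strict unique maximum, NA when tied
unique_argmax <- function(x) {
  j <- which.max(x)
  if (sum(x == x[j]) > 1L) NA_integer_ else j
}

#' Read a tabular protein hit file (outfmt-6-like TSV)
#'
#' Adapter so an external search engine can replace the built-in alignment:
#' columns query, target, identity, length, evalue, bitscore (no header).
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_hit_table <- function(path) {
  read.delim(path, header = FALSE, stringsAsFactors = FALSE,
             col.names = c("query", "target", "identity", "length",
                           "evalue", "bitscore"))
}

#' Write a tabular hit file from an internal search
#' @param search result of \code{\link{protein_search}}
#' @param path output file
#' @param e_max only hits with E <= e_max are written (default 10)
#' @export
write_hit_table <- function(search, path, e_max = 10) {
  idx <- which(search$evalue <= e_max, arr.ind = TRUE)
  df <- data.frame(query = rownames(search$score)[idx[, 1L]],
                   target = colnames(search$score)[idx[, 2L]],
                   identity = NA_real_, length = NA_integer_,
                   evalue = search$evalue[idx],
                   bitscore = bit_score(search$score[idx]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Candidate filter from precomputed tabular hits
#'
#' @param focal_ids all focal gene ids considered
#' @param hit_tables named list (one data.frame per relative genome, as from
#'   \code{\link{read_hit_table}})
#' @param e_threshold E-value cutoff
#' @return character vector of candidate gene ids
#' @export
candidate_filter_from_hits <- function(focal_ids, hit_tables, e_threshold = 1e-5) {
  hit_tables <- hit_tables[!duplicated(names(hit_tables))]
  hit <- unique(unlist(lapply(hit_tables, function(df)
    df$query[df$evalue <= e_threshold])))
  setdiff(focal_ids, hit)
}
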