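## Per-gene structural, codon-usage and disorder statistics, and the
## conserved-vs-de novo class comparisons.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

## amino acids with a degenerate codon family (Met, Trp, stops excluded)
degenerate_families <- local({
  fam <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
  fam[["*"]] <- NULL
  fam[lengths(fam) > 1L]
})

#' GC content overall and by codon position
#'
#' @param cds codon-clean DNA string (length divisible by 3, no N)
#' @return named numeric vector GC, GC1, GC2, GC3
#' @export
gc_by_codon_position <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  b <- strsplit(cds, "")[[1L]]
  gc <- b %in% c("G", "C")
  pos <- rep_len(1:3, n)
  c(GC = mean(gc), GC1 = mean(gc[pos == 1L]), GC2 = mean(gc[pos == 2L]),
    GC3 = mean(gc[pos == 3L]))
}

#' Infer the optimal codon of each degenerate amino-acid family
#'
#' The reference set is the top \code{top_fraction} of genes by expression
#' level; the optimal codon of each family is its most frequent codon there
#' (alphabetical tie-break). Families unseen in the reference set fall back
#' to the genome-wide most frequent codon, with a warning. Met, Trp and stop
#' codons are excluded.
#'
#' @param cds_set named character vector of codon-clean CDS
#' @param expression_levels named numeric vector (same genes)
#' @param top_fraction fraction of genes forming the reference set
#' @return named character vector amino_acid -> optimal codon
#' @export
infer_optimal_codons <- function(cds_set, expression_levels, top_fraction = 0.1) {
  if (length(cds_set) < 20L) stop("need at least 20 reference genes")
  expression_levels <- expression_levels[names(cds_set)]
  n_ref <- max(1L, floor(length(cds_set) * top_fraction))
  ref <- names(sort(expression_levels, decreasing = TRUE))[seq_len(n_ref)]
  count_codons <- function(set) {
    tab <- table(unlist(lapply(set, codons_of)))
    setNames(as.integer(tab), names(tab))
  }
  ref_counts <- count_codons(cds_set[ref])
  all_counts <- NULL
  out <- character(0)
  for (aa in names(degenerate_families)) {
    cods <- sort(degenerate_families[[aa]])
    cnt <- ref_counts[cods]
    cnt[is.na(cnt)] <- 0L
    if (sum(cnt) == 0L) {
      if (is.null(all_counts)) all_counts <- count_codons(cds_set)
      cnt <- all_counts[cods]
      cnt[is.na(cnt)] <- 0L
      warning("family ", aa, " absent from reference set; ",
              "using genome-wide frequencies")
    }
    out[[aa]] <- cods[which.max(cnt)]  # which.max: first max = alphabetical
  }
  out
}

#' Frequency of optimal codons
#'
#' Fraction of a CDS's degenerate-family codons that are the optimal codon of
#' their family; Met, Trp and stop codons count in neither numerator nor
#' denominator.
#'
#' @param cds codon-clean DNA string
#' @param optimal named map amino_acid -> codon, as from
#'   \code{\link{infer_optimal_codons}}
#' @return fraction in [0,1], or NA when the CDS has no eligible codon
#' @export
fop <- function(cds, optimal) {
  cods <- codons_of(cds)
  aas <- GENETIC_CODE_TABLE[cods]
  eligible <- aas %in% names(degenerate_families)
  if (!any(eligible)) return(NA_real_)
  mean(cods[eligible] == optimal[aas[eligible]])
}

## Kyte-Doolittle hydropathy, normalized to [0,1] over its [-4.5, 4.5] range
KD_NORM <- (c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2) + 4.5) / 9
CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

#' Sliding-window intrinsic-disorder proxy
#'
#' FoldIndex-style score per residue: 2.785 <H> - |<R>| - 1.151 over a
#' centered window (default 51; truncated at the ends and for shorter
#' peptides), with <H> the mean normalized Kyte-Doolittle hydrophobicity and
#' <R> the mean net charge. The disorder fraction is the proportion of
#' residues with a negative window score, in [0,1] (0 ordered, 1 disordered).
#' Non-standard residues are skipped. This is a documented proxy, not a
#' re-implementation of any external disorder predictor; externally computed
#' per-gene scores can be supplied to \code{\link{build_feature_table}}.
#'
#' @param peptide amino-acid string
#' @param window window size in residues
#' @return fraction of residues predicted disordered
#' @export
isd_proxy <- function(peptide, window = 51L) {
  aa <- strsplit(peptide, "")[[1L]]
  aa <- aa[aa %in% names(KD_NORM)]
  n <- length(aa)
  if (n == 0L) return(NA_real_)
  h <- KD_NORM[aa]
  r <- ifelse(aa %in% names(CHARGE), CHARGE[aa], 0)
  r[is.na(r)] <- 0
  half <- (min(window, n) - 1L) %/% 2L
  ch <- c(0, cumsum(h)); cr <- c(0, cumsum(r))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  w <- hi - lo + 1L
  mh <- (ch[hi + 1L] - ch[lo]) / w
  mr <- (cr[hi + 1L] - cr[lo]) / w
  mean(2.785 * mh - abs(mr) - 1.151 < 0)
}

#' Build the per-gene feature table
#'
#' Structural lengths come from the gene models (intron total = gene span -
#' exon total); GC/GC1/GC2/GC3 and Fop from the codon-clean CDS (flagged
#' genes and N-containing CDS get NA); the disorder fraction from the
#' translated peptide (or from \code{isd_override} where provided);
#' expression level and breadth are joined from the expression matrix.
#'
#' @param genome focal \code{\link{GenomeRecord}}
#' @param expr \code{\link{ExpressionMatrix}} or NULL
#' @param optimal optimal-codon map; inferred from the data when NULL
#' @param isd_override optional named numeric vector of externally computed
#'   per-gene disorder scores that replaces the built-in proxy
#' @param top_fraction passed to \code{\link{infer_optimal_codons}}
#' @return data.frame, one row per gene
#' @export
build_feature_table <- function(genome, expr = NULL, optimal = NULL,
                                isd_override = NULL, top_fraction = 0.1) {
  genes <- genome$genes
  ids <- names(genes)
  cds_seqs <- vapply(genes, extract_cds, "", chromosomes = genome$chromosomes)
  clean <- vapply(genes, function(g) isTRUE(g$codon_clean), TRUE) &
    !grepl("[^ACGT]", cds_seqs)
  lvl <- bre <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(expr)) {
    common <- intersect(ids, rownames(expr$fpkm))
    lvl[common] <- vapply(common, expression_level, 0, mat = expr)
    bre[common] <- vapply(common, expression_breadth, 0L, mat = expr)
  }
  if (is.null(optimal)) {
    ref_ids <- ids[clean & !is.na(lvl)]
    optimal <- tryCatch(
      suppressWarnings(infer_optimal_codons(cds_seqs[ref_ids], lvl[ref_ids],
                                            top_fraction = top_fraction)),
      error = function(e) {
        message("optimal-codon inference skipped (", conditionMessage(e),
                "); Fop reported as NA")
        NULL
      })
  }
  gc <- matrix(NA_real_, length(ids), 4L,
               dimnames = list(ids, c("GC", "GC1", "GC2", "GC3")))
  fop_v <- isd_v <- setNames(rep(NA_real_, length(ids)), ids)
  for (i in seq_along(ids)) {
    if (!clean[i]) next
    gc[i, ] <- gc_by_codon_position(cds_seqs[i])
    if (!is.null(optimal)) fop_v[i] <- fop(cds_seqs[i], optimal)
    pep <- sub("\\*$", "", translate_dna(cds_seqs[i]))
    isd_v[i] <- isd_proxy(pep)
  }
  if (!is.null(isd_override)) {
    ov <- intersect(names(isd_override), ids)
    isd_v[ov] <- isd_override[ov]
  }
  span <- vapply(genes, function(g) diff(gene_span(g)), 0L)
  exon_total <- vapply(genes, function(g) sum(g$exons[, 2L] - g$exons[, 1L]), 0L)
  data.frame(
    gene_id = ids,
    gene_length = span,
    cds_length = nchar(cds_seqs),
    exon_count = vapply(genes, function(g) nrow(g$exons), 0L),
    exon_length_total = exon_total,
    intron_length_total = span - exon_total,
    GC = gc[, "GC"], GC1 = gc[, "GC1"], GC2 = gc[, "GC2"], GC3 = gc[, "GC3"],
    Fop = fop_v, ISD = isd_v, level = lvl, breadth = bre,
    codon_clean = clean, stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare feature distributions between two gene classes
#'
#' Two-sided Mann-Whitney U tests (normal approximation with tie correction)
#' per feature, plus Spearman correlation between GC and the disorder score
#' within each class.
#'
#' @param features data.frame from \code{\link{build_feature_table}}
#' @param class_a,class_b gene id sets
#' @param feature_cols features to test
#' @return list(tests = data.frame(feature, U, p, median_a, median_b),
#'   gc_isd = data.frame(class, rho, p))
#' @export
compare_classes <- function(features, class_a, class_b,
                            feature_cols = c("gene_length", "cds_length",
                                             "intron_length_total", "exon_count",
                                             "GC", "GC1", "GC2", "GC3", "Fop",
                                             "ISD", "level", "breadth")) {
  fa <- features[features$gene_id %in% class_a, , drop = FALSE]
  fb <- features[features$gene_id %in% class_b, , drop = FALSE]
  if (nrow(fa) == 0L || nrow(fb) == 0L) stop("both classes must be nonempty")
  rows <- lapply(feature_cols, function(fc) {
    xa <- fa[[fc]][!is.na(fa[[fc]])]
    xb <- fb[[fc]][!is.na(fb[[fc]])]
    if (length(xa) < 3L || length(xb) < 3L) {
      warning("class size < 3 for feature ", fc, "; test skipped")
      return(data.frame(feature = fc, U = NA_real_, p = NA_real_,
                        median_a = median(xa), median_b = median(xb)))
    }
    wt <- wilcox.test(xa, xb, exact = FALSE, correct = FALSE)
    data.frame(feature = fc, U = unname(wt$statistic), p = wt$p.value,
               median_a = median(xa), median_b = median(xb))
  })
  gc_isd <- do.call(rbind, lapply(list(a = fa, b = fb), function(f) {
    keep <- !is.na(f$GC) & !is.na(f$ISD)
    if (sum(keep) < 3L)
      return(data.frame(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(f$GC[keep], f$ISD[keep], method = "spearman"))
    data.frame(rho = unname(ct$estimate), p = ct$p.value)
  }))
  gc_isd <- data.frame(class = c("a", "b"), gc_isd, row.names = NULL)
  list(tests = do.call(rbind, rows), gc_isd = gc_isd)
}
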