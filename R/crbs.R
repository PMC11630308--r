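## Promoter cis-regulatory binding sites: extraction of the 2-kb sequence
## upstream of the start codon, IUPAC consensus scanning on both strands, and
## the confidence-interval exceedance significance rule: an observed motif
## count is significant iff it exceeds the upper bound of the 95% CI around
## the expected count AND the expected count itself is below a cap.

#' Extract the promoter of a gene
#'
#' The \code{length} bases 5' of the CDS start on the coding strand,
#' truncated (with a warning) at the chromosome edge.
#'
#' @param gene \code{\link{GeneModel}} with a CDS
#' @param chromosomes named character vector of sequences
#' @param length promoter length in nt (default 2000)
#' @return DNA string on the coding strand
#' @export
extract_promoter <- function(gene, chromosomes, length = 2000L) {
  chrom <- chromosomes[[gene$chrom]]
  if (is.null(chrom)) stop("unknown chromosome '", gene$chrom, "'")
  if (gene$strand == "+") {
    cds_start <- min(gene$cds[, "start"])
    a <- cds_start - length
    if (a < 0L) {
      warning("promoter of '", gene$gene_id, "' truncated at chromosome start")
      a <- 0L
    }
    substr(chrom, a + 1L, cds_start)
  } else {
    cds_end <- max(gene$cds[, "end"])
    b <- cds_end + length
    if (b > nchar(chrom)) {
      warning("promoter of '", gene$gene_id, "' truncated at chromosome end")
      b <- nchar(chrom)
    }
    revcomp(substr(chrom, cds_end + 1L, b))
  }
}

#' Count motif occurrences in a promoter
#'
#' Exact IUPAC consensus matches at every offset on both strands; overlapping
#' matches are counted, and a palindromic site is counted once per strand.
#'
#' @param promoter DNA string
#' @param iupac motif consensus (IUPAC codes)
#' @return integer count
#' @export
scan_motif <- function(promoter, iupac) {
  if (nchar(promoter) < nchar(iupac)) return(0L)
  pat <- Biostrings::DNAString(toupper(iupac))
  subj <- Biostrings::DNAString(promoter)
  fixed <- c(pattern = FALSE, subject = TRUE)  # IUPAC in motif, literal subject
  Biostrings::countPattern(pat, subj, fixed = fixed) +
    Biostrings::countPattern(Biostrings::reverseComplement(pat), subj, fixed = fixed)
}

## per-position match probability of an IUPAC motif under the promoter's own
## base composition (independence across positions)
motif_match_prob <- function(promoter, iupac) {
  b <- strsplit(promoter, "")[[1L]]
  b <- b[b %in% DNA_BASES]
  if (!length(b)) return(0)
  p <- table(factor(b, levels = DNA_BASES)) / length(b)
  prod(vapply(strsplit(toupper(iupac), "")[[1L]], function(code) {
    sum(p[strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]]])
  }, 0))
}

#' Significance of an observed motif count
#'
#' The expected count under the null is E = 2 (L - w + 1) prod_i p(allowed at
#' i), with base probabilities from the promoter's own composition and the
#' factor 2 for the two strands. The 95% upper bound is E + 1.96 sqrt(E)
#' (normal approximation to a Poisson count; the exact Poisson quantile is
#' available via \code{ci_method = "poisson"}). The count is significant iff
#' observed > ci_upper AND E <= \code{expected_cap}.
#'
#' @param observed motif count from \code{\link{scan_motif}}
#' @param promoter DNA string
#' @param motif one-row data.frame (motif_id, iupac, tf_family) or a list
#' @param alpha significance level of the CI (default 0.05)
#' @param expected_cap maximum expected count for a callable motif
#' @param ci_method "normal" (default) or "poisson"
#' @return data.frame(motif_id, observed, expected, ci_upper, significant)
#' @export
crbs_significance <- function(observed, promoter, motif, alpha = 0.05,
                              expected_cap = 5.0, ci_method = c("normal", "poisson")) {
  ci_method <- match.arg(ci_method)
  w <- nchar(motif$iupac)
  L <- nchar(promoter)
  E <- if (L < w) 0 else 2 * (L - w + 1L) * motif_match_prob(promoter, motif$iupac)
  z <- -qnorm(alpha / 2)
  ci_upper <- if (ci_method == "normal") E + z * sqrt(E)
    else qpois(1 - alpha / 2, E)
  data.frame(motif_id = motif$motif_id, observed = observed, expected = E,
             ci_upper = ci_upper,
             significant = (observed > ci_upper) && (E <= expected_cap),
             stringsAsFactors = FALSE)
}

#' @importFrom stats qnorm qpois chisq.test
NULL

#' Scan a set of promoters against a motif library
#'
#' @param promoters named character vector (gene id -> promoter)
#' @param motifs data.frame from \code{\link{read_motifs}} /
#'   \code{\link{default_motifs}}
#' @param alpha,expected_cap,ci_method passed to \code{\link{crbs_significance}}
#' @return data.frame: gene_id, motif_id, observed, expected, ci_upper,
#'   significant
#' @export
scan_promoters <- function(promoters, motifs, alpha = 0.05, expected_cap = 5.0,
                           ci_method = "normal") {
  out <- vector("list", length(promoters) * nrow(motifs))
  n <- 0L
  for (g in names(promoters)) {
    for (j in seq_len(nrow(motifs))) {
      m <- motifs[j, ]
      obs <- scan_motif(promoters[[g]], m$iupac)
      res <- crbs_significance(obs, promoters[[g]], m, alpha = alpha,
                               expected_cap = expected_cap, ci_method = ci_method)
      n <- n + 1L
      out[[n]] <- data.frame(gene_id = g, res, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(n)])
}

#' Compare CRBS content between two gene classes
#'
#' Per gene, CRBS instances = total significant motif occurrences and CRBS
#' categories = distinct significant motifs. Reports, per class, the fraction
#' of genes possessing >= 1 CRBS, the mean instances per gene and the number
#' of categories; tests the 2 x C category-frequency table and the 2 x 2
#' possession table with Pearson chi-square (categories whose total expected
#' count is < 1 are pooled into "other").
#'
#' @param scan data.frame from \code{\link{scan_promoters}}
#' @param class_a,class_b gene id sets
#' @return list(summary, chisq_categories, chisq_possession)
#' @export
crbs_class_comparison <- function(scan, class_a, class_b) {
  per_class <- function(ids) {
    s <- scan[scan$gene_id %in% ids & scan$significant, , drop = FALSE]
    inst <- tapply(s$observed, factor(s$gene_id, levels = ids), sum, default = 0L)
    list(possess = mean(inst > 0),
         mean_instances = mean(inst),
         categories = unique(s$motif_id),
         cat_counts = table(s$motif_id))
  }
  a <- per_class(class_a); b <- per_class(class_b)
  summary <- data.frame(
    class = c("a", "b"),
    n_genes = c(length(class_a), length(class_b)),
    possess_fraction = c(a$possess, b$possess),
    mean_instances = c(a$mean_instances, b$mean_instances),
    n_categories = c(length(a$categories), length(b$categories)))
  ## 2 x C category table
  cats <- union(names(a$cat_counts), names(b$cat_counts))
  chisq_cat <- NULL
  if (length(cats) >= 2L) {
    tab <- rbind(a = as.integer(a$cat_counts[cats]),
                 b = as.integer(b$cat_counts[cats]))
    tab[is.na(tab)] <- 0L
    colnames(tab) <- cats
    ## pool rare categories (expected total < 1)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    rare <- colSums(expected < 1) > 0
    if (any(rare) && sum(!rare) >= 1L) {
      tab <- cbind(tab[, !rare, drop = FALSE], other = rowSums(tab[, rare, drop = FALSE]))
      message(sum(rare), " rare CRBS categories pooled into 'other'")
    }
    if (ncol(tab) >= 2L && all(rowSums(tab) > 0)) {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      chisq_cat <- data.frame(statistic = unname(ct$statistic),
                              df = unname(ct$parameter), p = ct$p.value)
    }
  }
  ## 2 x 2 possession table
  pos <- rbind(a = c(yes = round(a$possess * length(class_a)),
                     no = round((1 - a$possess) * length(class_a))),
               b = c(yes = round(b$possess * length(class_b)),
                     no = round((1 - b$possess) * length(class_b))))
  chisq_pos <- if (all(rowSums(pos) > 0) && all(colSums(pos) > 0)) {
    ct <- suppressWarnings(chisq.test(pos, correct = FALSE))
    data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value)
  } else data.frame(statistic = 0, df = 1L, p = 1)
  list(summary = summary, chisq_categories = chisq_cat, chisq_possession = chisq_pos)
}

#' Monte-Carlo calibration of the CRBS significance rule
#'
#' Generates \code{n_promoters} random uniform-composition promoters with no
#' planted motifs, applies the scan and the CI-exceedance rule to every
#' promoter x motif pair, and returns the observed false-positive rate. The
#' counting and the expected-count model are the same as in
#' \code{\link{scan_motif}} / \code{\link{crbs_significance}}, vectorized
#' over promoters.
#'
#' @param motifs motif library data.frame
#' @param n_promoters,length null-promoter design
#' @param alpha,expected_cap,ci_method rule parameters
#' @param seed RNG seed
#' @return list(fpr, n_pairs)
#' @export
crbs_calibration <- function(motifs = default_motifs(), n_promoters = 2000L,
                             length = 2000L, alpha = 0.05, expected_cap = 5.0,
                             ci_method = "normal", seed = 1L) {
  set.seed(seed)
  proms <- Biostrings::DNAStringSet(vapply(seq_len(n_promoters), function(i)
    random_dna(length), ""))
  freq <- Biostrings::letterFrequency(proms, DNA_BASES, as.prob = TRUE)
  z <- -qnorm(alpha / 2)
  fixed <- c(pattern = FALSE, subject = TRUE)
  n_sig <- 0L
  for (j in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(toupper(motifs$iupac[j]))
    obs <- Biostrings::vcountPattern(pat, proms, fixed = fixed) +
      Biostrings::vcountPattern(Biostrings::reverseComplement(pat), proms,
                                fixed = fixed)
    codes <- strsplit(as.character(pat), "")[[1L]]
    pmatch_pos <- vapply(codes, function(code) {
      allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]]
      rowSums(freq[, allowed, drop = FALSE])
    }, numeric(n_promoters))
    E <- 2 * (length - length(pat) + 1L) * apply(pmatch_pos, 1L, prod)
    upper <- if (ci_method == "normal") E + z * sqrt(E) else qpois(1 - alpha / 2, E)
    n_sig <- n_sig + sum(obs > upper & E <= expected_cap)
  }
  list(fpr = n_sig / (n_promoters * nrow(motifs)),
       n_pairs = n_promoters * nrow(motifs))
}

#' Bundled motif library
#'
#' About forty IUPAC consensus motifs for plant transcription-factor families
#' (MADS/CArG, AP2/ERF, WRKY W-box, MYB, bZIP/ABRE, CO-like, KNOX, RAV, SBF,
#' SRS, ...). This is a stand-in library for testing and demonstration, not a
#' reproduction of any external binding-site database.
#'
#' @return data.frame(motif_id, iupac, tf_family)
#' @export
default_motifs <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "denovoscan")
  read_motifs(path)
}
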