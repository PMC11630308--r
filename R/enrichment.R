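## GO enrichment of genes flanking de novo loci.
##
## The 10-kb regions upstream and downstream of each de novo locus are
## collected either in the relative genomes around the ancestral noncoding
## loci the candidate maps to ("ancestral" mode) or around the gene itself in
## the focal genome ("focal" mode); genes in those regions are tested for GO
## term enrichment against a background with a one-sided Fisher exact
## (hypergeometric upper-tail) test at raw p < alpha. BH-adjusted q-values
## are reported alongside but not used for the cutoff.

#' Genes flanking a locus
#'
#' All genes whose body overlaps [start - flank, start) or [end, end + flank)
#' by at least one base, clipped at chromosome edges; the gene owning the
#' locus itself is excluded.
#'
#' @param locus list(chrom, start, end) in 0-based half-open coordinates
#' @param genome \code{\link{GenomeRecord}}
#' @param flank flank size in nt (default 10000)
#' @param exclude gene ids never reported (e.g. the locus-owning gene)
#' @return character vector of gene ids
#' @export
flank_genes <- function(locus, genome, flank = 10000L, exclude = character(0)) {
  chrom_len <- nchar(genome$chromosomes[[locus$chrom]])
  if (is.null(chrom_len)) stop("unknown chromosome '", locus$chrom, "'")
  windows <- rbind(c(max(0L, locus$start - flank), locus$start),
                   c(locus$end, min(chrom_len, locus$end + flank)))
  windows <- windows[windows[, 2L] > windows[, 1L], , drop = FALSE]
  if (nrow(windows) == 0L) return(character(0))
  win <- iv_to_iranges(iv_mat(windows[, 1L], windows[, 2L]))
  hits <- character(0)
  for (g in genome$genes) {
    if (g$chrom != locus$chrom || g$gene_id %in% exclude) next
    span <- gene_span(g)
    body <- iv_to_iranges(iv_mat(span[1L], span[2L]))
    if (length(IRanges::findOverlaps(body, win)) > 0L)
      hits <- c(hits, g$gene_id)
  }
  hits
}

#' Flanking genes of de novo calls
#'
#' @param calls list from \code{\link{call_denovo}} (confirmed/putative used)
#' @param focal focal \code{\link{GenomeRecord}}
#' @param relatives list of relative \code{\link{GenomeRecord}}
#' @param mode "ancestral": flanks of the noncoding loci in the relative
#'   genomes the candidate maps to; "focal": flanks of the gene in the focal
#'   genome
#' @param flank flank size in nt
#' @return character vector of flanking gene ids (union over calls)
#' @export
denovo_flank_genes <- function(calls, focal, relatives,
                               mode = c("ancestral", "focal"), flank = 10000L) {
  mode <- match.arg(mode)
  by_id <- setNames(relatives, vapply(relatives, `[[`, "", "genome_id"))
  keep <- Filter(function(cl) cl$status %in% c("putative", "confirmed_expressed"),
                 calls)
  out <- character(0)
  for (cl in keep) {
    if (mode == "focal") {
      g <- focal$genes[[cl$candidate_id]]
      if (is.null(g)) next
      span <- gene_span(g)
      out <- c(out, flank_genes(list(chrom = g$chrom, start = span[1L],
                                     end = span[2L]),
                                focal, flank, exclude = cl$candidate_id))
    } else {
      for (h in cl$evidence) {
        if (is.null(h$region_class) || h$region_class != "noncoding" ||
            !h$passes_coverage || isTRUE(h$is_trap)) next
        out <- c(out, flank_genes(list(chrom = h$chrom,
                                       start = h$target_span[1L],
                                       end = h$target_span[2L]),
                                  by_id[[h$genome]], flank))
      }
    }
  }
  unique(out)
}

#' One-sided Fisher (hypergeometric) GO enrichment
#'
#' For each GO term: k = flank genes with the term, K = background genes with
#' it, n = |flank set|, N = |background|; p = upper-tail hypergeometric
#' probability of >= k successes. Enriched iff p < alpha (raw, matching the
#' practice of testing each term at 0.05); BH q-values are reported.
#'
#' @param flank_set gene ids (subset of background_set; others dropped with a
#'   warning)
#' @param background_set gene ids
#' @param go_map named list gene -> terms
#' @param alpha raw p cutoff
#' @return data.frame(term, k, K, n, N, p, q, enriched)
#' @export
fisher_enrichment <- function(flank_set, background_set, go_map, alpha = 0.05) {
  stray <- setdiff(flank_set, background_set)
  if (length(stray)) {
    warning(length(stray), " flank gene(s) not in background; dropped")
    flank_set <- intersect(flank_set, background_set)
  }
  unknown <- setdiff(background_set, names(go_map))
  if (length(unknown))
    message(length(unknown), " background gene(s) without GO annotation")
  terms <- sort(unique(unlist(go_map[intersect(background_set, names(go_map))])))
  N <- length(background_set)
  n <- length(flank_set)
  rows <- lapply(terms, function(tm) {
    with_term <- names(go_map)[vapply(go_map, function(x) tm %in% x, TRUE)]
    K <- length(intersect(with_term, background_set))
    k <- length(intersect(with_term, flank_set))
    if (K == 0L) return(NULL)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(0)))
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p < alpha
  out[order(out$p), , drop = FALSE]
}
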