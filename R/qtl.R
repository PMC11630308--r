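## Overlap of de novo genes with QTL/MTL intervals in focal coordinates.
## Lift-over from other genomes is out of scope: intervals are consumed
## already placed on the focal assembly.

#' Overlap genes with QTL/MTL intervals
#'
#' A gene hits an interval iff its gene body overlaps it by at least one base
#' (0-based half-open arithmetic, so abutting intervals do not overlap). A
#' gene lying in at least two intervals is flagged as a pleiotropy candidate.
#' Intervals on chromosomes absent from the genome are skipped with a
#' warning.
#'
#' @param gene_ids genes to report (e.g. confirmed de novo genes)
#' @param genome focal \code{\link{GenomeRecord}}
#' @param qtl data.frame from \code{\link{read_qtl}} (chrom, start, end,
#'   trait; 0-based half-open)
#' @return data.frame(gene_id, n_hits, traits, pleiotropy)
#' @export
qtl_overlap <- function(gene_ids, genome, qtl) {
  unknown <- !qtl$chrom %in% names(genome$chromosomes)
  if (any(unknown)) {
    warning(sum(unknown), " QTL interval(s) on unknown chromosomes skipped")
    qtl <- qtl[!unknown, , drop = FALSE]
  }
  rows <- lapply(gene_ids, function(id) {
    g <- genome$genes[[id]]
    if (is.null(g)) return(data.frame(gene_id = id, n_hits = 0L, traits = "",
                                      pleiotropy = FALSE, stringsAsFactors = FALSE))
    span <- gene_span(g)
    same <- qtl[qtl$chrom == g$chrom, , drop = FALSE]
    hit <- same$start < span[2L] & same$end > span[1L]
    data.frame(gene_id = id, n_hits = sum(hit),
               traits = paste(sort(unique(same$trait[hit])), collapse = ","),
               pleiotropy = sum(hit) >= 2L, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
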