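## Expression confirmation, level and breadth from an FPKM matrix.
##
## A transcript is "not expressed" when its FPKM is zero across the biological
## replicates of every tissue; conversely it is expressed in a tissue as soon
## as any replicate there is > 0. Expression level is log2(mean FPKM + 1) over
## all samples; breadth is the number of tissues with any nonzero replicate.

#' Construct an expression matrix
#'
#' @param fpkm numeric gene x sample matrix of non-negative FPKM values with
#'   row names (gene ids) and column names \code{<tissue>__rep<k>}
#' @param meta optional data.frame (sample, tissue, replicate); derived from
#'   the column names when missing
#' @return object of class \code{ExpressionMatrix}
#' @export
ExpressionMatrix <- function(fpkm, meta = NULL) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)), !is.null(colnames(fpkm)))
  if (any(fpkm < 0)) stop("negative FPKM values are not allowed")
  if (is.null(meta)) {
    parts <- strsplit(colnames(fpkm), "__rep", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("sample names must follow <tissue>__rep<k>")
    meta <- data.frame(sample = colnames(fpkm),
                       tissue = vapply(parts, `[[`, "", 1L),
                       replicate = as.integer(vapply(parts, `[[`, "", 2L)),
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(meta) == ncol(fpkm), !any(is.na(meta$tissue)))
  structure(list(fpkm = fpkm, meta = meta), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tissues)\n",
              nrow(x$fpkm), ncol(x$fpkm), length(unique(x$meta$tissue))))
  invisible(x)
}

tissues_of <- function(mat) unique(mat$meta$tissue)

get_gene_row <- function(gene, mat) {
  if (!gene %in% rownames(mat$fpkm)) stop("unknown gene '", gene, "'")
  mat$fpkm[gene, ]
}

#' Per-tissue and overall expression flags for a gene
#'
#' A gene is expressed in a tissue iff any replicate there has FPKM > 0, and
#' expressed overall iff expressed in at least one tissue.
#'
#' @param gene gene id
#' @param mat \code{\link{ExpressionMatrix}}
#' @return list with \code{by_tissue} (named logical) and \code{overall}
#' @export
is_expressed <- function(gene, mat) {
  v <- get_gene_row(gene, mat)
  by_tissue <- vapply(split(v, mat$meta$tissue), function(x) any(x > 0), TRUE)
  by_tissue <- by_tissue[tissues_of(mat)]  # stable tissue order
  list(by_tissue = by_tissue, overall = any(by_tissue))
}

#' Expression level of a gene: log2(mean FPKM over all samples + 1)
#' @inheritParams is_expressed
#' @return numeric scalar
#' @export
expression_level <- function(gene, mat) {
  log2(mean(get_gene_row(gene, mat)) + 1)
}

#' Expression breadth: number of tissues in which the gene is expressed
#' @inheritParams is_expressed
#' @return integer in [0, n_tissues]
#' @export
expression_breadth <- function(gene, mat) {
  sum(is_expressed(gene, mat)$by_tissue)
}

#' Confirm putative de novo calls by expression
#'
#' Putative calls expressed in at least one tissue are promoted to
#' \code{confirmed_expressed}; unexpressed putatives keep their status.
#' Genes absent from the matrix are treated as unexpressed (with a warning).
#'
#' @param calls list of \code{DeNovoCall} (see \code{\link{call_denovo}})
#' @param mat \code{\link{ExpressionMatrix}}
#' @return updated calls list
#' @export
confirm_expressed <- function(calls, mat) {
  missing <- setdiff(vapply(calls, `[[`, "", "candidate_id"), rownames(mat$fpkm))
  if (length(missing))
    warning(length(missing), " call(s) absent from the expression matrix; ",
            "treated as unexpressed")
  lapply(calls, function(cl) {
    if (cl$status == "putative" && cl$candidate_id %in% rownames(mat$fpkm) &&
        is_expressed(cl$candidate_id, mat)$overall) {
      cl$status <- "confirmed_expressed"
    }
    cl
  })
}

#' Per-gene expression summary table
#' @param mat \code{\link{ExpressionMatrix}}
#' @return data.frame with gene_id, level, breadth, expressed
#' @export
expression_summary <- function(mat) {
  genes <- rownames(mat$fpkm)
  data.frame(
    gene_id = genes,
    level = vapply(genes, expression_level, 0, mat = mat),
    breadth = vapply(genes, expression_breadth, 0L, mat = mat),
    expressed = vapply(genes, function(g) is_expressed(g, mat)$overall, TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
}
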