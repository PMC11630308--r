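## Genome input/output and the internal data containers.
##
## Internal coordinate convention: 0-based half-open everywhere. GFF3 and the
## QTL TSV are 1-based inclusive at the file boundary, so the conversion
## internal_start = gff_start - 1, internal_end = gff_end happens exactly once,
## at read time.

#' Construct a gene model
#'
#' A gene model holds the representative transcript of one gene: its exons and
#' CDS segments as 0-based half-open intervals on one chromosome, plus strand
#' and biotype. A CDS whose concatenated length is not divisible by 3 is kept
#' but flagged (\code{codon_clean = FALSE}) and excluded from codon statistics
#' downstream.
#'
#' @param gene_id character scalar
#' @param chrom chromosome identifier
#' @param strand "+" or "-"
#' @param exons integer matrix with columns start, end (0-based half-open)
#' @param cds integer matrix like \code{exons}; must lie within the exon union
#' @param biotype one of "protein_coding", "transposable_element", "other"
#' @return an object of class \code{GeneModel}
#' @export
GeneModel <- function(gene_id, chrom, strand, exons, cds,
                      biotype = c("protein_coding", "transposable_element", "other")) {
  biotype <- match.arg(biotype)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, strand %in% c("+", "-"))
  exons <- iv_mat(exons[, 1L], exons[, 2L])
  cds <- iv_mat(cds[, 1L], cds[, 2L])
  if (nrow(exons) > 1L && any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("exons of gene '", gene_id, "' overlap")
  if (iv_overlap_width(cds, exons) != iv_union_width(cds))
    stop("CDS of gene '", gene_id, "' extends outside its exons")
  cds_len <- sum(cds[, "end"] - cds[, "start"])
  structure(
    list(gene_id = gene_id, chrom = as.character(chrom), strand = strand,
         exons = exons, cds = cds, biotype = biotype,
         codon_clean = (cds_len %% 3L == 0L)),
    class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s [%s:%d-%d (%s), %d exon(s), %s]\n", x$gene_id,
              x$chrom, gene_span(x)[1L], gene_span(x)[2L], x$strand,
              nrow(x$exons), x$biotype))
  invisible(x)
}

## gene body span (0-based half-open) over the exon union
gene_span <- function(gene) c(min(gene$exons[, "start"]), max(gene$exons[, "end"]))

#' Construct a genome record
#'
#' Bundles one genome's chromosome sequences with its gene models and its role
#' in the analysis: the focal genome under study, or an in-group / out-group
#' relative used to establish ancestral noncoding state.
#'
#' @param genome_id character scalar
#' @param role one of "focal", "ingroup", "outgroup"
#' @param chromosomes named character vector of uppercase A/C/G/T/N sequences
#' @param genes list of \code{\link{GeneModel}} objects
#' @return an object of class \code{GenomeRecord}
#' @export
GenomeRecord <- function(genome_id, role = c("focal", "ingroup", "outgroup"),
                         chromosomes, genes = list()) {
  role <- match.arg(role)
  stopifnot(is.character(chromosomes), !is.null(names(chromosomes)))
  if (anyDuplicated(names(chromosomes)))
    stop("duplicate chromosome ids in genome '", genome_id, "'")
  bad <- grepl("[^ACGTN]", chromosomes)
  if (any(bad))
    stop("chromosome '", names(chromosomes)[bad][1L], "' contains non-ACGTN characters")
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(names(genes)))
    stop("duplicate gene ids in genome '", genome_id, "'")
  for (g in genes) {
    if (!g$chrom %in% names(chromosomes))
      stop("gene '", g$gene_id, "' references unknown chromosome '", g$chrom, "'")
    if (max(g$exons[, "end"]) > nchar(chromosomes[[g$chrom]]))
      stop("gene '", g$gene_id, "' extends beyond chromosome '", g$chrom, "'")
  }
  structure(list(genome_id = genome_id, role = role,
                 chromosomes = chromosomes, genes = genes),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s (%s): %d chromosome(s), %.1f kb, %d gene(s)\n",
              x$genome_id, x$role, length(x$chromosomes),
              sum(nchar(x$chromosomes)) / 1000, length(x$genes)))
  invisible(x)
}

#' Read a FASTA file of chromosome sequences
#'
#' Sequences are uppercased; anything outside A/C/G/T/N and duplicate or empty
#' records are hard errors.
#'
#' @param path FASTA file
#' @return named character vector chrom_id -> sequence
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA '", path, "'")
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence id '", ids[duplicated(ids)][1L],
                               "' in FASTA '", path, "'")
  if (any(nchar(seqs) == 0L)) stop("empty record in FASTA '", path, "'")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("record '", ids[bad][1L], "' contains non-ACGTN characters")
  setNames(seqs, ids)
}

#' Write chromosome sequences to FASTA
#' @param chromosomes named character vector
#' @param path output file
#' @export
write_fasta <- function(chromosomes, path) {
  ss <- Biostrings::DNAStringSet(chromosomes)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Consumes gene/mRNA/exon/CDS features (1-based inclusive) and converts to the
#' internal 0-based half-open convention. When a gene carries several mRNAs
#' only the representative transcript with the longest total CDS is retained.
#' Biotype is read from a \code{biotype=} attribute on the gene, defaulting to
#' protein_coding.
#'
#' @param path GFF3 file
#' @param chromosomes optional named character vector used for bounds checks
#' @return list of \code{\link{GeneModel}}
#' @export
read_gff3 <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$Parent <- vapply(as.list(gr$Parent),
                      function(p) if (length(p)) p[[1L]] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  if (any(is.na(mrnas$Parent))) stop("mRNA without Parent gene in '", path, "'")
  if (any(is.na(exons$Parent)) || any(is.na(cdss$Parent)))
    stop("exon/CDS feature without Parent mRNA in '", path, "'")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) stop("gene '", gid, "' has no mRNA child")
    ## representative transcript: longest total CDS (ties: first by ID order)
    cds_len <- vapply(tx$ID, function(tid)
      sum(cdss$width[cdss$Parent == tid]), 0)
    tid <- tx$ID[which.max(cds_len)]
    ex <- exons[exons$Parent == tid, , drop = FALSE]
    cd <- cdss[cdss$Parent == tid, , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cd   # exonless models: exons default to CDS
    if (nrow(cd) == 0L) stop("transcript '", tid, "' has no CDS")
    biotype <- if ("biotype" %in% names(genes) && !is.na(genes$biotype[i]))
      genes$biotype[i] else "protein_coding"
    if (!is.null(chromosomes)) {
      chrom <- genes$seqnames[i]
      if (!chrom %in% names(chromosomes))
        stop("gene '", gid, "' on unknown chromosome '", chrom, "'")
      if (max(cd$end) > nchar(chromosomes[[chrom]]))
        stop("CDS of transcript '", tid, "' extends beyond chromosome '", chrom, "'")
    }
    out[[i]] <- GeneModel(
      gene_id = gid, chrom = genes$seqnames[i], strand = genes$strand[i],
      exons = iv_mat(ex$start - 1L, ex$end),
      cds = iv_mat(cd$start - 1L, cd$end),
      biotype = biotype)
  }
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Write gene models to GFF3 (1-based inclusive at the file boundary)
#' @param genes list of \code{\link{GeneModel}}
#' @param path output file
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- gene_span(g)
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tdenovoscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       g$chrom, span[1L] + 1L, span[2L], g$strand, gid, g$biotype), con)
    writeLines(sprintf("%s\tdenovoscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, span[1L] + 1L, span[2L], g$strand, tid, gid), con)
    for (j in seq_len(nrow(g$exons)))
      writeLines(sprintf("%s\tdenovoscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$chrom, g$exons[j, 1L] + 1L, g$exons[j, 2L], g$strand,
                         tid, j, tid), con)
    ## CDS phase: cumulative length modulo 3, in transcription order
    cds <- g$cds
    ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    phase <- integer(nrow(cds))
    acc <- 0L
    for (j in ord) {
      phase[j] <- (3L - acc %% 3L) %% 3L
      acc <- acc + (cds[j, 2L] - cds[j, 1L])
    }
    for (j in seq_len(nrow(cds)))
      writeLines(sprintf("%s\tdenovoscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.c%d;Parent=%s",
                         g$chrom, cds[j, 1L] + 1L, cds[j, 2L], g$strand,
                         phase[j], tid, j, tid), con)
  }
  invisible(path)
}

#' Read a genome (FASTA + GFF3) into a GenomeRecord
#' @param fasta_path,gff3_path input files
#' @param genome_id identifier for the genome
#' @param role "focal", "ingroup" or "outgroup"
#' @return \code{\link{GenomeRecord}}
#' @export
read_genome <- function(fasta_path, gff3_path, genome_id, role = "focal") {
  chroms <- read_fasta(fasta_path)
  genes <- read_gff3(gff3_path, chromosomes = chroms)
  GenomeRecord(genome_id, role, chroms, genes)
}

#' Extract the spliced, strand-corrected CDS of a gene
#'
#' Returns the 5'->3' coding sequence. A CDS whose length is not divisible by
#' 3 is returned as-is; the \code{codon_clean} flag on the gene model marks it
#' for exclusion from codon statistics.
#'
#' @param gene \code{\link{GeneModel}}
#' @param chromosomes named character vector of sequences
#' @return character scalar DNA
#' @export
extract_cds <- function(gene, chromosomes) {
  if (nrow(gene$cds) == 0L) stop("gene '", gene$gene_id, "' has no CDS")
  chrom <- chromosomes[[gene$chrom]]
  if (is.null(chrom)) stop("unknown chromosome '", gene$chrom, "'")
  if (max(gene$cds[, "end"]) > nchar(chrom))
    stop("CDS of gene '", gene$gene_id, "' out of chromosome bounds")
  parts <- substring(chrom, gene$cds[, "start"] + 1L, gene$cds[, "end"])
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Protein sequences of a genome's codon-clean protein-coding genes
#'
#' Translates the representative CDS of every protein-coding, codon-clean gene
#' (N-containing CDS are skipped); a trailing stop is removed.
#'
#' @param genome \code{\link{GenomeRecord}}
#' @return \code{Biostrings::AAStringSet} named by gene id
#' @export
genome_proteome <- function(genome) {
  keep <- vapply(genome$genes, function(g)
    g$biotype == "protein_coding" && isTRUE(g$codon_clean), TRUE)
  prots <- character(0)
  for (g in genome$genes[keep]) {
    cds <- extract_cds(g, genome$chromosomes)
    if (grepl("N", cds, fixed = TRUE)) next
    aa <- translate_dna(cds)
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) next  # internal stop: not a clean protein
    prots[[g$gene_id]] <- aa
  }
  Biostrings::AAStringSet(prots)
}

#' Read an FPKM expression matrix
#'
#' TSV with a \code{gene_id} column followed by one column per sample named
#' \code{<tissue>__rep<k>}. Negative FPKM values are a hard error.
#'
#' @param path TSV file
#' @return \code{\link{ExpressionMatrix}}
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column of '", path, "' must be gene_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  ExpressionMatrix(m)
}

#' Write an expression matrix to TSV
#' @param mat \code{\link{ExpressionMatrix}}
#' @param path output file
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat$fpkm), mat$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> GO terms map
#'
#' TSV: gene_id TAB comma-separated GO ids.
#' @param path TSV file
#' @return named list gene_id -> character vector of terms
#' @export
read_go_map <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   col.names = c("gene_id", "terms"))
  setNames(strsplit(df$terms, ",", fixed = TRUE), df$gene_id)
}

#' Write a gene -> GO terms map
#' @param go_map named list gene -> terms
#' @param path output file
#' @export
write_go_map <- function(go_map, path) {
  df <- data.frame(gene_id = names(go_map),
                   terms = vapply(go_map, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read QTL/MTL intervals
#'
#' BED-like TSV with header (chrom, start, end, trait); coordinates in the
#' file are 1-based inclusive and converted to 0-based half-open.
#'
#' @param path TSV file
#' @return data.frame with columns chrom, start, end, trait
#' @export
read_qtl <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "trait"))
  out <- data.frame(chrom = as.character(df$chrom),
                    start = as.integer(df$start) - 1L,
                    end = as.integer(df$end), trait = df$trait,
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("QTL interval with end <= start in '", path, "'")
  out
}

#' Write QTL intervals (back to 1-based inclusive)
#' @param qtl data.frame as from \code{\link{read_qtl}}
#' @param path output file
#' @export
write_qtl <- function(qtl, path) {
  df <- data.frame(chrom = qtl$chrom, start = qtl$start + 1L,
                   end = qtl$end, trait = qtl$trait, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif library
#'
#' TSV: motif_id, IUPAC consensus, tf_family.
#' @param path TSV file
#' @return data.frame with columns motif_id, iupac, tf_family
#' @export
read_motifs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   col.names = c("motif_id", "iupac", "tf_family"))
  validate_motifs(df)
  df
}

validate_motifs <- function(df) {
  iupac <- toupper(df$iupac)
  if (any(nchar(iupac) < 4L)) stop("motif consensus shorter than 4 bases")
  ok <- !grepl(paste0("[^", paste(names(Biostrings::IUPAC_CODE_MAP), collapse = ""), "]"),
               iupac)
  if (!all(ok)) stop("motif '", df$motif_id[!ok][1L], "' contains non-IUPAC letters")
  invisible(df)
}
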