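## Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

## the default-condition simulation (seed 7)
fix_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_genomes(sim_config(seed = 7L))
  .fixtures$sim
}

## full pipeline result on the default simulation
fix_res <- function() {
  if (is.null(.fixtures$res)) {
    sim <- fix_sim()
    .fixtures$res <- suppressMessages(suppressWarnings(
      run_pipeline(sim$focal, sim$relatives, sim$expression, sim$go_map,
                   sim$motifs, sim$qtl, run_network = FALSE)))
  }
  .fixtures$res
}

## truth table keyed by gene id
fix_truth <- function() {
  tr <- fix_sim()$truth
  rownames(tr) <- tr$gene_id
  tr
}

## a small, fast simulation for orchestration tests
fix_sim_small <- function() {
  if (is.null(.fixtures$sim_small))
    .fixtures$sim_small <- simulate_genomes(sim_config(
      seed = 3L, n_conserved = 12L, n_type1 = 2L, n_type2 = 1L, n_decoy = 1L,
      n_trap = 1L, n_ingroup = 1L, n_outgroup = 1L, n_tissues = 5L,
      replicates = 2L))
  .fixtures$sim_small
}

## planted co-expression blocks
fix_coexpr <- function() {
  if (is.null(.fixtures$cx))
    .fixtures$cx <- simulate_coexpression(seed = 7L)
  .fixtures$cx
}

## ---- small hand-built genomes for unit tests ------------------------------

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

## an open reading frame of n_codons with no internal stop
random_orf <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  ok <- names(code)[code != "*"]
  paste0("ATG", paste(sample(ok, n_codons - 2L, TRUE), collapse = ""), "TAA")
}

## one-chromosome genome: `inserts` is a named list of sequences planted in
## order with 400-nt random spacers between them; genes optionally annotate
## planted inserts (list of list(id, insert, biotype))
toy_genome <- function(genome_id, role, inserts, genes = list(), spacer = 400L) {
  seqs <- character(0)
  pos <- 0L
  where <- integer(0)
  for (nm in names(inserts)) {
    sp <- random_dna_str(spacer)
    seqs <- c(seqs, sp, inserts[[nm]])
    where[[nm]] <- pos + spacer
    pos <- pos + spacer + nchar(inserts[[nm]])
  }
  seqs <- c(seqs, random_dna_str(spacer))
  chrom <- c(chr1 = paste(seqs, collapse = ""))
  gms <- lapply(genes, function(g) {
    s <- where[[g$insert]]
    e <- s + nchar(inserts[[g$insert]])
    GeneModel(g$id, "chr1", "+", iv_mat_pub(s, e), iv_mat_pub(s, e),
              biotype = if (is.null(g$biotype)) "protein_coding" else g$biotype)
  })
  gr <- GenomeRecord(genome_id, role, chrom, gms)
  attr(gr, "where") <- where
  gr
}

## interval matrix builder mirroring the package's internal convention
iv_mat_pub <- function(start, end) {
  cbind(start = as.integer(start), end = as.integer(end))
}
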