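## Synthetic study generator: a focal genome plus in-group/out-group
## relatives with planted gene classes and a truth table, together with a
## matched expression matrix, GO map, motif library and QTL intervals, so the
## whole pipeline is testable without external data.
##
## Recipes per planted class:
##   conserved  - ancestral CDS present and annotated in the focal genome and
##                every relative (per-relative substitutions preserve the
##                ORF), guaranteeing a one-to-one ortholog;
##   type1      - focal gene whose locus in every relative is the ancestral
##                sequence with the reading frame disrupted (>= 3 in-frame
##                stops, verified in all six frames) and unannotated;
##   type2      - chimeric focal CDS: a short fragment copied out of frame
##                from a conserved donor gene's first exon, followed by
##                sequence whose ancestral state is noncoding; the frameshift
##                keeps protein-level similarity to the donor below the
##                homology filter's E-value bar (checked, resampled);
##   decoy      - gene with an intact annotated ortholog in exactly one
##                in-group relative: filtered before mapping, never called;
##   orf_trap   - focal gene whose relative loci are unannotated but contain
##                an intact, synonymously diverged ORF: caught by the
##                ORF-trap screen.
##
## The focal genome plays the ancestor; each relative is derived from it by
## substitutions everywhere and short indels in intergenic sequence. Genes
## sit in 5-kb slots, 20 per ~100-kb chromosome, so 2-kb promoters never
## collide and 10-kb flanks span a predictable two slots on each side.

SLOT <- 5000L
LOCUS_OFFSET <- 2500L
GENES_PER_CHROM <- 20L
CHROM_TAIL <- 3000L

## planted optimal codon per degenerate family: the C-ending codon when one
## exists (e.g. Ala -> GCC), else the alphabetically first
planted_optimal_codons <- function() {
  vapply(degenerate_families, function(cods) {
    cods <- sort(cods)
    c_end <- cods[substr(cods, 3L, 3L) == "C"]
    if (length(c_end)) c_end[1L] else cods[1L]
  }, "")
}

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the test-suite:
#' 100 conserved genes, 20 Type I and 10 Type II de novo genes, 10 decoys
#' with a partial ortholog, 5 unannotated-ORF traps; two in-group and two
#' out-group relatives at 10% substitution divergence; 19 tissues with 3
#' replicates; broad log-normal expression (meanlog 3, sdlog 1) for
#' conserved genes and low, narrow expression (meanlog 0.5, sdlog 1, 1-4
#' tissues) for de novo genes; a mean of 2 planted motif instances per
#' promoter; 90% optimal-codon usage in conserved genes.
#'
#' @param seed integer RNG seed
#' @param n_conserved,n_type1,n_type2,n_decoy,n_trap planted class counts
#' @param n_ingroup,n_outgroup numbers of relative genomes
#' @param substitution_rate per-site substitution fraction focal vs relative,
#'   in [0, 0.3]
#' @param indel_rate per-site indel rate in intergenic sequence
#' @param n_tissues,replicates expression design
#' @param conserved_meanlog,conserved_sdlog,denovo_meanlog,denovo_sdlog
#'   log-normal FPKM parameters per class
#' @param motif_plant_rate mean planted motif instances per promoter
#' @param codon_bias probability that a conserved gene's degenerate codon is
#'   the planted optimal codon
#' @param n_qtl_covered de novo genes covered by simulated QTL intervals
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(seed = 7L, n_conserved = 100L, n_type1 = 20L,
                       n_type2 = 10L, n_decoy = 10L, n_trap = 5L,
                       n_ingroup = 2L, n_outgroup = 2L,
                       substitution_rate = 0.1, indel_rate = 0.01,
                       n_tissues = 19L, replicates = 3L,
                       conserved_meanlog = 3.0, conserved_sdlog = 1.0,
                       denovo_meanlog = 0.5, denovo_sdlog = 1.0,
                       motif_plant_rate = 2, codon_bias = 0.9,
                       n_qtl_covered = 12L) {
  cfg <- as.list(environment())
  counts <- c(n_conserved, n_type1, n_type2, n_decoy, n_trap)
  stopifnot(all(counts >= 0L), n_ingroup >= 1L, n_outgroup >= 1L,
            substitution_rate >= 0, substitution_rate <= 0.3,
            indel_rate >= 0, indel_rate <= 1,
            n_tissues >= 1L, replicates >= 1L)
  structure(cfg, class = "sim_config")
}

## ---- low-level sequence machinery ----------------------------------------

## substitutions at `rate` per site
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1L]]
  idx <- which(runif(length(v)) < rate)
  if (length(idx)) {
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(v, collapse = "")
}

## short (1-3 nt) insertions/deletions at `rate` per site; intergenic only
apply_indels <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  idx <- sort(which(runif(n) < rate), decreasing = TRUE)
  if (!length(idx)) return(seq)
  v <- strsplit(seq, "")[[1L]]
  for (i in idx) {
    len <- sample(1:3, 1L)
    if (runif(1) < 0.5) {
      v <- v[-(i:min(n, i + len - 1L))]
    } else {
      v <- append(v, sample(DNA_BASES, len, replace = TRUE), after = i)
    }
    n <- length(v)
  }
  paste(v, collapse = "")
}

## random CDS: ATG + codons + stop; optional planted codon usage bias
make_cds <- function(n_codons, optimal = NULL, bias = 0) {
  mid <- character(n_codons - 2L)
  aas <- sample(unique(GENETIC_CODE_TABLE[GENETIC_CODE_TABLE != "*"]),
                n_codons - 2L, replace = TRUE)
  fam <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
  for (i in seq_along(aas)) {
    aa <- aas[i]
    cods <- fam[[aa]]
    mid[i] <- if (!is.null(optimal) && aa %in% names(optimal) && runif(1) < bias)
      optimal[[aa]] else sample(cods, 1L)
  }
  paste0("ATG", paste(mid, collapse = ""), sample(STOP_CODONS, 1L))
}

## substitutions that keep the ORF intact (start, internal codons, stop)
mutate_cds_keep_orf <- function(cds, rate) {
  out <- mutate_bases(cds, rate)
  substr(out, 1L, 3L) <- "ATG"
  substr(out, nchar(out) - 2L, nchar(out)) <- substr(cds, nchar(cds) - 2L, nchar(cds))
  cods <- codons_of(out)
  internal <- if (length(cods) > 2L) 2L:(length(cods) - 1L) else integer(0)
  bad <- internal[cods[internal] %in% STOP_CODONS]
  for (i in bad) substr(out, 3L * i, 3L * i) <- "C"   # TAA/TAG->TAC, TGA->TGC
  out
}

## synonymous-only divergence: swap ~`rate_codon` of codons within family
mutate_cds_synonymous <- function(cds, rate_codon = 0.3) {
  cods <- codons_of(cds)
  fam <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
  for (i in seq_along(cods)) {
    if (runif(1) >= rate_codon) next
    aa <- GENETIC_CODE_TABLE[[cods[i]]]
    if (aa == "*") next
    cods[i] <- sample(fam[[aa]], 1L)
  }
  paste(cods, collapse = "")
}

#' Six-frame ORF scan with coordinates
#'
#' Maximal ATG-to-stop ORFs (first ATG per inter-stop segment) in all six
#' frames, with 0-based half-open forward-strand coordinates including the
#' stop codon.
#'
#' @param dna DNA string
#' @return data.frame(strand, frame, start, end, peptide)
#' @export
orf_scan <- function(dna) {
  N <- nchar(dna)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (f in 0:2) {
      if (N - f < 3L) next
      aa <- translate_dna(substr(s, f + 1L, N))
      m <- gregexpr("M[^*]*\\*", aa)[[1L]]
      if (m[1L] == -1L) next
      for (j in seq_along(m)) {
        len <- attr(m, "match.length")[j]
        nt_s <- f + (m[j] - 1L) * 3L
        nt_e <- nt_s + len * 3L
        res[[length(res) + 1L]] <- data.frame(
          strand = strand, frame = f,
          start = if (strand == "+") nt_s else N - nt_e,
          end = if (strand == "+") nt_e else N - nt_s,
          peptide = substr(aa, m[j], m[j] + len - 2L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0)))
  do.call(rbind, res)
}

## disrupt a sequence into verified noncoding state: plant >= `min_stops`
## in-frame stops and keep adding stops until no frame on either strand has
## an ORF of >= `max_orf_aa` residues
disrupt_to_noncoding <- function(seq, min_stops = 3L, max_orf_aa = NULL) {
  n_cod <- nchar(seq) %/% 3L
  if (is.null(max_orf_aa)) max_orf_aa <- max(10L, floor(0.75 * n_cod))
  pos <- unique(round(seq(0.2, 0.8, length.out = max(min_stops, 3L)) * n_cod))
  for (i in pos)
    substr(seq, 3L * i - 2L, 3L * i) <- sample(STOP_CODONS, 1L)
  for (iter in 1:50) {
    orfs <- orf_scan(seq)
    long <- orfs[nchar(orfs$peptide) >= max_orf_aa, , drop = FALSE]
    if (nrow(long) == 0L) return(seq)
    o <- long[1L, ]
    k <- floor(nchar(o$peptide) / 2)
    if (o$strand == "+") {
      p0 <- o$start + 3L * k
      substr(seq, p0 + 1L, p0 + 3L) <- "TAA"
    } else {
      p0 <- o$end - 3L * (k + 1L)
      substr(seq, p0 + 1L, p0 + 3L) <- "TTA"
    }
  }
  stop("failed to disrupt sequence into noncoding state")
}

## concrete instance of an IUPAC consensus
instantiate_iupac <- function(iupac) {
  paste(vapply(strsplit(toupper(iupac), "")[[1L]], function(code) {
    sample(strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1L]], 1L)
  }, ""), collapse = "")
}

## ---- expression profiles ---------------------------------------------------

#' Simulated FPKM row for one planted class
#'
#' Conserved-like genes ("broad") are expressed in every tissue with
#' log-normal levels; de novo-like genes ("narrow") are expressed in 1-4
#' random tissues at low levels and are exactly zero elsewhere. Replicates
#' add multiplicative log-normal noise.
#'
#' @param planted_class one of the truth-table classes
#' @param config \code{\link{sim_config}}
#' @return numeric vector of length n_tissues * replicates
#' @export
expression_profile <- function(planted_class, config) {
  nt <- config$n_tissues; nr <- config$replicates
  broad <- planted_class %in% c("conserved", "decoy_partial_ortholog")
  mu <- if (broad) rlnorm(nt, config$conserved_meanlog, config$conserved_sdlog)
  else {
    m <- numeric(nt)
    on <- sample(nt, sample(seq_len(min(4L, nt)), 1L))
    m[on] <- rlnorm(length(on), config$denovo_meanlog, config$denovo_sdlog)
    m
  }
  as.vector(t(outer(mu, rlnorm(nr, 0, 0.2))))  # tissue-major, rep within
}

## ---- the generator ---------------------------------------------------------

#' Simulate a focal genome, relatives, and all matched inputs
#'
#' Deterministic given \code{config$seed}. See the class recipes in the file
#' header; the truth table records every focal gene's planted class, Type II
#' donor, expression class and planted promoter motif counts.
#'
#' @param config \code{\link{sim_config}}
#' @return list(focal, relatives, expression, go_map, motifs, qtl, truth);
#'   truth is a data.frame with attribute \code{"motif_counts"}
#' @export
simulate_genomes <- function(config = sim_config()) {
  set.seed(config$seed)
  motifs <- default_motifs()
  optimal <- planted_optimal_codons()

  classes <- rep(c("conserved", "denovo_type1", "denovo_type2",
                   "decoy_partial_ortholog", "orf_trap"),
                 c(config$n_conserved, config$n_type1, config$n_type2,
                   config$n_decoy, config$n_trap))
  n_all <- length(classes)
  if (n_all == 0L) stop("no genes to simulate")
  classes <- sample(classes)   # shuffle classes across slots
  ids <- sprintf("gene%03d", seq_len(n_all))
  n_chrom <- ceiling(n_all / GENES_PER_CHROM)
  chrom_of <- rep(sprintf("chr%d", seq_len(n_chrom)),
                  each = GENES_PER_CHROM)[seq_len(n_all)]
  slot_of <- (seq_len(n_all) - 1L) %% GENES_PER_CHROM + 1L
  strands <- sample(c("+", "-"), n_all, replace = TRUE)

  relnames <- c(sprintf("ingroup%s", LETTERS[seq_len(config$n_ingroup)]),
                sprintf("outgroup%s", LETTERS[seq_len(config$n_outgroup)]))
  relroles <- rep(c("ingroup", "outgroup"), c(config$n_ingroup, config$n_outgroup))
  decoy_host <- relnames[1L]   # the single in-group genome carrying decoy orthologs

  ## 1. focal CDS and locus construct per gene ------------------------------
  loci <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    cl <- classes[i]
    g <- list(class = cl, donor = NA_character_, frag_nt = 0L)
    if (cl %in% c("conserved", "decoy_partial_ortholog")) {
      n_cod <- sample(80:200, 1L)
      g$cds <- make_cds(n_cod,
                        optimal = if (cl == "conserved") optimal else NULL,
                        bias = if (cl == "conserved") config$codon_bias else 0)
      g$n_exons <- if (cl == "conserved") sample(1:4, 1L) else sample(1:2, 1L)
    } else if (cl %in% c("denovo_type1", "orf_trap")) {
      g$cds <- make_cds(sample(50:150, 1L))
      g$n_exons <- 1L
    } else {               # denovo_type2: chimera built later (needs donors)
      g$cds <- NA_character_
      g$n_exons <- 1L
    }
    loci[[i]] <- g
  }

  ## 2. Type II chimeras from conserved donors ------------------------------
  conserved_idx <- which(classes == "conserved")
  scoring <- protein_scoring()
  if (config$n_type2 > 0L && length(conserved_idx) == 0L)
    stop("type2 chimeras need at least one conserved donor gene")
  for (i in which(classes == "denovo_type2")) {
    for (try in 1:30) {
      L_nt <- 3L * sample(150:200, 1L)
      f <- runif(1, 0.1, 0.4)
      ## donor fragment must fit in the donor's first exon
      di <- conserved_idx[sample.int(length(conserved_idx), 1L)]
      donor <- loci[[di]]
      exon1_nt <- exon_split(nchar(donor$cds), donor$n_exons)[1L]
      frag_nt <- 3L * (max(60L, round(f * L_nt)) %/% 3L)
      if (frag_nt > exon1_nt - 6L) next
      frag <- substr(donor$cds, 2L, 1L + frag_nt)        # +1 frameshift copy
      rest <- make_cds((L_nt - 3L - frag_nt) %/% 3L + 1L)
      rest <- substr(rest, 4L, nchar(rest))              # drop its ATG
      chimera <- paste0("ATG", frag, rest)
      cods <- codons_of(chimera)
      bad <- which(cods[-length(cods)] %in% STOP_CODONS)
      for (b in bad) substr(chimera, 3L * b, 3L * b) <- "C"
      ## construction check: no protein-level homology to the donor
      pep <- sub("\\*$", "", translate_dna(chimera))
      dpep <- sub("\\*$", "", translate_dna(donor$cds))
      if (align_protein(pep, dpep, scoring)$evalue > 1e-5) {
        loci[[i]]$cds <- chimera
        loci[[i]]$donor <- ids[di]
        loci[[i]]$frag_nt <- frag_nt
        break
      }
    }
    if (is.na(loci[[i]]$cds))
      stop("could not build a homology-free type2 chimera")
  }

  ## 2b. pre-generate the relatives' annotated ortholog CDS (conserved genes
  ## everywhere, the decoy ortholog in its host genome) so candidate-class
  ## proteins can be screened against the actual relative proteomes
  bg_idx <- which(classes %in% c("conserved", "decoy_partial_ortholog"))
  cand_idx <- which(classes %in% c("denovo_type1", "denovo_type2", "orf_trap"))
  for (i in bg_idx) {
    hosts <- if (classes[i] == "conserved") relnames else decoy_host
    loci[[i]]$rel_cds <- lapply(setNames(hosts, hosts), function(rn)
      mutate_cds_keep_orf(loci[[i]]$cds, config$substitution_rate))
  }
  ## construction check: no candidate-class protein may chance-hit any
  ## annotated protein (focal or relative copy) near the homology filter's
  ## E bar (margin 1e-4 vs the 1e-5 filter); offenders are resampled so the
  ## planted truth table stays recoverable by the pipeline
  if (length(bg_idx) && length(cand_idx)) {
    bg_prot <- unlist(lapply(bg_idx, function(i) {
      p <- c(list(sub("\\*$", "", translate_dna(loci[[i]]$cds))),
             lapply(loci[[i]]$rel_cds, function(s)
               sub("\\*$", "", translate_dna(s))))
      names(p) <- c(ids[i], paste0(names(loci[[i]]$rel_cds), "_", ids[i]))
      p
    }))
    for (round in 1:10) {
      cand_prot <- vapply(loci[cand_idx], function(g)
        sub("\\*$", "", translate_dna(g$cds)), "")
      names(cand_prot) <- ids[cand_idx]
      sr <- protein_search(cand_prot, bg_prot, scoring)
      ## type2 donor fragments are legitimate; only chance hits count
      strip_rel <- paste0("^(", paste(relnames, collapse = "|"), ")_")
      target_focal <- sub(strip_rel, "", colnames(sr$evalue))
      min_e <- vapply(seq_along(cand_idx), function(i) {
        e <- sr$evalue[i, ]
        if (classes[cand_idx[i]] == "denovo_type2")
          e <- e[target_focal != loci[[cand_idx[i]]]$donor]
        min(e)
      }, 0)
      bad <- which(min_e <= 1e-4)
      if (!length(bad)) break
      if (round == 10L) stop("could not draw homology-free candidate proteins")
      for (i in cand_idx[bad]) {
        if (classes[i] == "denovo_type2") {
          loci[[i]]$cds <- make_cds(nchar(loci[[i]]$cds) %/% 3L)  # fresh rest
          frag <- substr(loci[[which(ids == loci[[i]]$donor)]]$cds, 2L,
                         1L + loci[[i]]$frag_nt)
          chim <- paste0("ATG", frag,
                         substr(loci[[i]]$cds, 4L + loci[[i]]$frag_nt,
                                nchar(loci[[i]]$cds)))
          cods <- codons_of(chim)
          for (b in which(cods[-length(cods)] %in% STOP_CODONS))
            substr(chim, 3L * b, 3L * b) <- "C"
          loci[[i]]$cds <- chim
        } else {
          loci[[i]]$cds <- make_cds(nchar(loci[[i]]$cds) %/% 3L)
        }
      }
    }
  }

  ## 3. exon/intron structure and forward locus constructs ------------------
  for (i in seq_len(n_all)) {
    g <- loci[[i]]
    parts <- exon_split(nchar(g$cds), g$n_exons)
    introns <- if (g$n_exons > 1L)
      vapply(seq_len(g$n_exons - 1L), function(j) random_dna(sample(100:300, 1L)), "")
    else character(0)
    seq <- ""
    exons <- matrix(0L, g$n_exons, 2L, dimnames = list(NULL, c("start", "end")))
    off <- 0L
    cds_pos <- cumsum(c(0L, parts))
    for (j in seq_len(g$n_exons)) {
      exons[j, ] <- c(off, off + parts[j])
      seq <- paste0(seq, substr(g$cds, cds_pos[j] + 1L, cds_pos[j + 1L]))
      off <- off + parts[j]
      if (j < g$n_exons) {
        seq <- paste0(seq, introns[j])
        off <- off + nchar(introns[j])
      }
    }
    loci[[i]]$locus <- seq
    loci[[i]]$exons <- exons   # forward-construct coordinates
  }

  ## 4. assemble the focal genome and plant promoter motifs -----------------
  chrom_seqs <- character(n_chrom)
  names(chrom_seqs) <- sprintf("chr%d", seq_len(n_chrom))
  locus_pos <- integer(n_all)    # forward start of each locus on its chromosome
  for (ci in seq_len(n_chrom)) {
    members <- which(chrom_of == names(chrom_seqs)[ci])
    seqs <- character(0)
    pos <- 0L
    for (i in members) {
      sp_len <- LOCUS_OFFSET + SLOT * (slot_of[i] - 1L) - pos
      seqs <- c(seqs, random_dna(sp_len))
      pos <- pos + sp_len
      locus_pos[i] <- pos
      ins <- if (strands[i] == "+") loci[[i]]$locus else revcomp(loci[[i]]$locus)
      seqs <- c(seqs, ins)
      pos <- pos + nchar(ins)
    }
    seqs <- c(seqs, random_dna(SLOT * GENES_PER_CHROM - pos + CHROM_TAIL))
    chrom_seqs[ci] <- paste(seqs, collapse = "")
  }
  ## promoter planting on the assembled focal chromosomes
  motif_counts <- matrix(0L, n_all, nrow(motifs),
                         dimnames = list(ids, motifs$motif_id))
  for (i in seq_len(n_all)) {
    k <- rpois(1L, config$motif_plant_rate)
    if (k == 0L) next
    prom_iv <- if (strands[i] == "+")
      c(locus_pos[i] - 2000L, locus_pos[i])
    else c(locus_pos[i] + nchar(loci[[i]]$locus),
           locus_pos[i] + nchar(loci[[i]]$locus) + 2000L)
    used <- IRanges::IRanges()
    for (j in seq_len(k)) {
      mi <- sample(nrow(motifs), 1L)
      inst <- instantiate_iupac(motifs$iupac[mi])
      w <- nchar(inst)
      for (try in 1:20) {
        off <- sample.int(2000L - w, 1L)
        cand <- IRanges::IRanges(off, off + w - 1L)
        if (length(IRanges::findOverlaps(cand, used)) == 0L) {
          used <- c(used, cand)
          a <- prom_iv[1L] + off       # 0-based start on chromosome
          piece <- if (strands[i] == "+") inst else revcomp(inst)
          substr(chrom_seqs[chrom_of[i]], a + 1L, a + w) <- piece
          motif_counts[i, mi] <- motif_counts[i, mi] + 1L
          break
        }
      }
    }
  }

  ## 5. focal gene models ----------------------------------------------------
  focal_genes <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    focal_genes[[i]] <- locus_gene_model(ids[i], chrom_of[i], strands[i],
                                         locus_pos[i], loci[[i]])
  }
  focal <- GenomeRecord("focal", "focal", chrom_seqs, focal_genes)

  ## 6. relative genomes ------------------------------------------------------
  relatives <- vector("list", length(relnames))
  for (ri in seq_along(relnames)) {
    rn <- relnames[ri]
    rchroms <- character(n_chrom)
    names(rchroms) <- names(chrom_seqs)
    rgenes <- list()
    for (ci in seq_len(n_chrom)) {
      chrom <- names(chrom_seqs)[ci]
      members <- which(chrom_of == chrom)
      seqs <- character(0)
      pos <- 0L
      prev_end <- 0L
      for (i in members) {
        spacer <- substr(chrom_seqs[chrom], prev_end + 1L, locus_pos[i])
        spacer <- apply_indels(mutate_bases(spacer, config$substitution_rate),
                               config$indel_rate)
        seqs <- c(seqs, spacer)
        pos <- pos + nchar(spacer)
        rl <- relative_locus(loci[[i]], classes[i], rn, decoy_host, config)
        if (!is.null(rl$locus)) {
          ins <- if (strands[i] == "+") rl$locus else revcomp(rl$locus)
          if (rl$annotated) {
            rg <- locus_gene_model(paste0(rn, "_", ids[i]), chrom, strands[i],
                                   pos, rl)
            rgenes[[length(rgenes) + 1L]] <- rg
          }
          seqs <- c(seqs, ins)
          pos <- pos + nchar(ins)
        }
        prev_end <- locus_pos[i] + nchar(loci[[i]]$locus)
      }
      tail_seq <- substr(chrom_seqs[chrom], prev_end + 1L, nchar(chrom_seqs[chrom]))
      seqs <- c(seqs, apply_indels(mutate_bases(tail_seq, config$substitution_rate),
                                   config$indel_rate))
      rchroms[ci] <- paste(seqs, collapse = "")
    }
    relatives[[ri]] <- GenomeRecord(rn, relroles[ri], rchroms, rgenes)
  }
  names(relatives) <- relnames

  ## 7. expression matrix -----------------------------------------------------
  tissues <- sprintf("T%02d", seq_len(config$n_tissues))
  samples <- as.vector(t(outer(tissues, seq_len(config$replicates),
                               function(a, b) paste0(a, "__rep", b))))
  fpkm <- t(vapply(seq_len(n_all), function(i)
    expression_profile(classes[i], config), numeric(length(samples))))
  dimnames(fpkm) <- list(ids, samples)
  expr <- ExpressionMatrix(fpkm)

  ## 8. GO map: plastid-related term enriched near type1 loci -----------------
  go_pool <- c("GO:0009657", "GO:0006412", "GO:0009908", "GO:0006950",
               "GO:0055114", "GO:0016301", "GO:0005975", "GO:0006355",
               "GO:0009555", "GO:0048316", "GO:0009737", "GO:0007165")
  denovo_idx <- which(classes %in% c("denovo_type1", "denovo_type2"))
  near_denovo <- rep(FALSE, n_all)
  for (i in denovo_idx) {
    nb <- which(chrom_of == chrom_of[i] & abs(slot_of - slot_of[i]) <= 2L &
                  seq_len(n_all) != i)
    near_denovo[nb] <- TRUE
  }
  go_map <- list()
  for (i in seq_len(n_all)) {
    terms <- sample(go_pool[-1L], sample(1:3, 1L))
    p_plastid <- if (near_denovo[i]) 0.8 else 0.1
    if (runif(1) < p_plastid) terms <- c(go_pool[1L], terms)
    go_map[[ids[i]]] <- sort(unique(terms))
  }
  ## relatives' annotated orthologs inherit the focal gene's terms
  for (rn in relnames) {
    for (gid in names(relatives[[rn]]$genes)) {
      fid <- sub(paste0("^", rn, "_"), "", gid)
      if (fid %in% names(go_map)) go_map[[gid]] <- go_map[[fid]]
    }
  }

  ## 9. QTL intervals ----------------------------------------------------------
  traits <- c("fruit_weight", "sugar_content", "bloom_date", "fruit_dev",
              "chill_requirement", "acidity")
  qtl_genes <- ids[sample(denovo_idx, min(config$n_qtl_covered, length(denovo_idx)))]
  qtl <- NULL
  for (j in seq_along(qtl_genes)) {
    g <- focal$genes[[qtl_genes[j]]]
    span <- gene_span(g)
    pad <- sample(500:3000, 2L)
    qtl <- rbind(qtl, data.frame(chrom = g$chrom,
                                 start = max(0L, span[1L] - pad[1L]),
                                 end = span[2L] + pad[2L],
                                 trait = traits[(j - 1L) %% length(traits) + 1L],
                                 stringsAsFactors = FALSE))
    if (j <= 4L)   # pleiotropy candidates: a second overlapping interval
      qtl <- rbind(qtl, data.frame(chrom = g$chrom,
                                   start = max(0L, span[1L] - pad[2L]),
                                   end = span[2L] + pad[1L],
                                   trait = traits[j %% length(traits) + 1L],
                                   stringsAsFactors = FALSE))
  }
  ## background intervals away from de novo genes
  for (i in utils::head(setdiff(conserved_idx, denovo_idx), 3L)) {
    g <- focal$genes[[ids[i]]]
    span <- gene_span(g)
    qtl <- rbind(qtl, data.frame(chrom = g$chrom, start = span[1L],
                                 end = span[2L] + 1000L, trait = "leaf_shape",
                                 stringsAsFactors = FALSE))
  }

  truth <- data.frame(
    gene_id = ids, planted_class = classes, chrom = chrom_of, slot = slot_of,
    strand = strands, locus_start = locus_pos,
    locus_end = locus_pos + vapply(loci, function(g) nchar(g$locus), 0L),
    donor = vapply(loci, `[[`, "", "donor"),
    expr_class = ifelse(classes %in% c("conserved", "decoy_partial_ortholog"),
                        "broad", "narrow"),
    qtl_covered = ids %in% qtl_genes,
    stringsAsFactors = FALSE)
  attr(truth, "motif_counts") <- motif_counts
  list(focal = focal, relatives = relatives, expression = expr,
       go_map = go_map, motifs = motifs, qtl = qtl, truth = truth,
       optimal_codons = planted_optimal_codons())
}

## split a CDS of cds_nt into n roughly equal exon chunks (codon-agnostic)
exon_split <- function(cds_nt, n) {
  if (n == 1L) return(cds_nt)
  cuts <- round(seq(0L, cds_nt, length.out = n + 1L))
  diff(cuts)
}

## build a GeneModel from a forward locus construct placed at `pos`
locus_gene_model <- function(gene_id, chrom, strand, pos, locus) {
  M <- nchar(locus$locus)
  ex <- locus$exons
  if (strand == "+") {
    exons <- iv_mat(pos + ex[, "start"], pos + ex[, "end"])
  } else {
    exons <- iv_mat(pos + M - ex[, "end"], pos + M - ex[, "start"])
  }
  GeneModel(gene_id, chrom, strand, exons, exons, "protein_coding")
}

## the locus content of a planted gene in one relative genome
relative_locus <- function(locus, class, relname, decoy_host, config) {
  rate <- config$substitution_rate
  if (class == "conserved" ||
      (class == "decoy_partial_ortholog" && relname == decoy_host)) {
    ## intact annotated ortholog: keep-ORF mutated exons (pre-generated so
    ## the construction check saw the same proteome), mutated introns
    parts <- exon_split(nchar(locus$cds), nrow(locus$exons))
    mcds <- if (!is.null(locus$rel_cds[[relname]])) locus$rel_cds[[relname]]
      else mutate_cds_keep_orf(locus$cds, rate)
    seq <- ""
    cds_pos <- cumsum(c(0L, parts))
    for (j in seq_len(nrow(locus$exons))) {
      seq <- paste0(seq, substr(mcds, cds_pos[j] + 1L, cds_pos[j + 1L]))
      if (j < nrow(locus$exons)) {
        intr <- substr(locus$locus, locus$exons[j, "end"] + 1L,
                       locus$exons[j + 1L, "start"])
        seq <- paste0(seq, mutate_bases(intr, rate))
      }
    }
    return(list(locus = seq, exons = locus$exons, annotated = TRUE))
  }
  if (class == "orf_trap") {
    ## intact but unannotated ORF, synonymously diverged
    seq <- mutate_cds_synonymous(locus$cds, rate_codon = 3 * rate)
    return(list(locus = seq, annotated = FALSE))
  }
  if (class == "denovo_type2") {
    ## ancestral state: only the non-donor portion, disrupted
    rest <- substr(locus$cds, 4L + locus$frag_nt, nchar(locus$cds))
    rest <- substr(rest, 1L, nchar(rest) - nchar(rest) %% 3L)
    seq <- disrupt_to_noncoding(mutate_bases(rest, rate))
    return(list(locus = seq, annotated = FALSE))
  }
  ## denovo_type1, decoy in non-host relatives: disrupted noncoding ancestor
  seq <- disrupt_to_noncoding(mutate_bases(locus$cds, rate))
  list(locus = seq, annotated = FALSE)
}

#' Simulated expression matrix with planted co-expression blocks
#'
#' Genes in a block share a latent per-sample factor (pairwise correlation
#' about \code{within_cor} on the log scale); background genes are
#' independent noise. Used to exercise module detection.
#'
#' @param n_blocks,block_size,n_background design
#' @param n_tissues,replicates sample layout
#' @param within_cor target within-block correlation
#' @param seed RNG seed
#' @return list(mat = \code{\link{ExpressionMatrix}}, block = named
#'   assignment vector, "background" for noise genes)
#' @export
simulate_coexpression <- function(n_blocks = 2L, block_size = 50L,
                                  n_background = 100L, n_tissues = 19L,
                                  replicates = 3L, within_cor = 0.9,
                                  seed = 7L) {
  set.seed(seed)
  ns <- n_tissues * replicates
  tissues <- sprintf("T%02d", seq_len(n_tissues))
  samples <- as.vector(t(outer(tissues, seq_len(replicates),
                               function(a, b) paste0(a, "__rep", b))))
  n_genes <- n_blocks * block_size + n_background
  ids <- sprintf("cx%04d", seq_len(n_genes))
  block <- setNames(c(rep(sprintf("block%d", seq_len(n_blocks)), each = block_size),
                      rep("background", n_background)), ids)
  ## tissue-level latent factors, shared by replicates (plus replicate noise)
  z <- matrix(rnorm(n_genes * ns), n_genes, ns)
  for (b in seq_len(n_blocks)) {
    f_t <- rnorm(n_tissues, 0, 1)
    f <- rep(f_t, each = replicates)
    rows <- which(block == sprintf("block%d", b))
    z[rows, ] <- sqrt(within_cor) * matrix(f, length(rows), ns, byrow = TRUE) +
      sqrt(1 - within_cor) * z[rows, ]
  }
  fpkm <- 2^(3 + 1.5 * z)
  dimnames(fpkm) <- list(ids, samples)
  list(mat = ExpressionMatrix(fpkm), block = block)
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Emits FASTA + GFF3 per genome, the expression TSV, GO map, motif library,
#' QTL TSV (1-based inclusive) and truth_table.tsv into \code{dir}.
#'
#' @param sim result of \code{\link{simulate_genomes}}
#' @param dir output directory (created)
#' @return dir, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_genomes <- c(list(focal = sim$focal), sim$relatives)
  for (g in all_genomes) {
    write_fasta(g$chromosomes, file.path(dir, paste0(g$genome_id, ".fa")))
    write_gff3(g$genes, file.path(dir, paste0(g$genome_id, ".gff3")))
  }
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_go_map(sim$go_map, file.path(dir, "go_map.tsv"))
  write.table(sim$motifs, file.path(dir, "motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_qtl(sim$qtl, file.path(dir, "qtl.tsv"))
  write.table(sim$truth, file.path(dir, "truth_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
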