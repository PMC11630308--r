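## De novo gene calling: map candidate CDS onto relative genomes, classify the
## hit regions against the relative's annotation, screen out unannotated-ORF
## traps, apply the in-group/out-group noncoding support rule, and classify
## calls by origin.
##
## A candidate becomes a putative de novo gene iff it maps to noncoding
## regions in at least one in-group genome AND at least one out-group genome.

#' Default de novo calling parameters
#' @return named list of thresholds; see the individual operations
#' @export
denovo_params <- function() {
  list(min_identity = 0.7,    # per-hit DNA identity floor
       min_coverage = 0.5,    # chained query coverage needed for support
       min_score = 25,        # per-segment alignment score floor (noise gate)
       chain_gap = 5000L,     # max target gap when chaining co-linear hits
       tau_nc = 0.05,         # max annotated overlap still called noncoding
       trap_min_span = 0.8,   # ORF trap: min candidate-protein span covered
       trap_min_pid = 0.6,    # ORF trap: min protein identity
       trap_window = 300L,    # ORF trap: flank around the hit span (nt)
       theta = 0.5,           # max chimeric fraction for Type II/III
       te_class = "type3")    # label for TE-only chimeras: "type3" or "type2"
}

dna_scoring <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE, type = "DNA")
    cache
  }
})

#' Map a candidate CDS onto a relative genome
#'
#' Seed-and-extend local DNA alignment (match +1, mismatch -2, gap open 5 /
#' extend 2 costs) of the candidate against both strands of every chromosome.
#' Exact 12-mer seeds locate alignable windows; each window is aligned in
#' full. Co-linear alignments on one chromosome and strand separated by at
#' most \code{chain_gap} are chained into one hit whose query coverage is the
#' union of its segments' query intervals.
#'
#' Hits below \code{min_identity} are always discarded. By default chains
#' whose query coverage falls below \code{min_coverage} are also dropped; the
#' caller can keep them (\code{drop_partial = FALSE}) because sub-coverage
#' alignments onto annotated exons are the evidence for chimeric (Type II/III)
#' origin even though they never count as noncoding support.
#'
#' @param candidate_cds DNA string, length >= 30 nt
#' @param genome \code{\link{GenomeRecord}}
#' @param min_identity,min_coverage,chain_gap see above
#' @param min_score minimal alignment score per segment; suppresses the
#'   short chance alignments any seeded scan of a whole genome produces
#' @param drop_partial drop chains with coverage < min_coverage
#' @param seed_len,seed_step exact-seed length and spacing
#' @return list of hits; each hit has genome, chrom, strand, segments
#'   (data.frame qstart/qend/tstart/tend, 0-based half-open, query in original
#'   orientation), identity, query_coverage, target_span, passes_coverage
#' @export
map_dna <- function(candidate_cds, genome, min_identity = 0.7, min_coverage = 0.5,
                    chain_gap = 5000L, min_score = 25, drop_partial = TRUE,
                    seed_len = 12L, seed_step = 3L) {
  L <- nchar(candidate_cds)
  if (L < 30L) stop("candidate CDS must be at least 30 nt")
  segs <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") candidate_cds else revcomp(candidate_cds)
    starts <- seq(1L, L - seed_len + 1L, by = seed_step)
    seeds <- Biostrings::DNAStringSet(substring(qs, starts, starts + seed_len - 1L))
    pd <- Biostrings::PDict(seeds)
    for (chrom in names(genome$chromosomes)) {
      subj <- Biostrings::DNAString(genome$chromosomes[[chrom]])
      mt <- Biostrings::matchPDict(pd, subj)
      hit_i <- which(S4Vectors::elementNROWS(mt) > 0L)
      if (!length(hit_i)) next
      tpos <- unlist(lapply(hit_i, function(i) S4Vectors::start(mt[[i]])))
      qpos <- rep(starts[hit_i], S4Vectors::elementNROWS(mt)[hit_i])
      ## cluster seed matches into windows by target position
      ord <- order(tpos)
      tpos <- tpos[ord]; qpos <- qpos[ord]
      brk <- c(0L, which(diff(tpos) > L + 200L), length(tpos))
      for (k in seq_len(length(brk) - 1L)) {
        idx <- (brk[k] + 1L):brk[k + 1L]
        w0 <- max(1L, min(tpos[idx] - qpos[idx]) - 50L)
        w1 <- min(length(subj), max(tpos[idx] + (L - qpos[idx])) + 50L)
        win <- as.character(Biostrings::subseq(subj, w0, w1))
        seg <- align_dna_window(qs, win, w0 - 1L, strand, L)
        if (!is.null(seg) && seg$identity >= min_identity &&
            seg$score >= min_score) {
          seg$chrom <- chrom
          segs[[length(segs) + 1L]] <- seg
        }
      }
    }
  }
  chain_segments(segs, genome$genome_id, L, chain_gap, min_coverage, drop_partial)
}

## align strand-oriented query against one window; returns one segment or NULL
align_dna_window <- function(qs, window, offset0, strand, L) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qs), Biostrings::DNAString(window), type = "local",
    substitutionMatrix = dna_scoring(), gapOpening = 5, gapExtension = 2)
  if (Biostrings::score(pa) <= 0) return(NULL)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  ident <- mean(p == s)
  ps <- S4Vectors::start(Biostrings::pattern(pa))
  pe <- S4Vectors::end(Biostrings::pattern(pa))
  ts <- S4Vectors::start(Biostrings::subject(pa)) + offset0
  te <- S4Vectors::end(Biostrings::subject(pa)) + offset0
  if (strand == "+") { q0 <- ps - 1L; q1 <- pe }
  else { q0 <- L - pe; q1 <- L - ps + 1L }
  list(qstart = q0, qend = q1, tstart = ts - 1L, tend = te,
       strand = strand, identity = ident, score = Biostrings::score(pa))
}

## chain co-linear segments (same chrom/strand, target gap <= chain_gap)
chain_segments <- function(segs, genome_id, L, chain_gap, min_coverage, drop_partial) {
  if (!length(segs)) return(list())
  key <- vapply(segs, function(s) paste(s$chrom, s$strand), "")
  hits <- list()
  for (k in unique(key)) {
    grp <- segs[key == k]
    ts <- vapply(grp, `[[`, 0L, "tstart")
    grp <- grp[order(ts)]
    ts <- sort(ts)
    brk <- c(0L, which(diff(ts) > chain_gap), length(grp))
    for (i in seq_len(length(brk) - 1L)) {
      mem <- grp[(brk[i] + 1L):brk[i + 1L]]
      segdf <- do.call(rbind, lapply(mem, function(s)
        data.frame(qstart = s$qstart, qend = s$qend, tstart = s$tstart,
                   tend = s$tend, identity = s$identity)))
      cov <- iv_union_width(iv_mat(segdf$qstart, segdf$qend)) / L
      wid <- segdf$qend - segdf$qstart
      hits[[length(hits) + 1L]] <- list(
        genome = genome_id, chrom = mem[[1L]]$chrom, strand = mem[[1L]]$strand,
        segments = segdf,
        identity = sum(segdf$identity * wid) / sum(wid),
        query_coverage = cov,
        target_span = c(min(segdf$tstart), max(segdf$tend)),
        passes_coverage = cov >= min_coverage)
    }
  }
  if (drop_partial) hits <- Filter(function(h) h$passes_coverage, hits)
  hits
}

## per-genome annotation intervals (exons of protein-coding genes and of
## TE-biotype genes), split by chromosome
annotation_intervals <- function(genome, biotype) {
  keep <- vapply(genome$genes, function(g) g$biotype == biotype, TRUE)
  out <- list()
  for (g in genome$genes[keep]) {
    out[[g$chrom]] <- rbind(out[[g$chrom]], g$exons)
  }
  out
}

## both biotype interval sets for one genome, computed once per pipeline pass
genome_annotation <- function(genome) {
  list(protein_coding = annotation_intervals(genome, "protein_coding"),
       transposable_element = annotation_intervals(genome, "transposable_element"))
}

#' Classify the genomic region a hit falls in
#'
#' Computes the fraction of the hit's aligned target bases that lie inside
#' annotated protein-coding exons and inside TE annotations, and labels the
#' hit coding / te / noncoding: coding if the exon overlap fraction exceeds
#' \code{tau_nc}, else te if the TE overlap fraction does, else noncoding.
#'
#' @param hit one hit from \code{\link{map_dna}}
#' @param genome the target \code{\link{GenomeRecord}}
#' @param tau_nc overlap tolerance below which a region still counts as
#'   noncoding (default 0.05)
#' @param ann optional precomputed annotation intervals for the genome (an
#'   internal cache used by \code{\link{call_denovo}})
#' @return the hit with exon_overlap_fraction, te_overlap_fraction and
#'   region_class filled in
#' @export
classify_region <- function(hit, genome, tau_nc = 0.05, ann = NULL) {
  if (is.null(ann)) ann <- genome_annotation(genome)
  aligned <- iv_mat(hit$segments$tstart, hit$segments$tend)
  nb <- iv_union_width(aligned)
  ex <- ann$protein_coding[[hit$chrom]]
  te <- ann$transposable_element[[hit$chrom]]
  hit$exon_overlap_fraction <- if (is.null(ex)) 0 else iv_overlap_width(aligned, ex) / nb
  hit$te_overlap_fraction <- if (is.null(te)) 0 else iv_overlap_width(aligned, te) / nb
  hit$region_class <- if (hit$exon_overlap_fraction > tau_nc) "coding"
    else if (hit$te_overlap_fraction > tau_nc) "te" else "noncoding"
  hit
}

## maximal ATG->stop ORFs (first ATG per inter-stop segment) in all six frames
six_frame_orfs <- function(dna) orf_scan(dna)$peptide

#' Check whether a noncoding hit is an unannotated-ORF trap
#'
#' Six-frame scan of the hit's aligned target span plus \code{window} nt of
#' flank. The hit is a trap iff some ATG-to-stop ORF encodes a peptide whose
#' local alignment to the candidate protein covers at least \code{min_span}
#' of it at identity >= \code{min_pid}: the "noncoding" region then actually
#' harbors an intact unannotated homolog, and the hit cannot support a de
#' novo call.
#'
#' @param candidate_protein peptide of the candidate (no trailing stop)
#' @param hit a noncoding hit from \code{\link{map_dna}}
#' @param genome target \code{\link{GenomeRecord}}
#' @param min_span,min_pid,window trap thresholds
#' @return TRUE iff the hit is a trap
#' @export
orf_trap_check <- function(candidate_protein, hit, genome,
                           min_span = 0.8, min_pid = 0.6, window = 300L) {
  chrom <- genome$chromosomes[[hit$chrom]]
  a <- max(0L, hit$target_span[1L] - window)
  b <- min(nchar(chrom), hit$target_span[2L] + window)
  region <- substr(chrom, a + 1L, b)
  Lp <- nchar(candidate_protein)
  min_len <- if (min_span > 0) floor(min_span * Lp * 0.9) else 1L
  for (pep in six_frame_orfs(region)) {
    if (nchar(pep) < max(1L, min_len)) next
    al <- align_protein(candidate_protein, pep)
    span_frac <- (al$query_span[2L] - al$query_span[1L] + 1L) / Lp
    if (span_frac >= min_span && al$identity >= min_pid) return(TRUE)
  }
  FALSE
}

#' Call de novo genes from candidates and relative genomes
#'
#' For every candidate, maps its CDS onto each relative genome, classifies
#' the hit regions, and screens qualifying noncoding hits against unannotated
#' ORFs. A genome supports the candidate iff it has at least one non-trap
#' noncoding hit with chained query coverage >= \code{min_coverage}. Status:
#' \code{putative} with support from >= 1 in-group AND >= 1 out-group genome;
#' \code{excluded_orf_trap} when support would have been reached but the
#' deciding noncoding hits were traps; \code{excluded_no_support} otherwise.
#' Putative calls are then typed with \code{\link{classify_type}}.
#'
#' @param candidates named character vector of candidate CDS sequences
#' @param relatives list of \code{\link{GenomeRecord}} with roles ingroup /
#'   outgroup (at least one of each)
#' @param params as \code{\link{denovo_params}}
#' @return list of DeNovoCall objects (lists) with candidate_id, status,
#'   type, f_gene, f_te, supporting_genomes, evidence
#' @export
call_denovo <- function(candidates, relatives, params = denovo_params()) {
  roles <- vapply(relatives, `[[`, "", "role")
  if (!any(roles == "ingroup") || !any(roles == "outgroup"))
    stop("need at least one ingroup and one outgroup relative genome")
  ann_cache <- lapply(relatives, genome_annotation)
  calls <- vector("list", length(candidates))
  names(calls) <- names(candidates)
  for (id in names(candidates)) {
    cds <- candidates[[id]]
    protein <- sub("\\*$", "", translate_dna(cds))
    evidence <- list()
    support <- support_with_traps <- character(0)
    for (gi in seq_along(relatives)) {
      gnm <- relatives[[gi]]
      hits <- map_dna(cds, gnm, min_identity = params$min_identity,
                      min_coverage = params$min_coverage,
                      chain_gap = params$chain_gap,
                      min_score = params$min_score, drop_partial = FALSE)
      got_nc <- got_nontrap <- FALSE
      for (h in hits) {
        h <- classify_region(h, gnm, tau_nc = params$tau_nc,
                             ann = ann_cache[[gi]])
        h$candidate_id <- id
        h$is_trap <- FALSE
        if (h$region_class == "noncoding" && h$passes_coverage) {
          got_nc <- TRUE
          h$is_trap <- orf_trap_check(protein, h, gnm,
                                      min_span = params$trap_min_span,
                                      min_pid = params$trap_min_pid,
                                      window = params$trap_window)
          if (!h$is_trap) got_nontrap <- TRUE
        }
        evidence[[length(evidence) + 1L]] <- h
      }
      if (got_nontrap) support <- c(support, gnm$genome_id)
      if (got_nc) support_with_traps <- c(support_with_traps, gnm$genome_id)
    }
    ingroups <- unname(vapply(relatives, `[[`, "", "genome_id")[roles == "ingroup"])
    outgroups <- unname(vapply(relatives, `[[`, "", "genome_id")[roles == "outgroup"])
    ok <- function(s) any(s %in% ingroups) && any(s %in% outgroups)
    status <- if (ok(support)) "putative"
      else if (ok(support_with_traps)) "excluded_orf_trap"
      else "excluded_no_support"
    cl <- list(candidate_id = id, status = status, type = "unclassified",
               f_gene = NA_real_, f_te = NA_real_,
               supporting_genomes = list(ingroup = intersect(support, ingroups),
                                         outgroup = intersect(support, outgroups)),
               evidence = evidence, cds_length = nchar(cds))
    if (status == "putative")
      cl <- classify_type(cl, relatives, theta = params$theta,
                          te_class = params$te_class, ann_cache = ann_cache)
    calls[[id]] <- cl
  }
  calls
}

## map a target subinterval [a, b) of a segment back onto query coordinates
seg_query_interval <- function(seg, strand, a, b) {
  scale <- (seg$qend - seg$qstart) / (seg$tend - seg$tstart)
  if (strand == "+") {
    qa <- seg$qstart + floor((a - seg$tstart) * scale)
    qb <- seg$qstart + ceiling((b - seg$tstart) * scale)
  } else {
    qa <- seg$qstart + floor((seg$tend - b) * scale)
    qb <- seg$qstart + ceiling((seg$tend - a) * scale)
  }
  c(max(seg$qstart, qa), min(seg$qend, qb))
}

## query intervals of a call's evidence whose target bases carry a biotype
ancestral_query_intervals <- function(call, relatives, biotype, ann_cache = NULL) {
  ids <- vapply(relatives, `[[`, "", "genome_id")
  if (is.null(ann_cache)) ann_cache <- lapply(relatives, genome_annotation)
  names(ann_cache) <- ids
  out <- NULL
  for (h in call$evidence) {
    ann <- ann_cache[[h$genome]][[biotype]][[h$chrom]]
    if (is.null(ann)) next
    ann <- IRanges::reduce(iv_to_iranges(ann))
    for (j in seq_len(nrow(h$segments))) {
      seg <- h$segments[j, ]
      ov <- IRanges::intersect(ann, iv_to_iranges(iv_mat(seg$tstart, seg$tend)))
      for (k in seq_along(ov)) {
        qi <- seg_query_interval(seg, h$strand,
                                 S4Vectors::start(ov)[k] - 1L, S4Vectors::end(ov)[k])
        if (qi[2L] > qi[1L]) out <- rbind(out, qi)
      }
    }
  }
  out
}

#' Classify a putative de novo call by origin
#'
#' Computes f_gene (f_te): the fraction of the candidate CDS covered by the
#' union, over all relatives and all evidence alignments, of query bases
#' aligned onto annotated protein-coding exons (TE annotations). Type I iff
#' both are zero (entirely noncoding ancestry); Type II iff a minor fraction
#' derives from pre-existing genes (f_gene > 0, f_gene + f_te <= theta);
#' Type III iff only TE-derived (f_gene = 0 < f_te <= theta). When
#' f_gene + f_te > theta the sequence is majority ancestral-coding and the
#' call is demoted to excluded_no_support. \code{te_class = "type2"} folds
#' TE-only chimeras into Type II instead (the two published descriptions of
#' Type III conflict; both mappings are exposed).
#'
#' @param call a DeNovoCall from \code{\link{call_denovo}}
#' @param relatives the relative genomes used for calling
#' @param theta maximum chimeric fraction (default 0.5)
#' @param te_class "type3" (default) or "type2"
#' @param ann_cache internal per-genome annotation cache
#' @return the call with f_gene, f_te, type (and possibly demoted status)
#' @export
classify_type <- function(call, relatives, theta = 0.5, te_class = "type3",
                          ann_cache = NULL) {
  L <- call$cds_length
  gi <- ancestral_query_intervals(call, relatives, "protein_coding", ann_cache)
  ti <- ancestral_query_intervals(call, relatives, "transposable_element", ann_cache)
  f_gene <- if (is.null(gi)) 0 else iv_union_width(iv_mat(gi[, 1L], gi[, 2L])) / L
  f_te <- if (is.null(ti)) 0 else iv_union_width(iv_mat(ti[, 1L], ti[, 2L])) / L
  call$f_gene <- f_gene
  call$f_te <- f_te
  if (f_gene + f_te > theta) {
    call$status <- "excluded_no_support"   # majority ancestral-coding
    call$type <- "unclassified"
  } else if (f_gene == 0 && f_te == 0) {
    call$type <- "I"
  } else if (f_gene > 0) {
    call$type <- "II"
  } else {
    call$type <- if (te_class == "type3") "III" else "II"
  }
  call
}

#' Calls as a data.frame (one row per candidate)
#' @param calls list from \code{\link{call_denovo}}
#' @return data.frame
#' @export
calls_to_df <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) data.frame(
    candidate_id = cl$candidate_id, status = cl$status, type = cl$type,
    f_gene = cl$f_gene, f_te = cl$f_te,
    ingroup_support = paste(cl$supporting_genomes$ingroup, collapse = ","),
    outgroup_support = paste(cl$supporting_genomes$outgroup, collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Write calls and their evidence to TSV
#' @param calls list from \code{\link{call_denovo}}
#' @param calls_path,evidence_path output files
#' @export
write_calls <- function(calls, calls_path, evidence_path = NULL) {
  write.table(calls_to_df(calls), calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(evidence_path)) {
    ev <- do.call(rbind, lapply(calls, function(cl)
      do.call(rbind, lapply(cl$evidence, function(h) data.frame(
        candidate_id = cl$candidate_id, genome = h$genome, chrom = h$chrom,
        strand = h$strand, target_start = h$target_span[1L],
        target_end = h$target_span[2L], identity = h$identity,
        query_coverage = h$query_coverage, region_class = h$region_class,
        is_trap = isTRUE(h$is_trap), stringsAsFactors = FALSE)))))
    write.table(ev, evidence_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(calls_path)
}
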