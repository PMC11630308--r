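## replace three internal codons by stops: a minimally diverged noncoding copy
disrupt3 <- function(cds) {
  n <- nchar(cds) %/% 3L
  for (i in round(n * c(0.25, 0.5, 0.75)))
    substr(cds, 3 * i - 2, 3 * i) <- "TAA"
  cds
}

test_that("mapping finds exact substrings on both strands", {
  set.seed(20)
  cds <- random_orf(60)   # 180 nt
  fwd <- toy_genome("gF", "ingroup", list(x = cds))
  hits <- map_dna(cds, fwd)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$identity, 1.0)
  expect_equal(hits[[1]]$query_coverage, 1.0)
  expect_equal(hits[[1]]$strand, "+")

  rev <- toy_genome("gR", "ingroup",
                    list(x = as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(cds)))))
  hits_r <- map_dna(cds, rev)
  expect_length(hits_r, 1)
  expect_equal(hits_r[[1]]$strand, "-")
  expect_equal(hits_r[[1]]$query_coverage, 1.0)
  expect_error(map_dna(substr(cds, 1, 20), fwd), "at least 30 nt")
})

test_that("region classification thresholds annotated overlap at tau_nc", {
  set.seed(21)
  chrom <- c(chr1 = random_dna_str(2000))
  hit <- list(genome = "gX", chrom = "chr1", strand = "+",
              segments = data.frame(qstart = 0L, qend = 100L,
                                    tstart = 1000L, tend = 1100L,
                                    identity = 1),
              target_span = c(1000L, 1100L), query_coverage = 1,
              passes_coverage = TRUE)
  exon_in <- GeneModel("gin", "chr1", "+", rbind(c(1000L, 1100L)),
                       rbind(c(1000L, 1100L)))
  g_in <- GenomeRecord("gX", "ingroup", chrom, list(exon_in))
  expect_equal(classify_region(hit, g_in)$region_class, "coding")

  g_none <- GenomeRecord("gX", "ingroup", chrom, list())
  h0 <- classify_region(hit, g_none)
  expect_equal(h0$region_class, "noncoding")
  expect_equal(h0$exon_overlap_fraction, 0)

  ## 4% exon overlap: noncoding at tau 0.05, coding at tau 0.03
  exon_4 <- GeneModel("g4", "chr1", "+", rbind(c(1096L, 1200L)),
                      rbind(c(1096L, 1200L)))
  g4 <- GenomeRecord("gX", "ingroup", chrom, list(exon_4))
  expect_equal(classify_region(hit, g4, tau_nc = 0.05)$region_class, "noncoding")
  expect_equal(classify_region(hit, g4, tau_nc = 0.03)$region_class, "coding")
})

test_that("ORF-trap screen flags intact hidden homologs but not disrupted loci", {
  set.seed(22)
  cds <- random_orf(80)
  protein <- sub("\\*$", "", denovoscan:::translate_dna(cds))
  intact <- toy_genome("gT", "ingroup", list(x = cds))
  h <- map_dna(cds, intact)[[1]]
  expect_true(orf_trap_check(protein, h, intact))

  broken <- toy_genome("gB", "ingroup", list(x = disrupt3(cds)))
  hb <- map_dna(cds, broken)[[1]]
  expect_false(orf_trap_check(protein, hb, broken))
  ## degenerate limit: any ORF at all is a trap
  expect_true(orf_trap_check(protein, hb, broken, min_span = 0, min_pid = 0))
})

test_that("the in-group/out-group support rule decides the call status", {
  set.seed(23)
  cds <- random_orf(80)
  nc <- disrupt3(cds)
  g_in <- toy_genome("inA", "ingroup", list(x = nc))
  g_out <- toy_genome("outA", "outgroup", list(x = nc))
  g_out_empty <- toy_genome("outB", "outgroup", list(y = random_dna_str(300)))

  both <- call_denovo(c(cand = cds), list(g_in, g_out))
  expect_equal(both$cand$status, "putative")
  expect_equal(both$cand$type, "I")
  expect_setequal(both$cand$supporting_genomes$ingroup, "inA")
  expect_setequal(both$cand$supporting_genomes$outgroup, "outA")

  one_side <- call_denovo(c(cand = cds), list(g_in, g_out_empty))
  expect_equal(one_side$cand$status, "excluded_no_support")

  trap_in <- toy_genome("inT", "ingroup", list(x = cds))   # intact ORF
  trapped <- call_denovo(c(cand = cds), list(trap_in, g_out))
  expect_equal(trapped$cand$status, "excluded_orf_trap")

  expect_error(call_denovo(c(cand = cds), list(g_in)), "outgroup")
})

test_that("chimeric fractions drive Type I/II/III and the demotion rule", {
  set.seed(24)
  donor <- random_orf(100)                       # 300 nt "pre-existing gene"
  frag <- substr(donor, 101, 190)                # 90 nt from its interior
  rest <- random_orf(70)                         # 210 nt novel part
  cand <- paste0(frag, rest)                     # 300 nt chimera, f_gene ~ 0.3
  nc_rest <- disrupt3(rest)

  ## loci sit > 5 kb apart so the donor and ancestral hits are not chained
  mk_rel <- function(id, role, te = FALSE) {
    toy_genome(id, role, list(donor = donor, anc = nc_rest),
               genes = list(list(id = paste0(id, "_donor"), insert = "donor",
                                 biotype = if (te) "transposable_element"
                                 else "protein_coding")),
               spacer = 6000L)
  }
  calls <- call_denovo(c(cand = cand),
                       list(mk_rel("inA", "ingroup"), mk_rel("outA", "outgroup")))
  expect_equal(calls$cand$status, "putative")
  expect_equal(calls$cand$type, "II")
  expect_gt(calls$cand$f_gene, 0.2)
  expect_lte(calls$cand$f_gene, 0.5)
  expect_equal(calls$cand$f_te, 0)

  ## same layout but the donor is annotated as a transposable element
  calls_te <- call_denovo(c(cand = cand),
                          list(mk_rel("inA", "ingroup", te = TRUE),
                               mk_rel("outA", "outgroup", te = TRUE)))
  expect_equal(calls_te$cand$type, "III")
  expect_gt(calls_te$cand$f_te, 0.2)
  expect_equal(calls_te$cand$f_gene, 0)

  ## majority ancestral-coding: noncoding support exists (a full disrupted
  ## copy), but 60% of the CDS also aligns into the donor exon -> demoted
  frag_big <- substr(donor, 31, 210)             # 180 of 300 nt -> f_gene ~ 0.6
  cand_big <- paste0(frag_big, substr(rest, 1, 120))
  nc_big <- disrupt3(cand_big)
  mk2 <- function(id, role)
    toy_genome(id, role, list(donor = donor, anc = nc_big),
               genes = list(list(id = paste0(id, "_d"), insert = "donor")),
               spacer = 6000L)
  calls_big <- call_denovo(c(cand = cand_big),
                           list(mk2("inA", "ingroup"), mk2("outA", "outgroup")))
  expect_equal(calls_big$cand$status, "excluded_no_support")
  expect_equal(calls_big$cand$type, "unclassified")
  expect_gt(calls_big$cand$f_gene, 0.5)
})

test_that("classified type counts partition the classified calls", {
  res <- fix_res()
  types <- vapply(res$calls, `[[`, "", "type")
  status <- vapply(res$calls, `[[`, "", "status")
  classified <- status %in% c("putative", "confirmed_expressed")
  expect_equal(sum(types %in% c("I", "II", "III")), sum(classified))
  expect_true(all(types[!classified] == "unclassified"))
})

test_that("stricter identity/coverage thresholds never enlarge the putative set", {
  set.seed(25)
  cds <- random_orf(80)
  nc <- disrupt3(cds)
  rels <- list(toy_genome("inA", "ingroup", list(x = nc)),
               toy_genome("outA", "outgroup", list(x = nc)))
  putative_at <- function(p) {
    calls <- call_denovo(c(cand = cds), rels, p)
    names(calls)[vapply(calls, `[[`, "", "status") == "putative"]
  }
  base <- denovo_params()
  loose <- putative_at(base)
  strict_id <- base; strict_id$min_identity <- 0.995
  strict_cov <- base; strict_cov$min_coverage <- 0.999
  expect_true(all(putative_at(strict_id) %in% loose))
  expect_true(all(putative_at(strict_cov) %in% loose))
  expect_length(putative_at(strict_id), 0)   # 3 planted stops break identity 0.995
})

test_that("union coverage equals the per-base boolean OR oracle", {
  set.seed(26)
  for (i in 1:50) {
    L <- sample(50:400, 1)
    n <- sample(1:6, 1)
    s <- sample(0:(L - 10), n, replace = TRUE)
    e <- pmin(L, s + sample(5:80, n, replace = TRUE))
    frac <- denovoscan:::iv_union_width(denovoscan:::iv_mat(s, e)) / L
    expect_equal(frac, union_cov_oracle(s, e, L), tolerance = 1e-10)
  }
})

test_that("calls export to TSV with their evidence", {
  set.seed(27)
  cds <- random_orf(70)
  nc <- disrupt3(cds)
  calls <- call_denovo(c(candX = cds),
                       list(toy_genome("inA", "ingroup", list(x = nc)),
                            toy_genome("outA", "outgroup", list(x = nc))))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_calls(calls, f1, f2)
  out <- read.delim(f1)
  expect_equal(out$candidate_id, "candX")
  expect_equal(out$status, "putative")
  ev <- read.delim(f2)
  expect_true(all(ev$region_class == "noncoding"))
})
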