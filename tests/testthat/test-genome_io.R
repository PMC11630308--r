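test_that("FASTA reading normalizes case and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), f)
  expect_identical(read_fasta(f), c(chr1 = "ACGT"))

  writeLines(c(">c1", "ACGT", ">c1", "A"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">c1", "ACQT"), f)
  expect_error(read_fasta(f), "non-ACGTN")
})

test_that("FASTA write -> read round trip is the identity", {
  set.seed(1)
  chroms <- c(chr1 = random_dna_str(500), chr2 = random_dna_str(321),
              chr3 = random_dna_str(77))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(chroms, f)
  expect_identical(read_fasta(f), chroms)
})

test_that("GFF3 coordinates are converted to 0-based half-open", {
  ## file start=11,end=20 (1-based inclusive) -> internal [10, 20)
  set.seed(2)
  chrom <- c(chr1 = random_dna_str(100))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t11\t20\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t11\t20\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t11\t20\t.\t+\t.\tID=e1;Parent=t1",
               "chr1\tx\tCDS\t11\t20\t.\t+\t0\tID=c1;Parent=t1"), f)
  genes <- read_gff3(f, chrom)
  expect_equal(unname(genes[["g1"]]$cds[1, ]), c(10L, 20L))
})

test_that("internal/GFF3 coordinate conversion holds on randomized intervals", {
  set.seed(3)
  for (i in 1:25) {
    s1 <- sample(1:500, 1)
    e1 <- s1 + 3 * sample(5:50, 1) - 1     # 1-based inclusive, length %% 3 == 0
    chrom <- c(chr1 = random_dna_str(e1 + 50))
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 sprintf("chr1\tx\tgene\t%d\t%d\t.\t+\t.\tID=g", s1, e1),
                 sprintf("chr1\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=t;Parent=g", s1, e1),
                 sprintf("chr1\tx\texon\t%d\t%d\t.\t+\t.\tID=e;Parent=t", s1, e1),
                 sprintf("chr1\tx\tCDS\t%d\t%d\t.\t+\t0\tID=c;Parent=t", s1, e1)), f)
    g <- read_gff3(f, chrom)[["g"]]
    expect_equal(unname(g$cds[1, "start"]), s1 - 1L)
    expect_equal(unname(g$cds[1, "end"]), e1)
  }
})

test_that("the representative transcript with the longest CDS is kept", {
  set.seed(4)
  chrom <- c(chr1 = random_dna_str(1200))
  f <- withr::local_tempfile(fileext = ".gff3")
  ## t1: CDS total 300 nt; t2: CDS total 450 nt -> t2 retained
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t1000\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t1\t300\t.\t+\t.\tID=t1e;Parent=t1",
               "chr1\tx\tCDS\t1\t300\t.\t+\t0\tID=t1c;Parent=t1",
               "chr1\tx\tmRNA\t1\t1000\t.\t+\t.\tID=t2;Parent=g1",
               "chr1\tx\texon\t101\t550\t.\t+\t.\tID=t2e;Parent=t2",
               "chr1\tx\tCDS\t101\t550\t.\t+\t0\tID=t2c;Parent=t2"), f)
  g <- read_gff3(f, chrom)[["g1"]]
  expect_equal(sum(g$cds[, "end"] - g$cds[, "start"]), 450L)
})

test_that("CDS extraction splices and strand-corrects", {
  chroms <- c(c1 = "ATGAAACCC")
  g <- GeneModel("gp", "c1", "+", rbind(c(0L, 9L)),
                 rbind(c(0L, 3L), c(6L, 9L)))
  expect_identical(extract_cds(g, chroms), "ATGCCC")

  chroms2 <- c(c1 = "ATGAAA")
  gm <- GeneModel("gm", "c1", "-", rbind(c(0L, 6L)), rbind(c(0L, 6L)))
  expect_identical(extract_cds(gm, chroms2), "TTTCAT")
})

test_that("a CDS not divisible by 3 is kept but flagged non-codon-clean", {
  chroms <- c(c1 = "ATGAAACC")
  g <- GeneModel("g", "c1", "+", rbind(c(0L, 8L)), rbind(c(0L, 8L)))
  expect_false(g$codon_clean)
  expect_identical(extract_cds(g, chroms), "ATGAAACC")
})

test_that("expression/GO/QTL TSV round trips and input validation", {
  set.seed(5)
  fpkm <- matrix(c(0, 1.5, 2, 0, 3.25, 0, 0, 4), 2, 4,
                 dimnames = list(c("gA", "gB"),
                                 c("leaf__rep1", "leaf__rep2",
                                   "root__rep1", "root__rep2")))
  mat <- ExpressionMatrix(fpkm)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(mat, f)
  expect_equal(read_expression(f)$fpkm, fpkm)

  writeLines(c("gene_id\tleaf__rep1", "gA\t-1"), f)
  expect_error(read_expression(f), "negative")

  writeLines(c("chrom\tstart\tend\ttrait", "chr1\t101\t200\tfruit_weight"), f)
  q <- read_qtl(f)
  expect_equal(q$start, 100L)   # 1-based inclusive -> 0-based half-open
  expect_equal(q$end, 200L)
  expect_equal(q$trait, "fruit_weight")

  go <- list(gA = c("GO:1", "GO:2"), gB = "GO:3")
  write_go_map(go, f)
  expect_equal(read_go_map(f), go)
})

test_that("simulated genomes round-trip through FASTA + GFF3 on disk", {
  sim <- fix_sim_small()
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  g2 <- read_genome(file.path(d, "focal.fa"), file.path(d, "focal.gff3"),
                    "focal", "focal")
  expect_identical(g2$chromosomes, sim$focal$chromosomes)
  expect_setequal(names(g2$genes), names(sim$focal$genes))
  for (id in names(sim$focal$genes)) {
    expect_identical(extract_cds(g2$genes[[id]], g2$chromosomes),
                     extract_cds(sim$focal$genes[[id]], sim$focal$chromosomes))
  }
})
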