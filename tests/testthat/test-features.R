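test_that("GC by codon position matches hand counts", {
  gc <- gc_by_codon_position("ATGGCC")
  expect_equal(unname(gc["GC1"]), 0.5)   # A,G
  expect_equal(unname(gc["GC2"]), 0.5)   # T,C
  expect_equal(unname(gc["GC3"]), 1.0)   # G,C
  expect_equal(unname(gc["GC"]), 2 / 3)
  expect_equal(unname(gc_by_codon_position("AAATTT")), rep(0, 4))
  expect_error(gc_by_codon_position("ATGGC"), "divisible")
})

test_that("GC equals the mean of the three positional GCs on random CDS", {
  set.seed(40)
  for (i in 1:1000) {
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * sample(2:60, 1), TRUE),
                 collapse = "")
    gc <- gc_by_codon_position(cds)
    expect_equal(unname(gc["GC"]),
                 unname((gc["GC1"] + gc["GC2"] + gc["GC3"]) / 3),
                 tolerance = 1e-12)
  }
})

test_that("optimal codon inference follows frequency with alphabetical ties", {
  ## reference set coding Ala only as GCC
  cds <- setNames(c(rep("ATGGCCGCCTAA", 19), "ATGGCAGCGTAA"),
                  paste0("g", 1:20))
  lv <- setNames(c(rep(10, 19), 1), names(cds))  # top 10% = 2 genes, all GCC
  opt <- suppressWarnings(infer_optimal_codons(cds, lv, top_fraction = 0.1))
  expect_equal(unname(opt["A"]), "GCC")

  ## equal GCA/GCC counts in the reference -> GCA by alphabetical tie-break
  cds2 <- setNames(rep("ATGGCAGCCTAA", 20), paste0("g", 1:20))
  lv2 <- setNames(rep(1, 20), names(cds2))
  opt2 <- suppressWarnings(infer_optimal_codons(cds2, lv2))
  expect_equal(unname(opt2["A"]), "GCA")
  expect_error(infer_optimal_codons(cds[1:5], lv[1:5]), "at least 20")
})

test_that("the planted codon bias is recovered from the simulation", {
  sim <- fix_sim()
  truth <- fix_truth()
  ids <- truth$gene_id[truth$planted_class == "conserved"]
  cds <- vapply(ids, function(id)
    extract_cds(sim$focal$genes[[id]], sim$focal$chromosomes), "")
  lv <- vapply(ids, expression_level, 0, mat = sim$expression)
  opt <- suppressWarnings(infer_optimal_codons(cds, lv))
  planted <- sim$optimal_codons
  expect_gte(mean(opt[names(planted)] == planted), 0.9)
  expect_equal(unname(opt["A"]), unname(planted["A"]))
})

test_that("Fop counts optimal codons over degenerate families only", {
  opt <- c(A = "GCC")
  expect_equal(fop("ATGGCC", opt), 1.0)  # ATG (Met) excluded, GCC optimal
  expect_equal(fop("ATGGCA", opt), 0.0)
  expect_true(is.na(fop("ATGTGG", opt))) # Met + Trp only: no eligible codon
  set.seed(41)
  sim <- fix_sim()
  planted <- sim$optimal_codons
  for (i in 1:200) {
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * sample(10:80, 1), TRUE),
                 collapse = "")
    f <- fop(cds, planted)
    if (!is.na(f)) { expect_gte(f, 0); expect_lte(f, 1) }
  }
})

test_that("Fop is invariant to codon order when counts are preserved", {
  set.seed(42)
  planted <- fix_sim()$optimal_codons
  cds <- random_orf(60)
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  shuffled <- paste(sample(cods), collapse = "")
  expect_equal(fop(cds, planted), fop(shuffled, planted))
})

test_that("disorder proxy hits the extremes and stays in [0, 1]", {
  expect_equal(isd_proxy(strrep("E", 100)), 1.0)   # charged, hydrophilic
  expect_equal(isd_proxy(strrep("I", 100)), 0.0)   # hydrophobic, uncharged
  set.seed(43)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:50) {
    v <- isd_proxy(paste(sample(aa, sample(5:200, 1), TRUE), collapse = ""))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  set.seed(44)
  for (i in 1:30) {
    x <- sample(1:20, sample(3:12, 1), TRUE)   # ties included
    y <- sample(1:20, sample(3:12, 1), TRUE)
    wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(unname(wt$statistic), mwu_oracle(x, y), tolerance = 1e-10)
    ## U + U' = n_a * n_b
    wt2 <- wilcox.test(y, x, exact = FALSE, correct = FALSE)
    expect_equal(unname(wt$statistic + wt2$statistic), length(x) * length(y))
  }
})

test_that("comparing a class with itself is null", {
  set.seed(45)
  feats <- data.frame(gene_id = paste0("g", 1:20), GC = runif(20),
                      ISD = runif(20), Fop = runif(20))
  cmp <- compare_classes(feats, feats$gene_id, feats$gene_id,
                         feature_cols = c("GC", "ISD", "Fop"))
  expect_true(all(abs(cmp$tests$p - 1) < 1e-8))
  expect_equal(cmp$tests$U, rep(20 * 20 / 2, 3))
})

test_that("feature table flags and excludes non-codon-clean genes", {
  set.seed(46)
  chrom <- c(chr1 = random_dna_str(4000))
  good <- random_orf(40)
  substr(chrom["chr1"], 501, 500 + nchar(good)) <- good
  g1 <- GeneModel("clean", "chr1", "+",
                  rbind(c(500L, 500L + nchar(good))),
                  rbind(c(500L, 500L + nchar(good))))
  g2 <- GeneModel("ragged", "chr1", "+", rbind(c(2000L, 2080L)),
                  rbind(c(2000L, 2080L)))   # 80 nt: not divisible by 3
  gr <- GenomeRecord("f", "focal", chrom, list(g1, g2))
  ft <- build_feature_table(gr, optimal = c(A = "GCC"))
  expect_true(ft$codon_clean[ft$gene_id == "clean"])
  expect_false(ft$codon_clean[ft$gene_id == "ragged"])
  expect_true(is.na(ft$GC[ft$gene_id == "ragged"]))
  expect_equal(ft$intron_length_total, c(0L, 0L))
})
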