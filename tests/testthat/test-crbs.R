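test_that("promoter extraction is strand-aware and truncates at edges", {
  set.seed(50)
  chrom <- c(chr1 = random_dna_str(10000))
  gp <- GeneModel("gp", "chr1", "+", rbind(c(5000L, 5300L)),
                  rbind(c(5000L, 5300L)))
  expect_identical(extract_promoter(gp, chrom),
                   unname(substr(chrom, 3001, 5000)))

  gm <- GeneModel("gm", "chr1", "-", rbind(c(4700L, 5000L)),
                  rbind(c(4700L, 5000L)))
  expect_identical(extract_promoter(gm, chrom),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(unname(substr(chrom, 5001, 7000))))))

  near <- GeneModel("gn", "chr1", "+", rbind(c(800L, 1100L)),
                    rbind(c(800L, 1100L)))
  expect_warning(p <- extract_promoter(near, chrom), "truncated")
  expect_equal(nchar(p), 800L)
})

test_that("scanning counts planted sites and palindromes on both strands", {
  set.seed(51)
  prom <- random_dna_str(500)
  substr(prom, 201, 206) <- "TTGACC"        # W-box consensus TTGACY
  expect_gte(scan_motif(prom, "TTGACY"), 1L)

  ## palindrome counted once per strand
  expect_equal(scan_motif("AAACACGTGAAA", "CACGTG"), 2L)
})

test_that("scan counts equal naive enumeration on random promoter-motif pairs", {
  set.seed(52)
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  for (i in 1:500) {
    prom <- random_dna_str(sample(50:300, 1))
    w <- sample(4:10, 1)
    iupac <- paste(sample(c(rep(c("A", "C", "G", "T"), 4), codes), w, TRUE),
                   collapse = "")
    expect_equal(scan_motif(prom, iupac), motif_count_oracle(prom, iupac),
                 tolerance = 1e-10)
  }
})

test_that("scan totals are strand-symmetric", {
  set.seed(53)
  for (i in 1:20) {
    prom <- random_dna_str(300)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
    m <- default_motifs()[sample(nrow(default_motifs()), 1), ]
    expect_equal(scan_motif(prom, m$iupac), scan_motif(rc, m$iupac))
  }
})

test_that("the CI-exceedance rule follows the stated expected-count model", {
  ## exactly uniform composition: E = 2 * (L - w + 1) * 0.25^w
  prom <- strrep("ACGT", 500)
  motif <- list(motif_id = "m", iupac = "ACGTAC", tf_family = "x")
  r <- crbs_significance(4L, prom, motif)
  expect_equal(r$expected, 2 * 1995 * 0.25^6, tolerance = 1e-12)
  expect_equal(r$ci_upper, r$expected + 1.96 * sqrt(r$expected), tolerance = 1e-3)
  expect_true(r$significant)                  # 4 > ~2.91, E < 5

  expect_false(crbs_significance(0L, prom, motif)$significant)

  ## high-expectation motifs are never significant (the expected-count cap)
  degenerate <- list(motif_id = "n", iupac = "NNNN", tf_family = "x")
  rn <- crbs_significance(5000L, prom, degenerate)
  expect_gt(rn$expected, 5)
  expect_false(rn$significant)
})

test_that("class comparison is null for identical class compositions", {
  set.seed(54)
  genes <- paste0("g", 1:40)
  proms <- setNames(vapply(genes, function(g) random_dna_str(2000), ""), genes)
  scan <- scan_promoters(proms, default_motifs()[1:10, ])
  cmp <- suppressMessages(crbs_class_comparison(scan, genes, genes))
  expect_equal(cmp$summary$possess_fraction[1], cmp$summary$possess_fraction[2])
  if (!is.null(cmp$chisq_categories)) {
    expect_equal(cmp$chisq_categories$statistic, 0, tolerance = 1e-10)
    expect_equal(cmp$chisq_categories$p, 1, tolerance = 1e-10)
  }
  expect_equal(cmp$chisq_possession$statistic, 0, tolerance = 1e-10)
})

test_that("chi-square statistics match the textbook formula on random tables", {
  set.seed(55)
  for (i in 1:100) {
    nr <- 2; nc <- sample(2:6, 1)
    tab <- matrix(sample(5:40, nr * nc, TRUE), nr, nc)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(unname(ct$statistic), chisq_oracle(tab), tolerance = 1e-10)
  }
  expect_equal(unname(suppressWarnings(
    chisq.test(matrix(10, 2, 2), correct = FALSE))$statistic), 0)
})
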