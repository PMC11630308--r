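test_that("self-alignment of identical peptides gives identity 1 and the self-score", {
  set.seed(10)
  sm <- oracle_blosum62()
  pep <- paste(sample(rownames(sm)[1:20], 100, TRUE), collapse = "")
  hit <- align_protein(pep, pep)
  expect_equal(hit$identity, 1.0)
  self_score <- sum(diag(sm[strsplit(pep, "")[[1]], strsplit(pep, "")[[1]]]))
  expect_equal(hit$score, self_score)
})

test_that("local alignment score matches the independent DP oracle", {
  ## the classic toy pair, plus randomized pairs up to 60 aa
  expect_equal(align_protein("HEAGAWGHEE", "PAWHEAE")$score,
               sw_oracle("HEAGAWGHEE", "PAWHEAE"))
  set.seed(11)
  aa <- rownames(oracle_blosum62())[1:20]
  for (i in 1:200) {
    a <- paste(sample(aa, sample(5:60, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:60, 1), TRUE), collapse = "")
    expect_equal(align_protein(a, b)$score, sw_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("Karlin-Altschul E-value arithmetic", {
  expect_equal(karlin_evalue(100, 200, 200),
               0.041 * 200 * 200 * exp(-26.7), tolerance = 1e-12)
  expect_equal(karlin_evalue(100, 200, 200), 4.1e-9, tolerance = 0.05)
  expect_equal(bit_score(100), (0.267 * 100 - log(0.041)) / log(2))
  expect_error(align_protein("", "PAW"), "empty")
})

test_that("candidate and conserved sets recover the planted classes", {
  sim <- fix_sim()
  res <- fix_res()
  truth <- fix_truth()
  planted_cand <- truth$gene_id[truth$planted_class %in%
                                  c("denovo_type1", "denovo_type2", "orf_trap")]
  expect_setequal(res$candidates, planted_cand)
  expect_setequal(res$conserved,
                  truth$gene_id[truth$planted_class == "conserved"])
  ## decoys with an ortholog in one relative only: neither candidate nor conserved
  decoys <- truth$gene_id[truth$planted_class == "decoy_partial_ortholog"]
  expect_length(intersect(decoys, res$candidates), 0)
  expect_length(intersect(decoys, res$conserved), 0)
})

test_that("candidate and conserved sets are disjoint; threshold is monotone", {
  set.seed(12)
  aa <- rownames(oracle_blosum62())[1:20]
  mk <- function(n) paste(sample(aa, n, TRUE), collapse = "")
  focal <- c(f1 = mk(80), f2 = mk(80), f3 = mk(80))
  rel <- list(gA = c(a1 = focal[["f1"]], a2 = mk(80)),
              gB = c(b1 = paste0(substr(focal[["f1"]], 1, 70), mk(10)), b2 = mk(80)))
  searches <- denovoscan:::search_all(Biostrings::AAStringSet(focal),
                                      lapply(rel, Biostrings::AAStringSet))
  prev <- NULL
  for (thr in c(1e-20, 1e-10, 1e-5, 1e-2, 1)) {
    cand <- candidate_filter(focal, rel, thr, searches)
    cons <- conserved_set(focal, rel, thr, searches)
    expect_length(intersect(cand, cons), 0)
    if (!is.null(prev)) expect_true(all(cand %in% prev))  # relaxing shrinks
    prev <- cand
  }
  ## infinite threshold: every finite-E alignment counts as a hit
  expect_length(candidate_filter(focal, rel, Inf, searches), 0)
})

test_that("duplicated focal genes are excluded by the one-to-one rule", {
  set.seed(13)
  aa <- rownames(oracle_blosum62())[1:20]
  shared <- paste(sample(aa, 90, TRUE), collapse = "")
  other <- paste(sample(aa, 90, TRUE), collapse = "")
  focal <- c(dup1 = shared, dup2 = shared, uniq = other)
  rel <- list(gA = c(t1 = shared, t2 = other))
  cons <- conserved_set(focal, rel)
  expect_false("dup1" %in% cons)
  expect_false("dup2" %in% cons)
  expect_true("uniq" %in% cons)
})

test_that("tabular hit adapter reproduces the candidate filter", {
  hits <- list(
    gA = data.frame(query = c("f1", "f2"), target = c("a1", "a2"),
                    identity = 0.9, length = 80,
                    evalue = c(1e-20, 1e-3), bitscore = 100),
    gB = data.frame(query = "f2", target = "b1", identity = 0.9, length = 80,
                    evalue = 1e-8, bitscore = 80))
  cand <- candidate_filter_from_hits(c("f1", "f2", "f3"), hits)
  expect_setequal(cand, "f3")   # f1 hit in gA, f2 hit in gB
  f <- withr::local_tempfile()
  write.table(hits$gA, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_hit_table(f)$evalue, c(1e-20, 1e-3))
})
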