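test_that("topological overlap is bounded and unit on the diagonal", {
  set.seed(70)
  n <- 30
  x <- matrix(rnorm(n * 50), 50, n)
  sim <- (1 + cor(x)) / 2
  tom <- tom_similarity(sim^6)
  expect_true(all(tom >= 0 - 1e-12) && all(tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, n))
})

test_that("TOM matches hand arithmetic on a 3-gene adjacency at beta = 1", {
  a <- matrix(c(0, 0.8, 0.2,
                0.8, 0, 0.4,
                0.2, 0.4, 0), 3, 3, byrow = TRUE)
  tom <- tom_similarity(a)
  k <- rowSums(a)
  ## TOM_12 = (a_13 a_32 + a_12) / (min(k1,k2) + 1 - a_12)
  expect_equal(tom[1, 2], (0.2 * 0.4 + 0.8) / (min(k[1], k[2]) + 1 - 0.8),
               tolerance = 1e-12)
  expect_equal(tom[1, 3], (0.8 * 0.4 + 0.2) / (min(k[1], k[3]) + 1 - 0.2),
               tolerance = 1e-12)
  expect_equal(tom[2, 3], (0.8 * 0.2 + 0.4) / (min(k[2], k[3]) + 1 - 0.4),
               tolerance = 1e-12)
})

test_that("planted co-expression blocks are recovered as two modules", {
  cx <- fix_coexpr()
  mods <- suppressWarnings(suppressMessages(build_modules(cx$mat)))
  expect_length(mods, 2)
  gm <- attr(mods, "gene_module")
  for (b in c("block1", "block2")) {
    members <- names(cx$block)[cx$block == b]
    hit_mod <- names(sort(table(gm[members]), decreasing = TRUE))[1]
    expect_false(hit_mod == "unassigned")
    expect_gte(mean(gm[members] == hit_mod), 0.95)
  }
  ## the two blocks land in different modules
  m1 <- names(sort(table(gm[names(cx$block)[cx$block == "block1"]]),
                   decreasing = TRUE))[1]
  m2 <- names(sort(table(gm[names(cx$block)[cx$block == "block2"]]),
                   decreasing = TRUE))[1]
  expect_false(m1 == m2)
})

test_that("module assignment is invariant to gene input order", {
  cx <- fix_coexpr()
  mods1 <- suppressWarnings(suppressMessages(build_modules(cx$mat, beta = 6)))
  set.seed(71)
  perm <- sample(nrow(cx$mat$fpkm))
  mat2 <- ExpressionMatrix(cx$mat$fpkm[perm, ])
  mods2 <- suppressWarnings(suppressMessages(build_modules(mat2, beta = 6)))
  gm1 <- attr(mods1, "gene_module")
  gm2 <- attr(mods2, "gene_module")
  ## same partition up to label names
  for (m in unique(gm1)) {
    members <- names(gm1)[gm1 == m]
    expect_equal(length(unique(gm2[members])), 1L)
  }
})

test_that("duplicated expression profiles always co-module", {
  cx <- fix_coexpr()
  fpkm <- cx$mat$fpkm
  fpkm <- rbind(fpkm, dupA = fpkm["cx0001", ], dupB = fpkm["cx0001", ])
  mods <- suppressWarnings(suppressMessages(
    build_modules(ExpressionMatrix(fpkm), beta = 6)))
  gm <- attr(mods, "gene_module")
  expect_equal(unname(gm["dupA"]), unname(gm["dupB"]))
  expect_equal(unname(gm["dupA"]), unname(gm["cx0001"]))
})

test_that("module significance reflects trait correlation", {
  cx <- fix_coexpr()
  mods <- suppressWarnings(suppressMessages(build_modules(cx$mat)))
  ## trait equal to one member's log-profile: that gene contributes |cor| = 1
  g <- mods[[1]]$members[1]
  trait <- log2(cx$mat$fpkm[g, ] + 1)
  one_gene_module <- list(label = "x", members = g)
  expect_equal(module_significance(one_gene_module, cx$mat, trait), 1,
               tolerance = 1e-12)
  expect_error(module_significance(one_gene_module, cx$mat,
                                   rep(1, ncol(cx$mat$fpkm))), "zero-variance")

  ## random trait on a large module: MS stays near zero
  set.seed(72)
  trait_rand <- rnorm(ncol(cx$mat$fpkm))
  ms <- module_significance(mods[[1]], cx$mat, trait_rand)
  expect_lt(ms, 3 / sqrt(ncol(cx$mat$fpkm)))

  ## a trait tracking block1's latent factor selects block1's module
  members1 <- names(cx$block)[cx$block == "block1"]
  trait_blk <- colMeans(log2(cx$mat$fpkm[members1, ] + 1))
  key <- key_modules(mods, cx$mat, traits = list(blk = trait_blk))
  gm <- attr(mods, "gene_module")
  blk_mod <- names(sort(table(gm[members1]), decreasing = TRUE))[1]
  expect_equal(key$module[1], blk_mod)
})

test_that("de novo-rich modules are flagged strictly above the threshold", {
  mods <- list(m1 = list(label = "m1", members = paste0("a", 1:40)),
               m2 = list(label = "m2", members = paste0("b", 1:40)))
  dn <- c(paste0("a", 1:11), paste0("b", 1:10))   # 11 vs 10 planted members
  mem <- denovo_membership(mods, dn, rich_threshold = 10L)
  expect_true(mem$rich[mem$module == "m1"])
  expect_false(mem$rich[mem$module == "m2"])
  expect_equal(sum(mem$denovo_count), 21L)        # counts sum to assigned de novo
})
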