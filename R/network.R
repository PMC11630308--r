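## Weighted co-expression module detection, in the style of weighted gene
## co-expression network analysis but deliberately simplified: signed
## similarity s = (1 + cor)/2 raised to a soft-threshold power beta chosen by
## scale-free fit, topological overlap, average-linkage clustering on
## 1 - TOM, and a static dendrogram cut (the reference tool's dynamic tree
## cut is out of scope).

#' Choose the soft-threshold power by scale-free fit
#'
#' Smallest integer beta in [1, max_beta] whose connectivity distribution
#' gives a scale-free model fit R^2 >= \code{target_r2} (log-log regression
#' of binned frequency on mean connectivity); falls back to \code{fallback}
#' with a message when none qualifies.
#'
#' @param sim similarity matrix in [0,1]
#' @param target_r2 required fit (default 0.8)
#' @param max_beta largest power tried
#' @param fallback power used when no beta fits
#' @return list(beta, r2): chosen power and the fit at each power tried
#' @export
pick_soft_threshold <- function(sim, target_r2 = 0.8, max_beta = 20L, fallback = 6L) {
  r2s <- numeric(max_beta)
  for (beta in seq_len(max_beta)) {
    a <- sim^beta
    diag(a) <- 0
    k <- rowSums(a)
    r2s[beta] <- scale_free_r2(k)
    if (!is.na(r2s[beta]) && r2s[beta] >= target_r2)
      return(list(beta = beta, r2 = r2s[seq_len(beta)]))
  }
  message("no soft-threshold power reached R^2 >= ", target_r2,
          "; falling back to beta = ", fallback)
  list(beta = fallback, r2 = r2s)
}

scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with unit
#' diagonal; entries lie in [0,1] for an adjacency in [0,1].
#'
#' @param adj adjacency matrix in [0,1] (diagonal ignored)
#' @return TOM matrix
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  num <- a %*% a + a
  k <- rowSums(a)
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Works on log2(FPKM + 1); constant-expression genes are dropped with a
#' warning. Pearson (or Spearman) correlation, signed or unsigned similarity,
#' soft thresholding, TOM, average-linkage clustering of 1 - TOM and a static
#' cut at \code{cut_height}; clusters of at least \code{min_module_size}
#' genes become named modules (size-ranked color labels), the rest is pooled
#' as "unassigned". Each module's eigengene is the first principal component
#' of its members' standardized expression, oriented to correlate positively
#' with mean member expression.
#'
#' @param mat \code{\link{ExpressionMatrix}}
#' @param beta soft-threshold power, or "auto"
#' @param min_module_size smallest named module
#' @param cut_height static cut height on the 1 - TOM dendrogram
#' @param network "signed" or "unsigned"
#' @param cor_method "pearson" or "spearman"
#' @return list of modules: label, members, eigengene; plus attributes
#'   beta and gene_module (named assignment vector)
#' @export
build_modules <- function(mat, beta = "auto", min_module_size = 30L,
                          cut_height = 0.9, network = c("signed", "unsigned"),
                          cor_method = c("pearson", "spearman")) {
  network <- match.arg(network)
  cor_method <- match.arg(cor_method)
  x <- t(log2(mat$fpkm + 1))           # samples x genes
  v <- apply(x, 2L, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant-expression gene(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 3L * min_module_size)
    stop("need at least ", 3L * min_module_size, " variable genes")
  cc <- cor(x, method = cor_method)
  sim <- if (network == "signed") (1 + cc) / 2 else abs(cc)
  if (identical(beta, "auto")) beta <- pick_soft_threshold(sim)$beta
  adj <- sim^beta
  tom <- tom_similarity(adj)
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- module_colors(length(big))
  assignment <- setNames(rep("unassigned", ncol(x)), colnames(x))
  modules <- list()
  for (i in seq_along(big)) {
    members <- colnames(x)[cl == as.integer(big[i])]
    assignment[members] <- labels[i]
    modules[[labels[i]]] <- list(label = labels[i], members = members,
                                 eigengene = module_eigengene(x[, members, drop = FALSE]))
  }
  structure(modules, beta = beta, gene_module = assignment,
            class = "coexpr_modules")
}

module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("module", seq_len(n - length(base))))
}

## first PC of standardized member expression, sign-aligned to the mean profile
module_eigengene <- function(x) {
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)$x[, 1L]
  if (cor(pc, rowMeans(xs)) < 0) pc <- -pc
  pc / sqrt(sum(pc^2))
}

#' @export
print.coexpr_modules <- function(x, ...) {
  sizes <- vapply(x, function(m) length(m$members), 0L)
  cat(sprintf("%d co-expression module(s) (beta = %s); sizes: %s; unassigned: %d\n",
              length(x), attr(x, "beta"), paste(sizes, collapse = ", "),
              sum(attr(x, "gene_module") == "unassigned")))
  invisible(x)
}

#' Module significance for a trait
#'
#' MS = mean over module members of |cor(gene expression, trait)| on
#' log2(FPKM + 1).
#'
#' @param module one module from \code{\link{build_modules}}
#' @param mat \code{\link{ExpressionMatrix}}
#' @param trait per-sample numeric vector aligned to the matrix columns
#' @return numeric MS score
#' @export
module_significance <- function(module, mat, trait) {
  if (var(trait) == 0) stop("zero-variance trait")
  x <- t(log2(mat$fpkm[module$members, , drop = FALSE] + 1))
  mean(abs(suppressWarnings(cor(x, trait))), na.rm = TRUE)
}

#' Key module per trait
#'
#' Computes MS for every module against each trait vector (default: one-hot
#' tissue indicators) and reports the argmax module per trait.
#'
#' @param modules from \code{\link{build_modules}}
#' @param mat \code{\link{ExpressionMatrix}}
#' @param traits named list of per-sample vectors; default one-hot tissues
#' @return data.frame(trait, module, ms) of key modules, with the full MS
#'   matrix as attribute \code{"ms"}
#' @export
key_modules <- function(modules, mat, traits = NULL) {
  if (is.null(traits)) {
    traits <- lapply(tissues_of(mat), function(tt) as.numeric(mat$meta$tissue == tt))
    names(traits) <- tissues_of(mat)
  }
  ms <- sapply(traits, function(tr)
    vapply(modules, module_significance, 0, mat = mat, trait = tr))
  ms <- matrix(ms, nrow = length(modules),
               dimnames = list(names(modules), names(traits)))
  key <- data.frame(trait = colnames(ms),
                    module = rownames(ms)[apply(ms, 2L, which.max)],
                    ms = apply(ms, 2L, max), row.names = NULL)
  attr(key, "ms") <- ms
  key
}

#' De novo gene membership per module
#'
#' Counts de novo genes in each module and flags modules with more than
#' \code{rich_threshold} of them as de novo-rich.
#'
#' @param modules from \code{\link{build_modules}}
#' @param denovo_ids de novo gene ids
#' @param rich_threshold count strictly above which a module is rich
#' @return data.frame(module, size, denovo_count, rich)
#' @export
denovo_membership <- function(modules, denovo_ids, rich_threshold = 10L) {
  if (length(modules) == 0L)
    return(data.frame(module = character(0), size = integer(0),
                      denovo_count = integer(0), rich = logical(0)))
  rows <- lapply(modules, function(m) {
    cnt <- length(intersect(m$members, denovo_ids))
    data.frame(module = m$label, size = length(m$members),
               denovo_count = cnt, rich = cnt > rich_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
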