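## End-to-end orchestration: homology filter -> de novo calling -> expression
## confirmation -> features -> promoter CRBS -> flank-gene GO enrichment ->
## co-expression modules -> QTL overlap, with one parameter list, seeded
## determinism and a summary report.

#' Default pipeline parameters
#'
#' Every threshold used by the stages, with the study's stated values where
#' they exist (E <= 1e-5 homology cutoff, 2-kb promoters, 10-kb flanks,
#' p < 0.05, de novo-rich modules at > 10 members) and documented choices
#' elsewhere.
#'
#' @return named list
#' @export
default_run_params <- function() {
  list(e_threshold = 1e-5,
       min_identity = 0.7, min_coverage = 0.5, chain_gap = 5000L,
       tau_nc = 0.05,
       trap_min_span = 0.8, trap_min_pid = 0.6, trap_window = 300L,
       theta = 0.5, te_class = "type3",
       promoter_length = 2000L, alpha = 0.05, expected_cap = 5.0,
       beta = "auto", cut_height = 0.9, min_module_size = 30L,
       rich_threshold = 10L,
       flank = 10000L, flank_mode = "ancestral",
       top_fraction = 0.1, seed = 1L)
}

check_params <- function(params) {
  defaults <- default_run_params()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  merged <- defaults
  merged[names(params)] <- params
  with(merged, stopifnot(
    e_threshold > 0, min_identity >= 0, min_identity <= 1,
    min_coverage >= 0, min_coverage <= 1, tau_nc >= 0, tau_nc <= 1,
    trap_min_span >= 0, trap_min_span <= 1, trap_min_pid >= 0, trap_min_pid <= 1,
    theta >= 0, theta <= 1, promoter_length > 0, alpha > 0, alpha < 1,
    expected_cap > 0, cut_height > 0, cut_height <= 1, min_module_size >= 2,
    rich_threshold >= 0, flank >= 0, flank_mode %in% c("ancestral", "focal"),
    top_fraction > 0, top_fraction <= 1))
  merged
}

#' Run the full de novo gene pipeline
#'
#' Executes every stage on in-memory inputs (use the \code{read_*} functions
#' or \code{\link{simulate_genomes}} to build them). Identical inputs and
#' parameters give identical results.
#'
#' @param focal focal \code{\link{GenomeRecord}}
#' @param relatives list of relative \code{\link{GenomeRecord}} (>= 1
#'   ingroup and >= 1 outgroup)
#' @param expression \code{\link{ExpressionMatrix}} or NULL to skip
#'   expression-dependent stages
#' @param go_map named list gene -> GO terms, or NULL
#' @param motifs motif library data.frame, default \code{\link{default_motifs}}
#' @param qtl QTL data.frame (0-based half-open) or NULL
#' @param params overrides of \code{\link{default_run_params}}
#' @param out_dir when set, all stage TSVs plus report.json are written here
#' @param run_network run module detection (the slowest optional stage)
#' @return list with candidates, conserved, calls, features, comparisons,
#'   crbs, enrichment, modules, qtl_overlap and report
#' @export
run_pipeline <- function(focal, relatives, expression = NULL, go_map = NULL,
                         motifs = default_motifs(), qtl = NULL,
                         params = list(), out_dir = NULL, run_network = TRUE) {
  p <- check_params(params)
  roles <- vapply(relatives, `[[`, "", "role")
  if (!any(roles == "ingroup") || !any(roles == "outgroup"))
    stop("need at least one ingroup and one outgroup relative genome")
  set.seed(p$seed)
  t0 <- Sys.time()
  log_stage <- function(name) message(sprintf("[%s] %s", format(Sys.time() - t0),
                                              name))

  ## 1-2. homology: candidates and conserved set
  log_stage("homology search")
  focal_prot <- genome_proteome(focal)
  rel_prot <- lapply(relatives, genome_proteome)
  names(rel_prot) <- vapply(relatives, `[[`, "", "genome_id")
  searches <- search_all(focal_prot, rel_prot)
  candidates <- candidate_filter(focal_prot, rel_prot, p$e_threshold, searches)
  conserved <- conserved_set(focal_prot, rel_prot, p$e_threshold, searches)

  ## 3. de novo calling
  log_stage(sprintf("de novo calling (%d candidates)", length(candidates)))
  cand_cds <- vapply(candidates, function(id)
    extract_cds(focal$genes[[id]], focal$chromosomes), "")
  dn_params <- denovo_params()
  for (nm in names(dn_params))
    if (nm %in% names(p)) dn_params[[nm]] <- p[[nm]]
  calls <- call_denovo(cand_cds, relatives, dn_params)

  ## 4. expression confirmation
  if (!is.null(expression)) {
    log_stage("expression confirmation")
    calls <- confirm_expressed(calls, expression)
  }
  status <- vapply(calls, `[[`, "", "status")
  confirmed <- names(calls)[status == "confirmed_expressed"]
  putative <- names(calls)[status %in% c("putative", "confirmed_expressed")]
  denovo_final <- if (is.null(expression)) putative else confirmed

  ## 5. features and class comparison
  log_stage("gene features")
  features <- build_feature_table(focal, expression, top_fraction = p$top_fraction)
  comparison <- if (length(denovo_final) >= 3L && length(conserved) >= 3L)
    compare_classes(features, denovo_final, conserved) else NULL

  ## 6. promoter CRBS
  log_stage("promoter CRBS scan")
  scan_ids <- c(denovo_final, conserved)
  promoters <- vapply(scan_ids, function(id)
    suppressWarnings(extract_promoter(focal$genes[[id]], focal$chromosomes,
                                      p$promoter_length)), "")
  crbs <- scan_promoters(promoters, motifs, alpha = p$alpha,
                         expected_cap = p$expected_cap)
  crbs_cmp <- if (length(denovo_final) && length(conserved))
    crbs_class_comparison(crbs, denovo_final, conserved) else NULL

  ## 7. flank-gene GO enrichment
  enrichment <- NULL
  if (!is.null(go_map) && length(denovo_final)) {
    log_stage("flank-gene enrichment")
    flanks <- denovo_flank_genes(calls[denovo_final], focal, relatives,
                                 mode = p$flank_mode, flank = p$flank)
    background <- if (p$flank_mode == "focal") names(focal$genes)
      else unlist(lapply(relatives, function(g) names(g$genes)), use.names = FALSE)
    enrichment <- fisher_enrichment(flanks, background, go_map, alpha = p$alpha)
  }

  ## 8. co-expression modules
  modules <- membership <- NULL
  if (run_network && !is.null(expression)) {
    log_stage("co-expression modules")
    modules <- tryCatch(
      suppressWarnings(build_modules(expression, beta = p$beta,
                                     min_module_size = p$min_module_size,
                                     cut_height = p$cut_height)),
      error = function(e) {
        message("module detection skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(modules))
      membership <- denovo_membership(modules, denovo_final, p$rich_threshold)
  }

  ## 9. QTL overlap
  qtl_hits <- NULL
  if (!is.null(qtl) && length(denovo_final)) {
    log_stage("QTL overlap")
    qtl_hits <- qtl_overlap(denovo_final, focal, qtl)
  }

  types <- vapply(calls, `[[`, "", "type")
  report <- list(
    n_focal_genes = length(focal$genes),
    n_candidates = length(candidates),
    n_conserved = length(conserved),
    n_putative = sum(status %in% c("putative", "confirmed_expressed")),
    n_confirmed = length(confirmed),
    n_excluded_orf_trap = sum(status == "excluded_orf_trap"),
    n_type1 = sum(types == "I" & names(calls) %in% denovo_final),
    n_type2 = sum(types == "II" & names(calls) %in% denovo_final),
    n_type3 = sum(types == "III" & names(calls) %in% denovo_final),
    crbs_possession_denovo = if (!is.null(crbs_cmp))
      crbs_cmp$summary$possess_fraction[1L] else NA,
    crbs_possession_conserved = if (!is.null(crbs_cmp))
      crbs_cmp$summary$possess_fraction[2L] else NA,
    n_modules = if (!is.null(modules)) length(modules) else NA,
    n_rich_modules = if (!is.null(membership)) sum(membership$rich) else NA,
    n_qtl_hit_genes = if (!is.null(qtl_hits)) sum(qtl_hits$n_hits > 0) else NA)

  res <- list(candidates = candidates, conserved = conserved, calls = calls,
              features = features, comparison = comparison, crbs = crbs,
              crbs_comparison = crbs_cmp, enrichment = enrichment,
              modules = modules, module_membership = membership,
              qtl_overlap = qtl_hits, denovo_final = denovo_final,
              report = report, params = p)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_calls(res$calls, file.path(out_dir, "calls.tsv"),
              file.path(out_dir, "evidence.tsv"))
  write.table(res$features, file.path(out_dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$comparison))
    write.table(res$comparison$tests, file.path(out_dir, "tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$crbs, file.path(out_dir, "crbs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment))
    write.table(res$enrichment, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$modules)) {
    gm <- attr(res$modules, "gene_module")
    write.table(data.frame(gene_id = names(gm), module = gm),
                file.path(out_dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$module_membership, file.path(out_dir, "module_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$qtl_overlap))
    write.table(res$qtl_overlap, file.path(out_dir, "qtl_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
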