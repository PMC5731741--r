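#' Pipeline configuration
#'
#' Collects every tunable of the full module-detection pipeline. Quantile
#' parameters are in "top percent" units exactly as conventionally printed:
#' \code{S = 0.005} means the top 0.005\% of pairs, \code{M_percent = 1} the
#' top 1\%. The run manifest echoes both the percent and the realized
#' threshold values.
#'
#' @param S Seed-pair quantile (percent of pairs).
#' @param D_min,D_max_percent Seed degree bounds (see
#'   \code{\link{extract_seed_pairs}}).
#' @param k Genes admitted per expansion iteration.
#' @param M_percent Module-threshold quantile (percent of pairs).
#' @param maxTreeHeight,deepSplit,minModuleSize Tree-cut parameters.
#' @param linkage Agglomeration method for both clustering steps.
#' @param extend_overlap Apply the overlap extension to the final modules of
#'   each large module.
#' @param feature_kind \code{"gene"} or \code{"isoform"}; selects the default
#'   module size bounds (10-300 and 10-500 respectively).
#' @param min_module_genes,max_module_genes Explicit size bounds (override the
#'   kind-based defaults).
#' @param permutation_N Random modules per permutation test; 0 skips the test.
#' @param seed Integer seed for every stochastic step.
#' @param zero_replace Replace zeros by the minimum non-zero value before
#'   correlation (raw data only).
#' @param low_expression_drop Fraction for \code{\link{filter_low_expression}};
#'   0 skips step (a) of that filter but still applies the zero-fraction rule
#'   when > 0 is given as \code{NULL}/0 the filter is skipped entirely.
#' @param gene_sets Named list of gene-set collections (each a named list of
#'   character vectors) for enrichment; NULL skips enrichment.
#' @param gene_lists Named list of character vectors for ratio statistics.
#' @param out_dir Output directory for artifact files; NULL keeps results in
#'   memory only.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(S = 0.005, D_min = 5L, D_max_percent = 0.1,
                            k = 10L, M_percent = 1,
                            maxTreeHeight = 1, deepSplit = TRUE,
                            minModuleSize = 50L,
                            linkage = "average",
                            extend_overlap = FALSE,
                            feature_kind = c("gene", "isoform"),
                            min_module_genes = NULL,
                            max_module_genes = NULL,
                            permutation_N = 0L,
                            seed = 1L,
                            zero_replace = FALSE,
                            low_expression_drop = NULL,
                            gene_sets = NULL,
                            gene_lists = NULL,
                            out_dir = NULL) {
  feature_kind <- match.arg(feature_kind)
  for (q in c(S, M_percent, D_max_percent))
    if (q <= 0 || q > 100)
      stop("quantile parameters must lie in (0, 100]", call. = FALSE)
  if (is.null(min_module_genes)) min_module_genes <- 10L
  if (is.null(max_module_genes))
    max_module_genes <- if (feature_kind == "gene") 300L else 500L
  structure(list(S = S, D_min = as.integer(D_min),
                 D_max_percent = D_max_percent, k = as.integer(k),
                 M_percent = M_percent,
                 tree_cut = tree_cut_params(maxTreeHeight, deepSplit,
                                            minModuleSize),
                 linkage = linkage,
                 extend_overlap = isTRUE(extend_overlap),
                 feature_kind = feature_kind,
                 min_module_genes = as.integer(min_module_genes),
                 max_module_genes = as.integer(max_module_genes),
                 permutation_N = as.integer(permutation_N),
                 seed = as.integer(seed),
                 zero_replace = isTRUE(zero_replace),
                 low_expression_drop = low_expression_drop,
                 gene_sets = gene_sets,
                 gene_lists = gene_lists,
                 out_dir = out_dir),
            class = "pipeline_config")
}

log_stage <- function(...) message("[fgmd] ", ...)

#' Run the full module-detection pipeline
#'
#' Executes preprocessing (optional), correlation, seed-pair extraction
#' (Step 1), greedy expansion (Step 2), overlap merging (Step 3), splitting
#' (Step 4), the optional overlap extension, size filtering, and the requested
#' validation battery. When \code{cfg$out_dir} is set, writes the module TSVs,
#' summary and validation tables, and a JSON run manifest recording every
#' resolved parameter and realized threshold, so a run can be reproduced
#' bit-for-bit from the manifest alone.
#'
#' @param expr Expression matrix (features x samples), or a path to a TSV
#'   readable by \code{\link{read_expression_tsv}}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the correlation matrix, seed network, all
#'   module sets (SPE, large, FGMD, filtered), validation tables and the
#'   manifest.
#' @export
run_pipeline <- function(expr, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  if (is.character(expr)) expr <- read_expression_tsv(expr)
  check_expression_matrix(expr)

  if (!is.null(cfg$low_expression_drop) && cfg$low_expression_drop > 0) {
    expr <- filter_low_expression(expr, cfg$low_expression_drop)
    log_stage("low-expression filter: ", nrow(expr), " features retained")
  }
  if (cfg$zero_replace)
    expr <- replace_zeros_with_min_nonzero(expr)

  log_stage("correlating ", nrow(expr), " features over ", ncol(expr),
            " samples")
  a <- abs_pcc_matrix(expr)

  sn <- extract_seed_pairs(a, S = cfg$S, D_min = cfg$D_min,
                           D_max_percent = cfg$D_max_percent)
  log_stage("step 1: ", nrow(sn$pairs), " seed pairs over ",
            length(sn$degrees), " genes (threshold ",
            sprintf("%.4f", sn$seed_threshold), ")")
  if (nrow(sn$pairs) == 0L)
    stop("stage seeding: no seed pairs survive; nothing to expand",
         call. = FALSE)

  ep <- expansion_params(a, M_percent = cfg$M_percent, k = cfg$k)
  spe <- expand_all_seeds(sn, a, ep)
  log_stage("step 2: ", length(spe), " SPE modules (mean size ",
            sprintf("%.1f", mean(lengths(spe$modules))), ", M ",
            sprintf("%.4f", ep$M), ")")

  large <- merge_similar_modules(spe, cfg$tree_cut, cfg$linkage)
  log_stage("step 3: ", length(large), " large modules")

  fgmd <- split_all_large_modules(large, a, cfg$tree_cut, cfg$linkage)
  log_stage("step 4: ", length(fgmd), " final modules")

  if (cfg$extend_overlap) {
    parts <- split(seq_along(fgmd$modules), fgmd$provenance)
    mods <- fgmd$modules
    for (parent_nm in names(parts)) {
      idx <- parts[[parent_nm]]
      sub <- module_set(mods[idx], stage = "FGMD")
      ext <- extend_small_modules_with_overlap(
        sub, large$modules[[parent_nm]], a)
      mods[idx] <- ext$modules
    }
    fgmd <- module_set(mods, stage = "FGMD", provenance = fgmd$provenance)
    log_stage("overlap extension applied within ", length(parts),
              " large modules")
  }

  final <- filter_module_sizes(fgmd, cfg$min_module_genes,
                               cfg$max_module_genes)
  log_stage("size filter [", cfg$min_module_genes, ", ",
            cfg$max_module_genes, "]: ", length(final), " modules retained")

  perm <- NULL
  if (cfg$permutation_N > 0L && length(final)) {
    perm <- permutation_test_set(final, a, N = cfg$permutation_N,
                                 seed = cfg$seed)
    log_stage("permutation test: ", sum(perm$q < 0.05), " of ",
              nrow(perm), " modules significant (Bonferroni q < 0.05)")
  }

  enrich <- NULL
  if (!is.null(cfg$gene_sets) && length(final)) {
    enrich <- lapply(cfg$gene_sets, hypergeom_enrichment,
                     ms = final, universe = rownames(a))
    for (nm in names(enrich))
      log_stage("enrichment [", nm, "]: ",
                length(unique(enrich[[nm]]$module[enrich[[nm]]$q < 0.05])),
                " enriched modules")
  }

  ratios <- NULL
  if (!is.null(cfg$gene_lists) && length(final)) {
    ratios <- data.frame(
      list_name = names(cfg$gene_lists),
      pooled = vapply(cfg$gene_lists, gene_list_ratio, numeric(1L),
                      ms = final, mode = "pooled"),
      unique = vapply(cfg$gene_lists, gene_list_ratio, numeric(1L),
                      ms = final, mode = "unique"),
      row.names = NULL)
  }

  manifest <- list(
    parameters = cfg[setdiff(names(cfg),
                             c("gene_sets", "gene_lists", "out_dir"))],
    realized = list(seed_threshold = sn$seed_threshold,
                    D_max = sn$D_max, M = ep$M,
                    expansion_degree_cap = ep$degree_cap),
    counts = list(n_features = nrow(expr), n_samples = ncol(expr),
                  seed_pairs = nrow(sn$pairs),
                  seed_genes = length(sn$degrees),
                  spe_modules = length(spe),
                  large_modules = length(large),
                  fgmd_modules = length(fgmd),
                  final_modules = length(final)))

  res <- list(correlation = a, seed_network = sn, spe = spe, large = large,
              fgmd = fgmd, final = final,
              summary = if (length(final)) module_summary(final, a) else NULL,
              permutation = perm, enrichment = enrich, ratios = ratios,
              manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    outp <- function(f) file.path(cfg$out_dir, f)
    write_seed_pairs_tsv(sn, a, outp("seed_pairs.tsv"))
    write_modules_tsv(spe, outp("spe_modules.tsv"))
    write_modules_tsv(large, outp("large_modules.tsv"))
    write_modules_tsv(fgmd, outp("fgmd_modules.tsv"))
    write_modules_tsv(final, outp("final_modules.tsv"))
    if (!is.null(res$summary))
      utils::write.table(res$summary, outp("module_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(perm))
      utils::write.table(perm, outp("permutation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(enrich))
      for (nm in names(enrich))
        utils::write.table(enrich[[nm]],
                           outp(paste0("enrichment_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ratios))
      utils::write.table(ratios, outp("gene_list_ratios.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    log_stage("artifacts written to ", cfg$out_dir)
  }
  invisible(res)
}
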