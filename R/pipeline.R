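#' Run the full SNG analysis pipeline on in-memory inputs
#'
#' Convenience driver that chains the stages: SNG identification, pair
#' records and binned co-expression summaries, the randomization null,
#' optional omics features, the repeated logistic model per feature set, and
#' (when metabolites are supplied) module construction and metabolite
#' association. When `outdir` is given, each stage's table is written as TSV
#' alongside `report.json` and the resolved configuration (including the
#' seed) as `config.json`, so a run is reproducible from its output
#' directory.
#'
#' @param focal Focal annotation tibble.
#' @param references Named list of reference annotations.
#' @param orthologs Ortholog table.
#' @param expr Genes x tissues TPM matrix.
#' @param config An [sng_config()].
#' @param atac,h3k27ac,contacts,go,elements,metabolites,tf_list Optional
#'   omics inputs (see the stage functions).
#' @param policy Missing-ortholog policy for [find_sngs()].
#' @param outdir Optional output directory.
#' @return List with elements `sngs`, `records`, `distance_bins`,
#'   `length_bins`, `null`, `models` (list per feature set incl.
#'   `"combined"`), `importance`, `modules`, `module_metabolite`,
#'   `gene_metabolite`, `report`.
#' @export
run_sng_pipeline <- function(focal, references, orthologs, expr,
                             config = sng_config(),
                             atac = NULL, h3k27ac = NULL, contacts = NULL,
                             go = NULL, elements = NULL, metabolites = NULL,
                             tf_list = character(), policy = "strict",
                             outdir = NULL) {
  stopifnot(inherits(config, "sng_config"))
  sngs <- find_sngs(focal, references, orthologs, policy = policy)
  records <- pair_records(sngs, expr, focal,
                          coexpr_threshold = config$coexpr_threshold)
  records <- build_feature_table(records, focal, expr, atac = atac,
                                 h3k27ac = h3k27ac, contacts = contacts,
                                 go = go, elements = elements,
                                 promoter_window = config$promoter_window)
  dist_bins <- bin_pairs(records, config$distance_edges, "distance",
                         n_boot = config$n_bootstrap, seed = config$seed)
  len_bins <- bin_pairs(records, config$length_edges, "mean_length",
                        n_boot = config$n_bootstrap, seed = config$seed)
  null <- randomization_null(expr, n_pairs = nrow(records),
                             n_iter = config$n_randomization,
                             threshold = config$coexpr_threshold,
                             seed = config$seed,
                             observed = coexpression_proportion(records))

  feature_cols <- intersect(
    c("distance", "mean_length", "atac", "h3k27ac", "hic", "go_shared",
      "promoter_shared", "enhancer_shared", "expr_diff"),
    names(records))
  models <- list()
  enough <- sum(records$coexpressed) >= 2 && sum(!records$coexpressed) >= 2
  if (enough) {
    for (f in feature_cols) {
      models[[f]] <- tryCatch(
        repeated_auc(records, f, n_repeats = config$n_model_repeats,
                     train_fraction = config$train_fraction,
                     seed = config$seed, allow_downsample_positives = TRUE),
        warning = function(w) NULL, error = function(e) NULL)
    }
    models[["combined"]] <- repeated_auc(records, feature_cols,
                                         n_repeats = config$n_model_repeats,
                                         train_fraction = config$train_fraction,
                                         seed = config$seed,
                                         allow_downsample_positives = TRUE)
  }
  importance <- if (enough) variable_importance(models[["combined"]]) else NULL

  modules <- mm <- gm <- NULL
  if (!is.null(metabolites)) {
    sng_expr <- expr[intersect(sng_gene_set(sngs), rownames(expr)), , drop = FALSE]
    modules <- build_modules(sng_expr)
    if (ncol(modules$eigengenes) > 0) {
      mm <- module_metabolite_correlation(modules, metabolites)
    }
    gm <- gene_metabolite_correlation(sng_expr, metabolites)
  }

  report <- list(
    n_sng_pairs = nrow(sngs),
    n_sng_genes = length(sng_gene_set(sngs)),
    coexpression_proportion_pct = round_half_up(100 * coexpression_proportion(records), 2),
    null_p_value = null$p_value,
    distance_bins = dist_bins,
    length_bins = len_bins,
    mean_auc = if (enough) purrr::map_dbl(models, "mean_auc") else NULL
  )
  out <- list(sngs = sngs, records = records, distance_bins = dist_bins,
              length_bins = len_bins, null = null, models = models,
              importance = importance, modules = modules,
              module_metabolite = mm, gene_metabolite = gm, report = report)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, outdir)
    write_records(sngs, file.path(outdir, "sng_pairs.tsv"))
    write_records(records, file.path(outdir, "pair_records.tsv"))
    write_records(bind_rows(dist_bins, len_bins), file.path(outdir, "bin_summaries.tsv"))
    readr::write_tsv(tibble(proportion = null$proportions),
                     file.path(outdir, "null_distribution.tsv"))
    if (!is.null(importance)) write_records(importance, file.path(outdir, "importance.tsv"))
    if (!is.null(modules)) write_records(modules$modules, file.path(outdir, "modules.tsv"))
    if (!is.null(mm)) write_records(mm, file.path(outdir, "module_metabolite.tsv"))
    write_report(report, file.path(outdir, "report.json"))
  }
  out
}
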