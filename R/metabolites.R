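cor_test_p <- function(r, n) {
  # two-sided p from the t transform of a Pearson correlation, n-2 df
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Gene-metabolite Pearson correlations across tissues
#'
#' @param expr Genes x tissues TPM matrix.
#' @param metabolites Metabolites x tissues matrix with the same tissue set
#'   (columns matched by name).
#' @return Tibble `gene_id`, `metabolite`, `r`, `p_value`.
#' @export
gene_metabolite_correlation <- function(expr, metabolites) {
  if (!setequal(colnames(expr), colnames(metabolites))) {
    stopf("expression and metabolite tissue sets differ")
  }
  metabolites <- metabolites[, colnames(expr), drop = FALSE]
  n <- ncol(expr)
  keep <- apply(expr, 1, sd) > 0
  r <- cor(t(expr[keep, , drop = FALSE]), t(metabolites))
  tibble(gene_id = rep(rownames(r), times = ncol(r)),
         metabolite = rep(colnames(r), each = nrow(r)),
         r = as.numeric(r),
         p_value = cor_test_p(as.numeric(r), n))
}

#' Filter gene-metabolite associations and count set intersections
#'
#' Keeps associations with `r >= r_min` and `p <= p_max`, then reports the
#' per-metabolite gene sets, the upset-style counts of every observed
#' metabolite combination, and percentages of the filtered gene universe
#' (1 dp, half-up).
#'
#' @param assoc Tibble from [gene_metabolite_correlation()].
#' @param r_min Minimum correlation (e.g. 0.5, or 0.9 for the strong set).
#' @param p_max Maximum p-value.
#' @return List: `genes` (all passing genes), `per_metabolite` (tibble with
#'   counts and percentages), `combinations` (upset counts tibble), `sets`
#'   (named list of gene IDs per metabolite).
#' @export
filter_and_count <- function(assoc, r_min = 0.5, p_max = 0.05) {
  hits <- filter(assoc, .data$r >= r_min, .data$p_value <= p_max)
  if (nrow(hits) == 0) stopf("no genes pass filter")
  genes <- unique(hits$gene_id)
  sets <- split(hits$gene_id, hits$metabolite)
  per <- hits |>
    group_by(metabolite = .data$metabolite) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    mutate(percent = round_half_up(100 * .data$n_genes / length(genes), 1))
  combos <- hits |>
    group_by(.data$gene_id) |>
    summarise(combination = paste(sort(unique(.data$metabolite)), collapse = "+"),
              .groups = "drop") |>
    dplyr::count(.data$combination, name = "n_genes") |>
    mutate(percent = round_half_up(100 * .data$n_genes / length(genes), 1)) |>
    arrange(dplyr::desc(.data$n_genes))
  list(genes = genes, per_metabolite = per, combinations = combos, sets = sets)
}

# First principal component of the module's standardized expression over
# tissues, unit norm, sign fixed so the mean gene-eigengene correlation is
# positive.
module_eigengene <- function(expr_mod) {
  z <- t(scale(t(expr_mod)))
  z <- z[stats::complete.cases(z), , drop = FALSE]
  if (nrow(z) == 0) stopf("module has no non-constant genes")
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  kme <- as.numeric(cor(t(z), e))
  if (mean(kme) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Build signed co-expression modules
#'
#' Simplified signed-network module construction: signed adjacency
#' `a_ij = ((1 + r_ij) / 2)^power` from Pearson correlations, average-linkage
#' hierarchical clustering of the dissimilarity `1 - a`, a static cut at
#' `cut_height`, reassignment of clusters smaller than `min_size` to the
#' unassigned module `"grey"`, and iterative merging of modules whose
#' eigengenes correlate above `1 - merge_height`. Fully deterministic.
#'
#' @param expr Genes x tissues TPM matrix.
#' @param power Soft-thresholding power (default 14).
#' @param min_size Minimum module size (default 30).
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param cut_height Static tree-cut height on the 1 - a scale.
#' @return Object of class `module_assignment`: `modules` (tibble `gene_id`,
#'   `module`), `eigengenes` (tissues x modules matrix), `sizes` (named
#'   vector incl. `"grey"`).
#' @export
build_modules <- function(expr, power = 14, min_size = 30, merge_height = 0.25,
                          cut_height = 0.99) {
  keep <- apply(expr, 1, sd) > 0
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) < min_size) {
    rlang::warn("fewer genes than `min_size`; all genes left unassigned")
    return(new_module_assignment(setNames(rep("grey", nrow(expr)), rownames(expr)), expr))
  }
  r <- cor(t(expr))
  a <- ((1 + r) / 2)^power
  hc <- hclust(as.dist(1 - a), method = "average")
  lab <- cutree(hc, h = cut_height * max(hc$height))
  sizes <- table(lab)
  lab <- ifelse(sizes[as.character(lab)] >= min_size, paste0("M", lab), "grey")
  names(lab) <- rownames(expr)

  # merge modules with near-identical eigengenes
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2 || merge_height <= 0) break
    eg <- vapply(mods, function(m) module_eigengene(expr[lab == m, , drop = FALSE]),
                 numeric(ncol(expr)))
    ce <- cor(eg)
    diag(ce) <- -Inf
    top <- which(ce == max(ce), arr.ind = TRUE)[1, ]
    if (max(ce) <= 1 - merge_height) break
    lab[lab == mods[top[2]]] <- mods[top[1]]
  }
  # stable names by decreasing size
  mods <- setdiff(unique(lab), "grey")
  mods <- mods[order(-vapply(mods, function(m) sum(lab == m), 0L), mods)]
  relab <- setNames(paste0("M", seq_along(mods)), mods)
  lab[lab != "grey"] <- relab[lab[lab != "grey"]]
  new_module_assignment(lab, expr)
}

new_module_assignment <- function(lab, expr) {
  mods <- setdiff(sort(unique(lab)), "grey")
  eg <- if (length(mods)) {
    vapply(mods, function(m) module_eigengene(expr[names(lab)[lab == m], , drop = FALSE]),
           numeric(ncol(expr)))
  } else {
    matrix(numeric(0), ncol(expr), 0)
  }
  rownames(eg) <- colnames(expr)
  structure(list(modules = tibble(gene_id = names(lab), module = unname(lab)),
                 eigengenes = eg,
                 sizes = c(table(lab))),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d gene(s) in %d module(s) (+grey)\n",
              nrow(x$modules), ncol(x$eigengenes)))
  print(x$sizes)
  invisible(x)
}

#' Read module assignments from file (external network output)
#'
#' Lets module assignments computed elsewhere be audited by the same
#' downstream correlation machinery.
#'
#' @param path TSV with columns `gene_id`, `module`.
#' @param expr Expression matrix used to recompute eigengenes.
#' @return A `module_assignment`.
#' @export
read_modules <- function(path, expr) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "module") %in% names(tb))) {
    stopf("module table must have columns gene_id, module")
  }
  lab <- setNames(tb$module, tb$gene_id)
  new_module_assignment(lab, expr[tb$gene_id, , drop = FALSE])
}

#' Module eigengene-metabolite correlation table
#'
#' Pearson correlation of each module eigengene with each metabolite across
#' tissues, with t-distribution p-values and a significance flag at
#' `r >= r_min` and `p <= p_max`. Module sizes are reported as percentages
#' of the analyzed gene universe (1 dp).
#'
#' @param ma A `module_assignment`.
#' @param metabolites Metabolites x tissues matrix.
#' @param r_min Correlation threshold (default 0.7).
#' @param p_max p-value threshold (default 0.05).
#' @return Tibble `module`, `metabolite`, `r`, `p_value`, `significant`,
#'   `module_size`, `percent_of_genes`.
#' @export
module_metabolite_correlation <- function(ma, metabolites, r_min = 0.7, p_max = 0.05) {
  stopifnot(inherits(ma, "module_assignment"))
  if (ncol(ma$eigengenes) == 0) stopf("no assigned modules")
  metabolites <- metabolites[, rownames(ma$eigengenes), drop = FALSE]
  n <- nrow(ma$eigengenes)
  r <- cor(ma$eigengenes, t(metabolites))
  total <- nrow(ma$modules)
  tibble(module = rep(rownames(r), times = ncol(r)),
         metabolite = rep(colnames(r), each = nrow(r)),
         r = as.numeric(r),
         p_value = cor_test_p(as.numeric(r), n)) |>
    mutate(significant = .data$r >= r_min & .data$p_value <= p_max,
           module_size = unname(ma$sizes[.data$module]),
           percent_of_genes = round_half_up(100 * .data$module_size / total, 1))
}

#' Rank module genes by eigengene-based connectivity (KME)
#'
#' KME is the Pearson correlation of a gene's profile with its module
#' eigengene; genes are ranked descending within their module and the top
#' `top_n` returned, with transcription factors flagged from a provided
#' list so TF hubs can be short-listed.
#'
#' @param ma A `module_assignment`.
#' @param expr Expression matrix (must cover the module genes).
#' @param tf_list Character vector of TF gene IDs (optional).
#' @param top_n Genes returned per module (default 60).
#' @return Tibble `module`, `gene_id`, `kme`, `rank`, `is_tf`.
#' @export
hub_ranking <- function(ma, expr, tf_list = character(), top_n = 60) {
  stopifnot(inherits(ma, "module_assignment"))
  mods <- colnames(ma$eigengenes)
  out <- purrr::map_dfr(mods, function(m) {
    ids <- ma$modules$gene_id[ma$modules$module == m]
    z <- t(scale(t(expr[ids, , drop = FALSE])))
    kme <- as.numeric(cor(t(z), ma$eigengenes[, m]))
    tibble(module = m, gene_id = ids, kme = kme) |>
      arrange(dplyr::desc(.data$kme)) |>
      mutate(rank = dplyr::row_number()) |>
      dplyr::slice_head(n = top_n)
  })
  mutate(out, is_tf = .data$gene_id %in% tf_list)
}
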