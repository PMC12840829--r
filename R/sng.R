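#' Rank genes along each chromosome
#'
#' Assigns each gene its 0-based position in start-coordinate order within
#' its chromosome. Ties on start are broken by end, then by gene ID, so the
#' ranking is deterministic. Adjacency ("linear neighbours") is defined on
#' these ranks and ignores strand and intergenic distance.
#'
#' @param ann Annotation tibble (`gene_id`, `chrom`, `start`, `end`, ...).
#' @return A tibble `gene_id`, `chrom`, `rank`.
#' @export
rank_genes <- function(ann) {
  ann |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(rank = dplyr::row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "chrom", "rank")
}

#' Are two genes linear neighbours?
#'
#' @param g1,g2 Gene IDs.
#' @param ranks Rank table from [rank_genes()].
#' @return `TRUE` iff the genes lie on the same chromosome with consecutive
#'   ranks.
#' @export
is_adjacent <- function(g1, g2, ranks) {
  i <- match(c(g1, g2), ranks$gene_id)
  if (anyNA(i)) stopf("unknown gene: %s", c(g1, g2)[which(is.na(i))[1]])
  ranks$chrom[i[1]] == ranks$chrom[i[2]] && abs(ranks$rank[i[1]] - ranks$rank[i[2]]) == 1
}

# Per-species ortholog lookup: named list species -> named list focal_gene -> chr vector
ortholog_index <- function(orthologs) {
  orthologs |>
    group_by(.data$species) |>
    group_map(~ split(.x$other_gene, .x$focal_gene), .keep = TRUE) |>
    setNames(sort(unique(orthologs$species)))
}

#' Classify a focal-adjacent pair in one reference species
#'
#' A pair is `adjacent` in a reference species if ANY ortholog of gene1 is a
#' linear neighbour of ANY ortholog of gene2 there (many-to-many OR rule,
#' conservative against false SNG calls); `no_ortholog` if either gene has no
#' ortholog in that species; otherwise `non_adjacent`.
#'
#' @param g1,g2 Focal gene IDs (must be adjacent in the focal genome).
#' @param species Reference species name.
#' @param orthologs Ortholog table (`focal_gene`, `other_gene`, `species`).
#' @param species_ranks Rank table for that species from [rank_genes()].
#' @return One of `"adjacent"`, `"non_adjacent"`, `"no_ortholog"`.
#' @export
classify_pair_in_species <- function(g1, g2, species, orthologs, species_ranks) {
  o1 <- orthologs$other_gene[orthologs$focal_gene == g1 & orthologs$species == species]
  o2 <- orthologs$other_gene[orthologs$focal_gene == g2 & orthologs$species == species]
  classify_with_sets(o1, o2, species_ranks)
}

classify_with_sets <- function(o1, o2, species_ranks) {
  if (length(o1) == 0 || length(o2) == 0) return("no_ortholog")
  i1 <- match(o1, species_ranks$gene_id)
  i2 <- match(o2, species_ranks$gene_id)
  if (anyNA(i1) || anyNA(i2)) {
    stopf("ortholog %s not present in the species annotation",
          c(o1, o2)[which(is.na(c(i1, i2)))[1]])
  }
  for (a in i1) {
    hit <- species_ranks$chrom[i2] == species_ranks$chrom[a] &
      abs(species_ranks$rank[i2] - species_ranks$rank[a]) == 1
    if (any(hit)) return("adjacent")
  }
  "non_adjacent"
}

#' Find specific neighboring gene pairs (SNGs)
#'
#' Enumerates every adjacent gene pair in the focal annotation, classifies it
#' in each reference species via orthologs, and keeps the pairs that are not
#' adjacent in any reference. Under the default `"strict"` policy a pair must
#' be `non_adjacent` in every reference species (a missing ortholog anywhere
#' disqualifies it); under `"lenient"` it must merely never be `adjacent`, so
#' `no_ortholog` species still count toward the intersection.
#'
#' @param focal Focal-species annotation tibble.
#' @param references Named list of reference annotation tibbles.
#' @param orthologs Ortholog table (`focal_gene`, `other_gene`, `species`).
#' @param policy `"strict"` or `"lenient"`.
#' @return A tibble of SNG pairs sorted by (chrom, rank): `gene1`, `gene2`,
#'   `chrom`, `rank1`, `rank2`, plus one `status_<species>` column per
#'   reference.
#' @examples
#' sim <- simulate_genomes(n_species = 3, n_genes = 30, frac_planted_sng = 0.1,
#'                         seed = 7)
#' find_sngs(sim$annotations$focal, sim$annotations[-1], sim$orthologs)
#' @export
find_sngs <- function(focal, references, orthologs, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stopf("`references` must be a named list of annotations")
  }
  if (nrow(focal) == 0) stopf("focal annotation is empty")
  if (length(references) < 1) stopf("at least one reference species is required")

  ranks <- rank_genes(focal)
  pairs <- ranks |>
    arrange(.data$chrom, .data$rank) |>
    group_by(.data$chrom) |>
    mutate(gene2 = dplyr::lead(.data$gene_id), rank2 = dplyr::lead(.data$rank)) |>
    ungroup() |>
    filter(!is.na(.data$gene2)) |>
    select(gene1 = "gene_id", gene2 = "gene2", chrom = "chrom",
           rank1 = "rank", rank2 = "rank2")
  ref_ranks <- lapply(references, rank_genes)
  omap <- ortholog_index(orthologs)

  for (sp in names(references)) {
    look <- omap[[sp]] %||% list()
    rr <- ref_ranks[[sp]]
    pairs[[paste0("status_", sp)]] <- purrr::map2_chr(
      pairs$gene1, pairs$gene2,
      function(a, b) classify_with_sets(look[[a]], look[[b]], rr)
    )
  }
  st <- as.matrix(pairs[paste0("status_", names(references))])
  keep <- if (policy == "strict") {
    rowSums(st == "non_adjacent") == ncol(st)
  } else {
    rowSums(st == "adjacent") == 0
  }
  arrange(pairs[keep, ], .data$chrom, .data$rank1)
}

#' Unique genes involved in a set of SNG pairs
#'
#' @param pairs Tibble with `gene1`, `gene2` columns.
#' @return Character vector of distinct gene IDs (fewer than `2 * nrow` when
#'   pairs chain through shared genes).
#' @export
sng_gene_set <- function(pairs) {
  unique(c(pairs$gene1, pairs$gene2))
}
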