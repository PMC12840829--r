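genes_granges <- function(ann, upstream = 0) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, ann$start - upstream), end = ann$end),
    gene_id = ann$gene_id
  )
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start, end = peaks$end)
  )
}

check_chrom_space <- function(peaks, ann, what = "peak") {
  bad <- setdiff(unique(peaks$chrom), unique(ann$chrom))
  if (length(bad)) {
    stopf("%s chromosome(s) absent from the annotation: %s", what,
          paste(bad, collapse = ", "))
  }
}

#' Flag genes carrying a peak
#'
#' A gene is flagged 1 if any peak overlaps its gene body extended by the
#' upstream promoter window (`[start - promoter_window, end]`, 1-based
#' inclusive) by at least 1 bp; strand-agnostic.
#'
#' @param peaks Peak tibble (1-based inclusive, from [read_peaks()] or the
#'   simulator).
#' @param ann Annotation tibble.
#' @param promoter_window Upstream extension in bp (default 2000).
#' @return Tibble `gene_id`, `flag` (0/1), one row per annotation gene.
#' @export
annotate_peaks_to_genes <- function(peaks, ann, promoter_window = 2000) {
  check_chrom_space(peaks, ann)
  hits <- GenomicRanges::findOverlaps(genes_granges(ann, upstream = promoter_window),
                                      peaks_granges(peaks))
  tibble(gene_id = ann$gene_id,
         flag = as.integer(seq_len(nrow(ann)) %in% S4Vectors::queryHits(hits)))
}

#' Call active enhancers and assign them to genes
#'
#' Active enhancers are the intersections of intergenic H3K27ac peaks (no
#' overlap with any gene body) with ATAC peaks. Each enhancer is assigned
#' its nearest gene by TSS distance (unlimited range); the two nearest genes
#' are also recorded so pair-level sharing can require that an enhancer's
#' two closest genes are exactly the pair.
#'
#' @param h3k27ac,atac Peak tibbles (1-based inclusive).
#' @param ann Annotation tibble.
#' @return Tibble of enhancers: `chrom`, `start`, `end`, `nearest_gene`,
#'   `second_gene`.
#' @export
call_active_enhancers <- function(h3k27ac, atac, ann) {
  check_chrom_space(h3k27ac, ann, "H3K27ac peak")
  check_chrom_space(atac, ann, "ATAC peak")
  bodies <- genes_granges(ann)
  k27 <- peaks_granges(h3k27ac)
  intergenic <- k27[!IRanges::overlapsAny(k27, bodies)]
  enh <- GenomicRanges::intersect(intergenic, GenomicRanges::reduce(peaks_granges(atac)))
  if (length(enh) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  nearest_gene = character(), second_gene = character()))
  }
  tss <- tss_positions(ann)
  mid <- (GenomicRanges::start(enh) + GenomicRanges::end(enh)) / 2
  echr <- as.character(GenomicRanges::seqnames(enh))
  near <- t(vapply(seq_along(enh), function(i) {
    d <- ifelse(tss$chrom == echr[i], abs(tss$tss - mid[i]), Inf)
    o <- order(d)[1:2]
    c(tss$gene_id[o[1]], if (is.finite(d[o[2]])) tss$gene_id[o[2]] else NA_character_)
  }, c("", "")))
  tibble(chrom = echr,
         start = GenomicRanges::start(enh),
         end = GenomicRanges::end(enh),
         nearest_gene = near[, 1],
         second_gene = near[, 2])
}

tss_positions <- function(ann) {
  tibble(gene_id = ann$gene_id, chrom = ann$chrom,
         tss = ifelse(ann$strand == "-", ann$end, ann$start))
}

#' ICE-normalize a contact matrix
#'
#' Iterative correction: the matrix is repeatedly divided by the outer
#' product of its relative row-sum bias until the maximum relative deviation
#' of the marginals drops below `tol` (or `max_iter` is reached), after
#' which all unmasked rows have equal sums. Bins whose marginal is zero are
#' masked and left untouched.
#'
#' @param cm A [contact_matrix()] (or plain symmetric matrix).
#' @param max_iter Maximum iterations (correction converges linearly; the
#'   default leaves ample headroom at these matrix sizes).
#' @param tol Convergence tolerance on `max |bias - 1|`.
#' @return A `contact_matrix` with attributes `bias` (per-bin cumulative
#'   bias, `NA` for masked bins), `mask` (logical), `converged`,
#'   `iterations`.
#' @export
ice_normalize <- function(cm, max_iter = 2000, tol = 1e-8) {
  plain <- is.matrix(cm)
  m <- if (plain) cm else cm$values
  if (max(abs(m - t(m))) > 1e-8) stopf("input matrix must be symmetric")
  if (any(m < 0)) stopf("input matrix must be non-negative")
  if (all(m == 0)) stopf("all-zero contact matrix cannot be normalized")
  mask <- rowSums(m) == 0
  bias <- rep(1, nrow(m))
  live <- which(!mask)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- rowSums(m[live, live, drop = FALSE])
    d <- s / mean(s)
    if (max(abs(d - 1)) < tol) { converged <- TRUE; break }
    m[live, live] <- m[live, live] / outer(d, d)
    bias[live] <- bias[live] * d
  }
  bias[mask] <- NA_real_
  out <- if (plain) contact_matrix(m) else contact_matrix(m, cm$bin_size, cm$bins)
  attr(out, "bias") <- bias
  attr(out, "mask") <- mask
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Hi-C contact between the TSS bins of a gene pair
#'
#' The TSS is the start coordinate for `+`/`.` genes and the end for `-`
#' genes; its bin is `floor((tss - 1) / bin_size)` within the chromosome.
#' Same-bin pairs return the diagonal entry. A TSS falling in a bin absent
#' from (or masked in) the matrix yields contact 0 with `missing = TRUE`.
#'
#' @param g1,g2 One-row gene tibbles/lists with `chrom`, `start`, `end`,
#'   `strand`.
#' @param cm A [contact_matrix()].
#' @return List: `contact`, `missing`.
#' @export
hic_contact_for_pair <- function(g1, g2, cm) {
  mask <- attr(cm, "mask") %||% rep(FALSE, nrow(cm$values))
  locate <- function(g) {
    tss <- if (identical(g$strand, "-")) g$end else g$start
    idx <- floor((tss - 1) / cm$bin_size)
    which(cm$bins$chrom == g$chrom & cm$bins$index == idx)
  }
  r1 <- locate(g1); r2 <- locate(g2)
  if (length(r1) != 1 || length(r2) != 1 || mask[r1] || mask[r2]) {
    return(list(contact = 0, missing = TRUE))
  }
  list(contact = cm$values[r1, r2], missing = FALSE)
}

#' Number of shared GO Biological Process terms
#'
#' Exact GO-ID intersection within the BP namespace; a gene with no BP
#' annotation shares 0 terms.
#'
#' @param g1,g2 Gene IDs.
#' @param go Tibble `gene_id`, `go_id`, `namespace`.
#' @return Non-negative integer count.
#' @export
shared_go_terms <- function(g1, g2, go) {
  bp <- go[go$namespace == "BP", ]
  length(intersect(unique(bp$go_id[bp$gene_id == g1]),
                   unique(bp$go_id[bp$gene_id == g2])))
}

#' Number of shared promoter cis-regulatory elements
#'
#' Distinct element names present in both genes' promoter element sets
#' (multiplicities are ignored).
#'
#' @param g1,g2 Gene IDs.
#' @param elements Tibble `gene_id`, `element`.
#' @return Non-negative integer count.
#' @export
shared_promoter_elements <- function(g1, g2, elements) {
  length(intersect(unique(elements$element[elements$gene_id == g1]),
                   unique(elements$element[elements$gene_id == g2])))
}

#' Relative expression difference of a pair
#'
#' `|e1 - e2| / ((e1 + e2) / 2)`, symmetric and scale-invariant, in \[0, 2\].
#'
#' @param e1,e2 Mean TPM of each gene (e1 + e2 > 0).
#' @return Value in \[0, 2\].
#' @export
expression_difference <- function(e1, e2) {
  if (any(e1 + e2 <= 0)) stopf("both expression levels are zero")
  abs(e1 - e2) / ((e1 + e2) / 2)
}

#' Compare expression between peak-annotated and non-annotated genes
#'
#' Stratifies per-gene mean TPM by a 0/1 flag, reports group medians, the
#' relative increase of the flagged median (2 dp, half-up), and a
#' Mann-Whitney U p-value.
#'
#' @param expr Genes x tissues TPM matrix.
#' @param flags Tibble `gene_id`, `flag` (from [annotate_peaks_to_genes()]).
#' @return List: `median_with`, `median_without`, `relative_increase`,
#'   `p_value`, `n_with`, `n_without`.
#' @export
compare_expression_by_flag <- function(expr, flags) {
  mu <- rowMeans(expr)
  f <- flags$flag[match(names(mu), flags$gene_id)]
  if (anyNA(f)) stopf("flags missing for %d gene(s)", sum(is.na(f)))
  with_ <- mu[f == 1]; without <- mu[f == 0]
  if (length(with_) == 0 || length(without) == 0) stopf("one flag group is empty")
  mw <- mann_whitney_u(with_, without)
  list(median_with = median(with_), median_without = median(without),
       relative_increase = relative_change(median(with_), median(without)),
       p_value = mw$p_value, n_with = length(with_), n_without = length(without))
}

#' Assemble the full per-pair feature table
#'
#' Adds the nine model covariates to a pair-record tibble: `atac` and
#' `h3k27ac` flags (per-gene flags combined by AND by default, OR
#' available), ICE-normalized Hi-C TSS-bin contact (`hic`, with
#' `hic_missing`), shared GO BP terms (`go_shared`), shared promoter
#' elements (`promoter_shared`), enhancer sharing (`enhancer_shared`: the
#' two nearest genes of one enhancer are exactly the pair), relative
#' expression difference (`expr_diff`), plus the `distance` and
#' `mean_length` already on the records.
#'
#' @param records Pair records from [pair_records()].
#' @param ann Annotation tibble.
#' @param expr TPM matrix.
#' @param atac,h3k27ac Peak tibbles (either may be `NULL` to skip).
#' @param contacts A [contact_matrix()] or `NULL`.
#' @param go GO tibble or `NULL`.
#' @param elements Promoter element tibble or `NULL`.
#' @param promoter_window Upstream window for peak-to-gene annotation.
#' @param pair_flag_rule `"and"` (both genes flagged) or `"or"` (either).
#' @param ice If `TRUE` (default), ICE-normalize `contacts` first.
#' @return The records tibble with feature columns appended.
#' @export
build_feature_table <- function(records, ann, expr, atac = NULL, h3k27ac = NULL,
                                contacts = NULL, go = NULL, elements = NULL,
                                promoter_window = 2000,
                                pair_flag_rule = c("and", "or"), ice = TRUE) {
  pair_flag_rule <- match.arg(pair_flag_rule)
  comb <- function(a, b) if (pair_flag_rule == "and") as.integer(a & b) else as.integer(a | b)
  out <- records
  for (nm in c("atac", "h3k27ac")) {
    pk <- if (nm == "atac") atac else h3k27ac
    if (!is.null(pk)) {
      fl <- annotate_peaks_to_genes(pk, ann, promoter_window)
      f <- setNames(fl$flag, fl$gene_id)
      out[[nm]] <- comb(f[out$gene1] == 1, f[out$gene2] == 1)
    }
  }
  if (!is.null(contacts)) {
    cmn <- if (ice) ice_normalize(contacts) else contacts
    idx <- match(c(out$gene1, out$gene2), ann$gene_id)
    n <- nrow(out)
    hic <- vapply(seq_len(n), function(i) {
      h <- hic_contact_for_pair(ann[idx[i], ], ann[idx[n + i], ], cmn)
      c(h$contact, as.numeric(h$missing))
    }, c(0, 0))
    out$hic <- hic[1, ]
    out$hic_missing <- as.integer(hic[2, ])
  }
  if (!is.null(go)) {
    out$go_shared <- purrr::map2_int(out$gene1, out$gene2,
                                     ~ shared_go_terms(.x, .y, go))
  }
  if (!is.null(elements)) {
    out$promoter_shared <- purrr::map2_int(out$gene1, out$gene2,
                                           ~ shared_promoter_elements(.x, .y, elements))
  }
  if (!is.null(atac) && !is.null(h3k27ac)) {
    enh <- call_active_enhancers(h3k27ac, atac, ann)
    key <- paste(pmin(enh$nearest_gene, enh$second_gene),
                 pmax(enh$nearest_gene, enh$second_gene))
    pk <- paste(pmin(out$gene1, out$gene2), pmax(out$gene1, out$gene2))
    out$enhancer_shared <- as.integer(pk %in% key)
  }
  mu <- rowMeans(expr)
  out$expr_diff <- expression_difference(mu[out$gene1], mu[out$gene2])
  out
}
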