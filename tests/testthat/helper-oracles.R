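# Independent oracles and fixture builders, deliberately implemented with
# plain base-R loops so they share no code with the package internals.

# Exhaustive SNG scan over ALL gene pairs (not only pre-indexed adjacent
# ones), used to check find_sngs().
brute_force_sngs <- function(annotations, orthologs, policy = "strict") {
  focal <- annotations$focal
  refs <- annotations[setdiff(names(annotations), "focal")]
  position <- function(ann) {
    o <- order(ann$chrom, ann$start, ann$end, ann$gene_id)
    pos <- list()
    for (chr in unique(ann$chrom[o])) {
      ids <- ann$gene_id[o][ann$chrom[o] == chr]
      for (k in seq_along(ids)) pos[[ids[k]]] <- c(chr, k)
    }
    pos
  }
  adj <- function(pos, a, b) {
    pa <- pos[[a]]; pb <- pos[[b]]
    !is.null(pa) && !is.null(pb) && pa[1] == pb[1] &&
      abs(as.integer(pa[2]) - as.integer(pb[2])) == 1
  }
  fpos <- position(focal)
  rpos <- lapply(refs, position)
  out <- character(0)
  ids <- focal$gene_id
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      if (!adj(fpos, ids[i], ids[j])) next
      ok <- TRUE
      for (sp in names(refs)) {
        o1 <- orthologs$other_gene[orthologs$focal_gene == ids[i] & orthologs$species == sp]
        o2 <- orthologs$other_gene[orthologs$focal_gene == ids[j] & orthologs$species == sp]
        if (length(o1) == 0 || length(o2) == 0) {
          status <- "no_ortholog"
        } else {
          status <- "non_adjacent"
          for (a in o1) for (b in o2) if (adj(rpos[[sp]], a, b)) status <- "adjacent"
        }
        bad <- if (policy == "strict") status != "non_adjacent" else status == "adjacent"
        if (bad) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = " "))
    }
  }
  sort(out)
}

sng_keys <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  sort(paste(pmin(pairs$gene1, pairs$gene2), pmax(pairs$gene1, pairs$gene2)))
}

# Random small multi-species instance with arbitrary (0..2-to-many) orthology.
random_instance <- function(seed, max_genes = 50, max_species = 5) {
  set.seed(seed)
  n_sp <- sample(2:max_species, 1)
  make_ann <- function(species, n) {
    n_chr <- sample(1:3, 1)
    chrom <- sort(sample(paste0("chr", 1:n_chr), n, replace = TRUE))
    start <- sample.int(1e5, n)
    tibble::tibble(
      gene_id = paste0(species, "_g", seq_len(n)),
      species = species, chrom = chrom,
      start = start, end = start + sample.int(5000, n),
      strand = sample(c("+", "-"), n, replace = TRUE))
  }
  n_focal <- sample(10:max_genes, 1)
  anns <- list(focal = make_ann("focal", n_focal))
  orth <- list()
  for (s in seq_len(n_sp - 1)) {
    sp <- paste0("ref", s)
    n_ref <- sample(10:max_genes, 1)
    anns[[sp]] <- make_ann(sp, n_ref)
    k <- sample.int(2 * n_focal, 1)
    orth[[sp]] <- tibble::tibble(
      focal_gene = sample(anns$focal$gene_id, k, replace = TRUE),
      other_gene = sample(anns[[sp]]$gene_id, k, replace = TRUE),
      species = sp, score = 1)
  }
  list(annotations = anns, orthologs = unique(dplyr::bind_rows(orth)))
}

# Exhaustive pairwise AUC (ties counted 0.5).
auc_exhaustive <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Adjusted Rand index from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Minimal in-memory annotation builder.
toy_annotation <- function(starts, ends, chrom = "chr1", strand = "+",
                           species = "focal", ids = NULL) {
  n <- length(starts)
  tibble::tibble(
    gene_id = ids %||% paste0("g", seq_len(n)),
    species = species,
    chrom = rep_len(chrom, n),
    start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strand, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Pair records with planted per-bin co-expression counts, for reporting
# arithmetic driven by printed group sizes.
records_from_counts <- function(distances, n_pairs, n_coexpr) {
  recs <- list()
  for (k in seq_along(distances)) {
    recs[[k]] <- tibble::tibble(
      gene1 = sprintf("b%d_a%04d", k, seq_len(n_pairs[k])),
      gene2 = sprintf("b%d_b%04d", k, seq_len(n_pairs[k])),
      distance = distances[k],
      mean_length = 6000,
      coexpressed = seq_len(n_pairs[k]) <= n_coexpr[k],
      r = ifelse(seq_len(n_pairs[k]) <= n_coexpr[k], 0.8, 0.1))
  }
  dplyr::bind_rows(recs)
}
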