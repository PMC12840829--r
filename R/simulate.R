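#' Simulate multi-species genomes with planted specific neighboring pairs
#'
#' Builds a focal annotation plus `n_species - 1` reference annotations and a
#' 1:1 ortholog table. A chosen fraction of disjoint adjacent focal pairs is
#' "planted" as SNGs: in every reference species a species-specific filler
#' gene (with no focal ortholog) is inserted between the two orthologs, so
#' the planted pair is separated by an intervening gene everywhere while
#' every other focal-adjacent pair keeps its reference adjacency. Planted
#' genes always have orthologs in all species; a configurable fraction of the
#' remaining genes lacks orthologs in a random subset of species, exercising
#' the missing-ortholog policy.
#'
#' @param n_species Total species count (focal + references), >= 2.
#' @param n_genes Genes in the focal genome, >= 10.
#' @param frac_planted_sng Fraction of adjacent focal pairs planted as SNGs.
#' @param seed Integer seed.
#' @param n_chrom Number of focal chromosomes.
#' @param frac_missing_ortholog Per-gene probability of lacking an ortholog
#'   in some (never all) reference species.
#' @return A list: `annotations` (named list of tibbles, focal first),
#'   `orthologs` (tibble), `truth` (list with `true_sng_pairs` tibble).
#' @examples
#' sim <- simulate_genomes(4, 40, 0.1, seed = 1)
#' sim$truth$true_sng_pairs
#' @export
simulate_genomes <- function(n_species, n_genes, frac_planted_sng, seed,
                             n_chrom = 2, frac_missing_ortholog = 0.05) {
  if (n_species < 2) stopf("`n_species` must be >= 2")
  if (n_genes < 10) stopf("`n_genes` must be >= 10")
  if (frac_planted_sng < 0 || frac_planted_sng > 1) stopf("`frac_planted_sng` must be in [0,1]")
  with_seed(seed, {
    per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1)))
    focal <- sample_annotation("focal", per_chrom)

    # eligible planted pairs: disjoint even-odd rank pairs within chromosome
    eligible <- even_odd_pairs(focal)
    n_adj <- n_genes - n_chrom
    n_plant <- round(frac_planted_sng * n_adj)
    if (n_plant > nrow(eligible)) {
      stopf("frac_planted_sng = %g requires %d disjoint adjacent pairs but only %d exist",
            frac_planted_sng, n_plant, nrow(eligible))
    }
    planted <- eligible[sort(sample.int(nrow(eligible), n_plant)), , drop = FALSE]
    planted_genes <- unique(c(planted$gene1, planted$gene2))

    refs <- list()
    orth <- list()
    ref_names <- paste0("ref", seq_len(n_species - 1))
    for (sp in ref_names) {
      # same gene order as focal, per-species coordinates, fillers inside planted pairs
      ids <- paste0(sp, "_", focal$gene_id)
      ord <- tibble(chrom = focal$chrom, gene_id = ids, focal_gene = focal$gene_id)
      for (k in seq_len(nrow(planted))) {
        pos <- which(ord$focal_gene == planted$gene1[k])
        filler <- tibble(chrom = ord$chrom[pos],
                         gene_id = sprintf("%s_filler_%03d", sp, k),
                         focal_gene = NA_character_)
        ord <- bind_rows(ord[seq_len(pos), ], filler,
                         ord[seq(pos + 1, nrow(ord)), ])
      }
      ann <- sample_annotation(sp, table(ord$chrom)[unique(ord$chrom)],
                               ids = ord$gene_id, chroms = ord$chrom)
      refs[[sp]] <- ann
      keep <- !is.na(ord$focal_gene)
      orth[[sp]] <- tibble(focal_gene = ord$focal_gene[keep],
                           other_gene = ord$gene_id[keep],
                           species = sp,
                           score = round(runif(sum(keep), 0.3, 1), 3))
    }
    orthologs <- bind_rows(orth)

    # knock out orthologs for some non-planted genes in a proper species subset
    if (frac_missing_ortholog > 0 && n_species > 2) {
      cand <- setdiff(focal$gene_id, planted_genes)
      drop_gene <- cand[runif(length(cand)) < frac_missing_ortholog]
      for (g in drop_gene) {
        k <- sample.int(n_species - 2, 1)
        sps <- sample(ref_names, k)
        orthologs <- filter(orthologs,
                            !(.data$focal_gene == g & .data$species %in% sps))
      }
    }

    list(
      annotations = c(list(focal = focal), refs),
      orthologs = orthologs,
      truth = list(true_sng_pairs = select(planted, "gene1", "gene2", "chrom"))
    )
  })
}

# Random gene coordinates: lognormal lengths and intergenic gaps.
sample_annotation <- function(species, per_chrom, ids = NULL, chroms = NULL) {
  n <- sum(per_chrom)
  if (is.null(ids)) {
    ids <- sprintf("%s_g%04d", species, seq_len(n))
    chroms <- rep(paste0("chr", seq_along(per_chrom)), per_chrom)
  }
  len <- pmax(200L, as.integer(round(rlnorm(n, log(3000), 0.6))))
  gap <- pmax(100L, as.integer(round(rlnorm(n, log(9000), 1.1))))
  ann <- tibble(gene_id = ids, species = species, chrom = chroms,
                length = len, gap = gap) |>
    group_by(.data$chrom) |>
    mutate(start = cumsum(dplyr::lag(.data$length + .data$gap, default = 1L)),
           end = .data$start + .data$length - 1L) |>
    ungroup() |>
    mutate(strand = sample(c("+", "-"), n, replace = TRUE)) |>
    select("gene_id", "species", "chrom", "start", "end", "strand")
  ann
}

# Disjoint adjacent pairs at local ranks (0,1), (2,3), ... per chromosome.
even_odd_pairs <- function(ann) {
  rank_genes(ann) |>
    left_join(select(ann, "gene_id", "start", "end"), by = "gene_id") |>
    arrange(.data$chrom, .data$rank) |>
    group_by(.data$chrom) |>
    mutate(gene2 = dplyr::lead(.data$gene_id),
           start2 = dplyr::lead(.data$start),
           end2 = dplyr::lead(.data$end)) |>
    ungroup() |>
    filter(.data$rank %% 2 == 0, !is.na(.data$gene2)) |>
    transmute(gene1 = .data$gene_id, gene2 = .data$gene2, chrom = .data$chrom,
              distance = abs(.data$start2 - .data$start),
              mean_length = ((.data$end - .data$start + 1) +
                               (.data$end2 - .data$start2 + 1)) / 2)
}

#' Simulate a tissue expression matrix with distance/length-dependent pair
#' correlation
#'
#' Each disjoint adjacent gene pair shares a latent tissue profile with
#' mixing weight `w = clamp(base_weight - distance_effect * d +
#' length_effect * L, 0, 1)` where `d` is the intergenic distance (bp) and
#' `L` the mean gene length (bp); gene log-expression is
#' `w * z_pair + (1 - w) * u_gene + noise_sd * eps` and TPM is its
#' exponential, so values are non-negative and heavy-tailed like real TPM.
#' Larger `distance_effect` weakens co-expression of distant pairs; larger
#' `length_effect` strengthens it for long genes.
#'
#' @param ann Focal annotation tibble.
#' @param n_tissues Number of tissues (>= 3).
#' @param distance_effect Weight decay per bp of intergenic distance.
#' @param length_effect Weight gain per bp of mean gene length.
#' @param noise_sd Independent log-scale noise SD.
#' @param base_weight Baseline mixing weight before distance/length terms.
#' @param seed Integer seed.
#' @param log_mean,log_sd Location/scale of log-TPM.
#' @return Genes x tissues TPM matrix; attribute `"pair_weights"` holds the
#'   per-pair distance, mean length and realized mixing weight.
#' @export
simulate_expression <- function(ann, n_tissues = 8, distance_effect = 5e-6,
                                length_effect = 2e-5, noise_sd = 0.5,
                                base_weight = 0.75, seed = 1,
                                log_mean = 1.5, log_sd = 1) {
  if (n_tissues < 3) stopf("`n_tissues` must be >= 3")
  with_seed(seed, {
    n <- nrow(ann)
    pairs <- even_odd_pairs(ann) |>
      mutate(weight = pmin(1, pmax(0, base_weight -
                                     distance_effect * .data$distance +
                                     length_effect * .data$mean_length)))
    w <- rep(0, n)
    pid <- rep(NA_integer_, n)
    i1 <- match(pairs$gene1, ann$gene_id)
    i2 <- match(pairs$gene2, ann$gene_id)
    w[i1] <- pairs$weight; w[i2] <- pairs$weight
    pid[i1] <- seq_len(nrow(pairs)); pid[i2] <- seq_len(nrow(pairs))

    z <- matrix(rnorm(nrow(pairs) * n_tissues), nrow(pairs), n_tissues)
    u <- matrix(rnorm(n * n_tissues), n, n_tissues)
    eps <- matrix(rnorm(n * n_tissues, sd = noise_sd), n, n_tissues)
    shared <- matrix(0, n, n_tissues)
    shared[!is.na(pid), ] <- z[pid[!is.na(pid)], , drop = FALSE]
    x <- w * shared + (1 - w) * u + eps
    tpm <- exp(log_mean + log_sd * x)
    dimnames(tpm) <- list(ann$gene_id, paste0("tissue", seq_len(n_tissues)))
    attr(tpm, "pair_weights") <- pairs
    tpm
  })
}

#' Simulate ATAC-seq and H3K27ac peaks with a planted expression boost
#'
#' Each gene independently receives an ATAC and/or H3K27ac peak placed inside
#' its gene body; genes carrying at least one peak have their TPM multiplied
#' by `peak_boost`. Optionally, `n_enhancers` intergenic H3K27ac/ATAC peak
#' pairs are planted in distinct wide intergenic gaps, which downstream
#' active-enhancer calling should recover exactly.
#'
#' @param ann Annotation tibble.
#' @param expr TPM matrix over the same genes.
#' @param peak_prob Per-gene, per-assay peak probability.
#' @param peak_boost Multiplicative TPM boost for peak-annotated genes (>= 1).
#' @param n_enhancers Number of planted intergenic enhancers.
#' @param seed Integer seed.
#' @return List: `atac`, `h3k27ac` (peak tibbles, 1-based inclusive),
#'   `expression` (boosted TPM matrix), `truth` (list with `peak_genes` and
#'   `enhancers` tibble of planted intersections).
#' @export
simulate_peaks <- function(ann, expr, peak_prob = 0.3, peak_boost = 1.5,
                           n_enhancers = 0, seed = 1) {
  if (peak_boost < 1) stopf("`peak_boost` must be >= 1")
  with_seed(seed, {
    n <- nrow(ann)
    has_atac <- runif(n) < peak_prob
    has_k27 <- runif(n) < peak_prob
    body_peak <- function(idx) {
      if (!length(idx)) {
        return(tibble(chrom = character(), start = integer(), end = integer()))
      }
      g <- ann[idx, ]
      width <- pmin(g$end - g$start + 1L, sample(300:800, length(idx), replace = TRUE))
      s <- g$start + floor(runif(length(idx)) * (g$end - g$start - width + 2))
      tibble(chrom = g$chrom, start = as.integer(s), end = as.integer(s + width - 1L))
    }
    atac <- body_peak(which(has_atac))
    k27 <- body_peak(which(has_k27))

    enh <- tibble(chrom = character(), start = integer(), end = integer())
    if (n_enhancers > 0) {
      gaps <- ann |>
        arrange(.data$chrom, .data$start) |>
        group_by(.data$chrom) |>
        transmute(gap_start = .data$end + 1L,
                  gap_end = dplyr::lead(.data$start) - 1L) |>
        ungroup() |>
        filter(!is.na(.data$gap_end), .data$gap_end - .data$gap_start > 3000)
      if (nrow(gaps) < n_enhancers) {
        stopf("only %d intergenic gaps wide enough for %d enhancers",
              nrow(gaps), n_enhancers)
      }
      gaps <- gaps[sample.int(nrow(gaps), n_enhancers), ]
      mid <- floor((gaps$gap_start + gaps$gap_end) / 2)
      k27_e <- tibble(chrom = gaps$chrom, start = as.integer(mid - 300L),
                      end = as.integer(mid + 299L))
      atac_e <- tibble(chrom = gaps$chrom, start = as.integer(mid),
                       end = as.integer(mid + 599L))
      enh <- tibble(chrom = gaps$chrom, start = as.integer(mid),
                    end = as.integer(mid + 299L))
      k27 <- bind_rows(k27, k27_e)
      atac <- bind_rows(atac, atac_e)
    }
    boosted <- expr
    hit <- rownames(expr) %in% ann$gene_id[has_atac | has_k27]
    boosted[hit, ] <- boosted[hit, ] * peak_boost
    list(
      atac = arrange(mutate(atac, assay = "ATAC"), .data$chrom, .data$start),
      h3k27ac = arrange(mutate(k27, assay = "H3K27ac"), .data$chrom, .data$start),
      expression = boosted,
      truth = list(atac_genes = ann$gene_id[has_atac],
                   h3k27ac_genes = ann$gene_id[has_k27],
                   peak_genes = ann$gene_id[has_atac | has_k27],
                   enhancers = enh)
    )
  })
}

#' Simulate a Hi-C contact matrix with power-law distance decay
#'
#' Intra-chromosomal expected contact between bins `i` and `j` is
#' `scale * (1 + |i - j|)^-decay_exponent`; counts are Poisson draws,
#' symmetrized. Inter-chromosomal contacts use a small constant mean.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width (bp).
#' @param decay_exponent Power-law decay exponent (> 0).
#' @param scale Expected contact at distance 0.
#' @param trans_mean Expected inter-chromosomal contact.
#' @param seed Integer seed.
#' @return A [contact_matrix()].
#' @export
simulate_hic <- function(chrom_lengths, bin_size = 5000, decay_exponent = 1,
                         scale = 100, trans_mean = 0.1, seed = 1) {
  if (decay_exponent <= 0) stopf("`decay_exponent` must be > 0")
  with_seed(seed, {
    nb <- pmax(1L, as.integer(ceiling(chrom_lengths / bin_size)))
    bins <- tibble(
      chrom = rep(names(chrom_lengths), nb),
      index = unlist(lapply(nb, function(k) seq_len(k) - 1L), use.names = FALSE)
    )
    n <- nrow(bins)
    same <- outer(bins$chrom, bins$chrom, "==")
    dist <- abs(outer(seq_len(n), seq_len(n), "-"))
    lambda <- ifelse(same, scale * (1 + dist)^(-decay_exponent), trans_mean)
    v <- matrix(0, n, n)
    up <- upper.tri(v, diag = TRUE)
    v[up] <- rpois(sum(up), lambda[up])
    v <- v + t(v) - diag(diag(v))
    contact_matrix(v, bin_size = bin_size, bins = bins)
  })
}

#' Simulate expression with planted co-expression modules
#'
#' Generates near-orthogonal module archetype profiles across tissues and
#' assigns `genes_per_module` genes per module as archetype plus Gaussian
#' noise, plus optional unstructured background genes. Values are shifted to
#' be non-negative by a linear transform, which leaves Pearson correlations
#' intact, so planted modules are recoverable by correlation-based
#' clustering.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes in each module.
#' @param n_tissues Tissues (>= n_modules recommended).
#' @param noise_sd Per-gene noise SD around the archetype.
#' @param n_background Unstructured extra genes.
#' @param seed Integer seed.
#' @return List: `expression` (matrix), `module_members` (named list of gene
#'   IDs per module).
#' @export
simulate_module_expression <- function(n_modules = 3, genes_per_module = 50,
                                       n_tissues = 8, noise_sd = 0.3,
                                       n_background = 0, seed = 1) {
  if (n_tissues < 3) stopf("`n_tissues` must be >= 3")
  with_seed(seed, {
    arch <- qr.Q(qr(matrix(rnorm(n_tissues * n_modules), n_tissues)))[, seq_len(n_modules), drop = FALSE]
    arch <- sqrt(n_tissues) * arch  # unit-variance-ish archetypes
    genes <- list()
    rows <- list()
    for (m in seq_len(n_modules)) {
      ids <- sprintf("mod%d_g%03d", m, seq_len(genes_per_module))
      x <- matrix(rep(arch[, m], each = genes_per_module), genes_per_module) +
        matrix(rnorm(genes_per_module * n_tissues, sd = noise_sd), genes_per_module)
      genes[[paste0("module", m)]] <- ids
      rows[[m]] <- x
    }
    x <- do.call(rbind, rows)
    ids <- unlist(genes, use.names = FALSE)
    if (n_background > 0) {
      bg <- matrix(rnorm(n_background * n_tissues), n_background)
      x <- rbind(x, bg)
      ids <- c(ids, sprintf("bg_g%03d", seq_len(n_background)))
    }
    expr <- pmax(x + 6, 0)
    dimnames(expr) <- list(ids, paste0("tissue", seq_len(n_tissues)))
    list(expression = expr, module_members = genes)
  })
}

#' Simulate metabolite accumulation correlated with planted modules
#'
#' The k-th metabolite tracks the eigengene of the k-th module with target
#' correlation `metabolite_module_r` (metabolite = r * eigengene +
#' sqrt(1-r^2) * noise, then linearly rescaled to positive accumulation
#' levels, which preserves Pearson correlation). Metabolites beyond the
#' number of modules are pure noise. Default names are the six catechins
#' GC, EGCG, ECG, EGC, EC, C.
#'
#' @param expr Genes x tissues expression matrix.
#' @param module_members Named list of gene IDs per module.
#' @param metabolite_module_r Target correlation in [0, 1].
#' @param n_metabolites Number of metabolites (default 6).
#' @param names Metabolite names.
#' @param seed Integer seed.
#' @return Metabolites x tissues numeric matrix.
#' @export
simulate_metabolites <- function(expr, module_members, metabolite_module_r = 0.9,
                                 n_metabolites = 6,
                                 names = c("GC", "EGCG", "ECG", "EGC", "EC", "C"),
                                 seed = 1) {
  if (abs(metabolite_module_r) > 1) stopf("`metabolite_module_r` must be in [-1,1]")
  nm <- names[seq_len(n_metabolites)]
  with_seed(seed, {
    nt <- ncol(expr)
    out <- matrix(NA_real_, n_metabolites, nt,
                  dimnames = list(nm, colnames(expr)))
    r <- metabolite_module_r
    for (k in seq_len(n_metabolites)) {
      noise <- as.numeric(scale(rnorm(nt)))
      if (k <= length(module_members)) {
        e <- module_eigengene(expr[module_members[[k]], , drop = FALSE])
        e <- as.numeric(scale(e))
        y <- r * e + sqrt(1 - r^2) * noise
      } else {
        y <- noise
      }
      out[k, ] <- 10 + 3 * y
    }
    out
  })
}
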