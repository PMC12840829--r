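#' Read gene models from a GFF3 annotation
#'
#' Parses features of type `gene` and returns one row per gene with 1-based
#' inclusive coordinates, in file order. All internal computation in this
#' package uses 1-based inclusive coordinates; only the BED boundary converts.
#'
#' @param path Path to a GFF3 file.
#' @param species Species name attached to every returned gene.
#' @return A tibble with columns `gene_id`, `species`, `chrom`, `start`,
#'   `end`, `strand`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=gA",
#'   "chr1\tsrc\tgene\t2000\t2500\t.\t-\t.\tID=gB"), gff)
#' read_annotation(gff, "toy")
#' @export
read_annotation <- function(path, species) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  if (length(gr) == 0) stopf("no features of type 'gene' in %s", path)
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  if (is.null(S4Vectors::mcols(gr)$ID) || anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))[1]
    stopf("gene record %d in %s has no ID attribute", if (length(bad)) bad else 1L, path)
  }
  ann <- tibble(
    gene_id = ids,
    species = species,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  ann$strand[ann$strand == "*"] <- "."
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  bad <- which(ann$start > ann$end)
  if (length(bad)) stopf("gene %s has start > end", ann$gene_id[bad[1]])
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) stopf("duplicate gene_id within species: %s", dup[1])
  invisible(ann)
}

#' Write gene models to GFF3
#'
#' @param ann Annotation tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  lines <- sprintf("%s\tsngco\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   ann$chrom, ann$start, ann$end, ann$strand, ann$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a tissue-by-gene TPM expression matrix
#'
#' @param path TSV with gene IDs in the first column and one column per
#'   tissue/sample of non-negative TPM values.
#' @return A numeric matrix, genes in rows (rownames), tissues in columns.
#' @export
read_expression <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal")
  if (any(!nzchar(names(tb)))) stopf("empty column header in %s", path)
  genes <- as.character(tb[[1]])
  if (anyDuplicated(genes)) {
    stopf("duplicate gene ID in expression table: %s", genes[duplicated(genes)][1])
  }
  m <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stopf("non-numeric or missing expression value in %s", path)
  if (any(m < 0)) stopf("negative expression value in %s", path)
  rownames(m) <- genes
  m
}

#' Write an expression (or metabolite) matrix to TSV
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the first column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  tb <- as_tibble(m, rownames = id_col)
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read a peak set from BED/narrowPeak
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' package's internal 1-based inclusive convention on read and converted back
#' by [write_peaks()]. Input need not be sorted; output is sorted by
#' (chrom, start).
#'
#' @param path BED or narrowPeak file.
#' @param assay Label, e.g. `"ATAC"` or `"H3K27ac"`.
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive), `assay`.
#' @export
read_peaks <- function(path, assay = "peak") {
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  pk <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    assay = assay
  )
  if (any(pk$end < pk$start)) stopf("malformed interval (end < start) in %s", path)
  arrange(pk, .data$chrom, .data$start, .data$end)
}

#' Write a peak set as BED (0-based half-open)
#' @param peaks Tibble from [read_peaks()] or the simulator.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d", peaks$chrom, peaks$start - 1L, peaks$end)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog pair table
#'
#' @param path TSV with columns `focal_gene`, `other_gene`, `species` and
#'   optionally `score`.
#' @return A tibble with those columns (`score` filled with `NA` if absent).
#' @export
read_orthologs <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("focal_gene", "other_gene", "species")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stopf("ortholog table missing column(s): %s", paste(miss, collapse = ", "))
  if (!"score" %in% names(tb)) tb$score <- NA_real_
  select(tb, dplyr::all_of(c(need, "score")))
}

#' Read a Hi-C contact matrix
#'
#' Accepts either a dense tab-separated matrix (optionally with bin IDs as
#' the first row/column) or a 3-column `bin_i bin_j value` triple list with
#' 0-based bin indices; triples are mirrored so the result is symmetric.
#'
#' @param path TSV file.
#' @param bin_size Bin width in bp.
#' @param bins Optional tibble (`chrom`, `index`) describing the genomic bin
#'   of each row; defaults to a single unnamed chromosome.
#' @return A `contact_matrix` object (see [contact_matrix()]).
#' @export
read_contacts <- function(path, bin_size = 5000, bins = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) == 3 && nrow(raw) > 0 && !anyNA(suppressWarnings(as.numeric(raw[[1]])))) {
    i <- as.integer(raw[[1]]); j <- as.integer(raw[[2]]); v <- as.numeric(raw[[3]])
    if (any(v < 0)) stopf("negative contact value in %s", path)
    n <- max(i, j) + 1L
    m <- matrix(0, n, n)
    m[cbind(i + 1L, j + 1L)] <- v
    m[cbind(j + 1L, i + 1L)] <- v
  } else {
    m <- as.matrix(raw)
    storage.mode(m) <- "double"
    if (nrow(m) != ncol(m)) stopf("dense contact matrix in %s is not square", path)
    if (any(m < 0)) stopf("negative contact value in %s", path)
    if (max(abs(m - t(m))) > 1e-8) stopf("dense contact matrix in %s is not symmetric", path)
  }
  dimnames(m) <- NULL
  contact_matrix(m, bin_size = bin_size, bins = bins)
}

#' Construct a contact matrix object
#'
#' @param values Square symmetric non-negative numeric matrix.
#' @param bin_size Bin width in bp.
#' @param bins Tibble with one row per matrix row: `chrom`, `index` (0-based
#'   bin index within the chromosome). Defaults to one chromosome.
#' @return An object of class `contact_matrix`: list with `values`,
#'   `bin_size`, `bins`.
#' @export
contact_matrix <- function(values, bin_size = 5000, bins = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(values < 0)) stopf("contact matrix must be non-negative")
  if (max(abs(values - t(values))) > 1e-8) stopf("contact matrix must be symmetric")
  if (is.null(bins)) {
    bins <- tibble(chrom = "chr1", index = seq_len(nrow(values)) - 1L)
  }
  stopifnot(nrow(bins) == nrow(values))
  structure(list(values = values, bin_size = bin_size, bins = as_tibble(bins)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins of %d bp over %d chromosome(s)\n",
              nrow(x$values), x$bin_size, length(unique(x$bins$chrom))))
  invisible(x)
}

#' Write / read pair records
#'
#' `write_records()` and `read_pairs_table()` round-trip a pair-record tibble
#' through TSV without loss (full double precision is written).
#'
#' @param records Tibble of pair records.
#' @param path TSV path.
#' @return `read_pairs_table()` returns the tibble; `write_records()` returns
#'   `path` invisibly.
#' @export
write_records <- function(records, path) {
  # doubles are serialized at full precision so the TSV round-trips bit-exactly
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::where(~ is.double(.x) && !inherits(.x, "integer64")),
    ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_records
#' @export
read_pairs_table <- function(path) {
  # read.table parses doubles via strtod (correctly rounded), preserving the
  # bit-exact round-trip contract that approximate float parsers break
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE))
}

#' Write an analysis report as JSON
#' @param report Named list of results (numbers, tables as data frames).
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
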