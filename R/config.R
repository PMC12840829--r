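#' Pipeline configuration
#'
#' Bundles every threshold and replicate count the pipeline uses, with the
#' defaults of the analysis it implements: co-expression is Pearson r > 0.5
#' across tissues; intergenic distance is binned at 8 kb and 50 kb; mean gene
#' length at 5.5 kb and 9 kb; the randomization null uses 10,000 iterations,
#' bootstrap standard errors 1000, and the logistic model 50 repeats of a
#' stratified 80/20 split. Hi-C contacts are read at 5-kb bins and promoters
#' extend 2 kb upstream of the TSS.
#'
#' @param coexpr_threshold Pearson correlation above which a pair is called
#'   co-expressed.
#' @param distance_edges Strictly increasing intergenic-distance bin edges (bp).
#' @param length_edges Strictly increasing mean-gene-length bin edges (bp).
#' @param n_randomization Iterations for the randomization null.
#' @param n_bootstrap Bootstrap resamples for proportion standard errors.
#' @param n_model_repeats Repeats of the balanced train/test modelling loop.
#' @param train_fraction Fraction of pairs used for training, in (0, 1).
#' @param hic_bin Hi-C bin width in bp.
#' @param promoter_window Upstream promoter window in bp.
#' @param seed Integer seed used for every stochastic stage.
#' @return An object of class `sng_config` (a validated named list).
#' @examples
#' cfg <- sng_config(seed = 1)
#' cfg$distance_edges
#' @export
sng_config <- function(coexpr_threshold = 0.5,
                       distance_edges = c(8000, 50000),
                       length_edges = c(5500, 9000),
                       n_randomization = 10000,
                       n_bootstrap = 1000,
                       n_model_repeats = 50,
                       train_fraction = 0.8,
                       hic_bin = 5000,
                       promoter_window = 2000,
                       seed = 1L) {
  cfg <- list(
    coexpr_threshold = coexpr_threshold,
    distance_edges = as.numeric(distance_edges),
    length_edges = as.numeric(length_edges),
    n_randomization = n_randomization,
    n_bootstrap = n_bootstrap,
    n_model_repeats = n_model_repeats,
    train_fraction = train_fraction,
    hic_bin = hic_bin,
    promoter_window = promoter_window,
    seed = as.integer(seed)
  )
  for (nm in c("n_randomization", "n_bootstrap", "n_model_repeats", "hic_bin")) {
    if (!is_count(cfg[[nm]])) stopf("`%s` must be a positive integer, got %s", nm, cfg[[nm]])
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("`train_fraction` must lie in (0,1), got %s", train_fraction)
  }
  for (nm in c("distance_edges", "length_edges")) {
    e <- cfg[[nm]]
    if (length(e) < 1 || any(diff(e) <= 0) || any(e < 0)) {
      stopf("`%s` must be non-negative and strictly increasing", nm)
    }
  }
  if (promoter_window < 0) stopf("`promoter_window` must be >= 0")
  structure(cfg, class = "sng_config")
}

#' @export
print.sng_config <- function(x, ...) {
  cat("<sng_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Read a pipeline configuration from JSON or key=value text
#'
#' Keys mirror the arguments of [sng_config()]; unknown keys are an error.
#'
#' @param path Path to a `.json` file or a flat `key=value` text file.
#' @return An `sng_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) stopf("malformed config line: %s", lines[which(bad)[1]])
    vals <- lapply(kv, function(p) {
      v <- strsplit(trimws(p[2]), ",")[[1]]
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) v else num
    })
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  unknown <- setdiff(names(vals), names(formals(sng_config)))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(sng_config, vals)
}

#' Write the resolved configuration (provenance record) to a directory
#'
#' Every pipeline run records the full resolved configuration, including the
#' seed, so results can be reproduced from the output directory alone.
#'
#' @param config An `sng_config`.
#' @param outdir Output directory (created if needed).
#' @param input_paths Optional named character vector of input files; their
#'   md5 hashes are recorded alongside.
#' @return The path of the written JSON, invisibly.
#' @export
write_config <- function(config, outdir, input_paths = NULL) {
  stopifnot(inherits(config, "sng_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rec <- unclass(config)
  if (!is.null(input_paths)) {
    rec$input_md5 <- vapply(input_paths, function(p) unname(tools::md5sum(p)), "")
  }
  path <- file.path(outdir, "config.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
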