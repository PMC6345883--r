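#' Construct a validated count matrix
#'
#' A count matrix holds non-negative integer read counts for features
#' (genes, transcripts or exons) in rows and samples in columns. Row and
#' column names are mandatory and must be unique; they are the feature and
#' sample identifiers used throughout the pipeline.
#'
#' @param counts numeric matrix of non-negative integers with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param feature_level one of `"gene"`, `"transcript"`, `"exon"`; the
#'   quantification level the rows represent.
#' @return an integer matrix of class `count_matrix` with a
#'   `feature_level` attribute.
#' @export
count_matrix <- function(counts, feature_level = c("gene", "transcript", "exon")) {
  feature_level <- match.arg(feature_level)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  validate_count_matrix(counts)
  storage.mode(counts) <- "integer"
  structure(counts, feature_level = feature_level,
            class = c("count_matrix", class(counts)))
}

validate_count_matrix <- function(counts) {
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("count matrix must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf("invalid count %s at feature '%s', sample '%s' (must be a finite non-negative integer)",
                 format(counts[bad[1]]), rownames(counts)[i[1]], colnames(counts)[i[2]]))
  }
  invisible(counts)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a count matrix from a delimited text file
#'
#' The file must have a header row of sample ids and a first column of
#' feature ids; tab- and comma-separated dialects are auto-detected.
#' Non-integer numeric entries (e.g. FPKM-like values) are rejected unless
#' `round_counts = TRUE`, in which case they are rounded half-up with a
#' warning -- the model is a count model and requires integers.
#'
#' @param path path to a TSV/CSV file.
#' @param feature_level quantification level of the rows.
#' @param round_counts round non-integer entries half-up instead of erroring.
#' @return a [count_matrix].
#' @export
read_counts <- function(path, feature_level = c("gene", "transcript", "exon"),
                        round_counts = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  feature_level <- match.arg(feature_level)
  df <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                          row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    j <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric entries in column '", colnames(df)[j], "'")
  }
  nonint <- is.finite(m) & m != floor(m)
  if (any(nonint)) {
    if (!round_counts) {
      i <- arrayInd(which(nonint)[1], dim(m))
      stop(sprintf("non-integer value %s at feature '%s', sample '%s'; set round_counts = TRUE to round half-up",
                   format(m[nonint][1]), rownames(m)[i[1]], colnames(m)[i[2]]))
    }
    warning(sum(nonint), " non-integer entries rounded half-up")
    m <- floor(m + 0.5)
  }
  count_matrix(m, feature_level)
}

#' Write a count matrix to a tab-separated file
#'
#' @param cm a [count_matrix] (or plain integer matrix with dimnames).
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated sample table
#'
#' Per-sample metadata for a longitudinal design: the biological individual
#' (`subject_id`), the ordered `time_point`, the sequencing `lane` and
#' `batch`, and the `tech_rep_group` shared by all technical replicates of
#' one biological sample. Every `tech_rep_group` must map to exactly one
#' `(subject_id, time_point)` pair and at least two time points must be
#' present.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`,
#'   `time_point`, `lane`, `batch`, `tech_rep_group` (and optionally
#'   `excluded`, defaulting to `FALSE`).
#' @param time_levels character vector giving the time-point order. Labels
#'   such as `"D14"` sort before `"D3"` lexically, so supply this whenever
#'   the labels are not lexically ordered; the lexical fallback warns when
#'   it detects that case.
#' @return a data.frame of class `sample_table` with `time_point` an
#'   ordered factor.
#' @export
sample_table <- function(df, time_levels = NULL) {
  required <- c("sample_id", "subject_id", "time_point", "lane", "batch",
                "tech_rep_group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)

  tp <- as.character(df$time_point)
  if (is.null(time_levels)) {
    time_levels <- sort(unique(tp))
    num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", time_levels)))
    if (!anyNA(num) && is.unsorted(num))
      warning("lexical time-point order ", paste(time_levels, collapse = " < "),
              " disagrees with the numeric suffixes; supply time_levels explicitly")
  } else {
    unknown <- setdiff(unique(tp), time_levels)
    if (length(unknown))
      stop("time_point value(s) not in time_levels: ", paste(unknown, collapse = ", "))
  }
  df$time_point <- factor(tp, levels = time_levels, ordered = TRUE)
  if (nlevels(droplevels(df$time_point)) < 2)
    stop("at least two distinct time points are required")

  key <- paste(df$subject_id, df$time_point, sep = "\r")
  split_keys <- tapply(key, df$tech_rep_group, function(x) length(unique(x)))
  bad <- names(split_keys)[split_keys > 1]
  if (length(bad))
    stop("tech_rep_group(s) spanning more than one (subject, time point): ",
         paste(bad, collapse = ", "))
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from a delimited text file
#'
#' @inheritParams sample_table
#' @param path path to a TSV/CSV file with the six named metadata columns.
#' @return a [sample_table].
#' @export
read_sample_table <- function(path, time_levels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (!is.null(df$excluded)) df$excluded <- toupper(df$excluded) %in% c("TRUE", "T", "1")
  sample_table(df, time_levels = time_levels)
}

#' Write a sample table
#' @param st a [sample_table].
#' @param path output path.
#' @export
write_sample_table <- function(st, path) {
  out <- as.data.frame(st)
  out$time_point <- as.character(out$time_point)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

result_columns <- c("feature_id", "comparison_label", "phi_mean", "phi_sd",
                    "phi_ci_low", "phi_ci_high", "tail_pos", "tail_neg",
                    "null_mass", "de_call", "direction", "convergence_flag")

#' Write a differential expression result table
#'
#' Tab-separated, one row per feature, fixed column order, floating values
#' at 6 significant digits. [read_results()] round-trips losslessly at that
#' precision.
#'
#' @param results the `results` data.frame of an [fit_pairwise_ar()] fit
#'   (or the fit object itself).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "ar_fit")) results <- results$results
  missing_cols <- setdiff(result_columns, names(results))
  if (length(missing_cols))
    stop("result table is missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- results[, result_columns, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path path to the TSV file.
#' @return a data.frame with the fixed result columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Bundles the pipeline-level settings: MCMC length (10,000 iterations with
#' 8,000 burn-in by default), the tail-probability cutoff for differential
#' expression calls (0.1), the number of unwanted-variation factors, the
#' normalization method tag and the outlier median-correlation threshold.
#'
#' @param mcmc_iterations total MCMC iterations per feature.
#' @param burn_in iterations discarded (and used for step-size adaptation).
#' @param tail_cutoff tail-probability cutoff in (0, 0.5).
#' @param rng_seed integer seed.
#' @param n_unwanted_factors number of nuisance covariates `k`.
#' @param normalization normalization method tag.
#' @param outlier_threshold median-correlation threshold for outlier flags.
#' @return a list of class `run_config`.
#' @export
run_config <- function(mcmc_iterations = 10000L, burn_in = 8000L,
                       tail_cutoff = 0.1, rng_seed = 1L,
                       n_unwanted_factors = 1L,
                       normalization = "median-of-ratios",
                       outlier_threshold = 0.7) {
  mcmc_iterations <- as.integer(mcmc_iterations)
  burn_in <- as.integer(burn_in)
  if (mcmc_iterations <= 0L) stop("mcmc_iterations must be positive")
  if (burn_in < 0L || burn_in >= mcmc_iterations)
    stop("burn_in must satisfy 0 <= burn_in < mcmc_iterations")
  if (!(tail_cutoff > 0 && tail_cutoff < 0.5))
    stop("tail_cutoff must lie in (0, 0.5)")
  if (n_unwanted_factors < 0L) stop("n_unwanted_factors must be >= 0")
  structure(list(mcmc_iterations = mcmc_iterations, burn_in = burn_in,
                 tail_cutoff = tail_cutoff, rng_seed = as.integer(rng_seed),
                 n_unwanted_factors = as.integer(n_unwanted_factors),
                 normalization = normalization,
                 outlier_threshold = outlier_threshold),
            class = "run_config")
}

#' Read a run configuration from a YAML key/value file
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
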