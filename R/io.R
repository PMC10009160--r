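# On-disk layout: one delimited matrix per muscle (samples x channels), one
# force file, and a JSON manifest binding them together with the sampling
# rate — plus, for synthetic data, the generative weights and seed so the
# manifest doubles as the oracle for recovery tests.

#' Write a dataset in the delimited layout
#'
#' Writes `emg_<muscle>.csv` per muscle, `force.csv`, and `manifest.json`
#' carrying fs, the muscle-to-file mapping, and (for synthetic data) the
#' ground-truth weights and seed.
#'
#' @param dataset a `SyntheticDataset`, or any list with `emg` (list of
#'   [signalMatrix()]), `force` and optionally `config`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- samplingRate(dataset$force)
  muscles <- lapply(dataset$emg, function(sig) {
    id <- muscleId(sig)
    fn <- paste0("emg_", id, ".csv")
    utils::write.table(format(unclass(sig), digits = 17, trim = TRUE),
                       file.path(dir, fn), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    list(id = id, file = fn, n_channels = ncol(sig))
  })
  utils::write.table(format(unclass(dataset$force), digits = 17, trim = TRUE),
                     file.path(dir, "force.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  manifest <- list(fs = fs, muscles = muscles, force_file = "force.csv")
  if (!is.null(dataset$config)) {
    manifest$true_weights <- dataset$config$true_weights
    manifest$seed <- dataset$config$seed
    manifest$noise_sd <- dataset$config$noise_sd
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# strict numeric CSV reader with cell-level error context
readNumericCsv <- function(path) {
  if (!file.exists(path)) stop("missing data file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  bad <- which(is.na(m) & as.matrix(raw) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: non-numeric value '%s' at row %d, column %d",
                 path, as.matrix(raw)[bad[1L, 1L], bad[1L, 2L]],
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  if (anyNA(m))
    stop(path, ": missing values in signal matrix", call. = FALSE)
  m
}

#' Read a dataset from the delimited layout
#'
#' @param dir directory containing `manifest.json` and the referenced CSVs.
#' @return A list with `emg` (per-muscle [signalMatrix()]), `force`, and
#'   when present in the manifest, `true_weights` and `seed`.
#' @export
readDataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (is.null(mf$fs) || mf$fs <= 0) stop("manifest has no valid fs", call. = FALSE)
  emg <- lapply(mf$muscles, function(mu) {
    m <- readNumericCsv(file.path(dir, mu$file))
    if (!is.null(mu$n_channels) && ncol(m) != mu$n_channels)
      stop(sprintf("%s: expected %d channels, found %d",
                   mu$file, mu$n_channels, ncol(m)), call. = FALSE)
    signalMatrix(m, mf$fs, muscle_id = mu$id)
  })
  fm <- readNumericCsv(file.path(dir, mf$force_file))
  if (ncol(fm) != 1L) stop("force file must have exactly one column", call. = FALSE)
  lens <- vapply(emg, nrow, integer(1))
  if (any(lens != nrow(fm)))
    stop("sEMG and force files have different sample counts", call. = FALSE)
  out <- list(emg = emg, force = signalMatrix(fm, mf$fs))
  if (!is.null(mf$true_weights)) out$true_weights <- unlist(mf$true_weights)
  if (!is.null(mf$seed)) out$seed <- mf$seed
  out
}

#' Read a run configuration (JSON or YAML)
#'
#' Light schema validation: unknown top-level keys are rejected, known keys
#' are type-checked before any computation runs.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("data_dir", "synthetic", "models", "split_fractions",
               "split_scheme", "envelope_cutoff_hz", "bandpass",
               "pso", "ridge_lambda", "svr_cost_grid", "ann_hidden",
               "seed", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$split_fractions)) {
    cfg$split_fractions <- as.numeric(cfg$split_fractions)
    if (abs(sum(cfg$split_fractions) - 1) > 1e-9)
      stop("split_fractions must sum to 1", call. = FALSE)
  }
  if (!is.null(cfg$models) && !all(cfg$models %in% modelRoster()))
    stop("unknown model families in config", call. = FALSE)
  cfg
}
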