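# Cohort persistence: one binary array container (IEEE doubles, little
# endian, subjects x pairs x frequencies in column-major order) plus a
# JSON header with dimensions/seed and a CSV sidecar with per-subject
# metadata. The round trip is lossless to the bit.

#' Save a cohort to disk
#'
#' Writes `<path>.bin` (stacked magnitudes), `<path>.json` (dimensions,
#' seed, endianness) and `<path>.csv` (subject_id, label, optional split
#' assignment).
#'
#' @param cohort A `cohort_dataset`.
#' @param path Path prefix (without extension).
#' @param split Optional [split_dataset()] assignment to record.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path, split = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  arr <- cohort_array(cohort)
  header <- list(dims = dim(arr), seed = cohort$seed,
                 endian = "little", dtype = "float64",
                 frequencies = as.numeric(cohort$grid),
                 liver_weight = cohort$geometry$liver_weight,
                 n_electrodes = cohort$geometry$n_electrodes)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(arr), con, size = 8L, endian = "little")
  meta <- data.frame(subject_id = cohort$subject_ids,
                     label = cohort$labels,
                     stringsAsFactors = FALSE)
  if (!is.null(split)) meta$split <- split$assignment
  utils::write.csv(meta, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Load a cohort from disk
#'
#' Validates the binary payload size against the header before reading;
#' a truncated or oversized file raises a parse error naming the
#' offending file rather than silently truncating.
#'
#' @param path Path prefix used in [save_cohort()].
#' @return A `cohort_dataset` equal (bitwise magnitudes, equal metadata)
#'   to the saved one. Phase spectra are not persisted.
#' @export
load_cohort <- function(path) {
  hfile <- paste0(path, ".json")
  bfile <- paste0(path, ".bin")
  cfile <- paste0(path, ".csv")
  for (f in c(hfile, bfile, cfile)) {
    if (!file.exists(f)) stop("missing cohort file: ", f, call. = FALSE)
  }
  header <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  dims <- as.integer(header$dims)
  expected <- 8 * prod(dims)
  actual <- file.info(bfile)$size
  if (actual != expected) {
    stop("corrupt cohort payload ", bfile, ": expected ", expected,
         " bytes for dims ", paste(dims, collapse = "x"), ", found ",
         actual, call. = FALSE)
  }
  meta <- utils::read.csv(cfile, stringsAsFactors = FALSE)
  if (nrow(meta) != dims[1L]) {
    stop("corrupt cohort metadata ", cfile, ": ", nrow(meta),
         " rows for ", dims[1L], " subjects", call. = FALSE)
  }
  con <- file(bfile, "rb")
  on.exit(close(con), add = TRUE)
  arr <- array(readBin(con, "double", n = prod(dims), size = 8L,
                       endian = "little"), dims)
  geometry <- sensor_geometry(header$n_electrodes,
                              liver_weight = header$liver_weight)
  grid <- structure(as.numeric(header$frequencies),
                    class = c("frequency_grid", "numeric"))
  matrices <- lapply(seq_len(dims[1L]), function(i) {
    structure(list(magnitudes = arr[i, , ], phase = NULL,
                   label = meta$label[i], subject_id = meta$subject_id[i]),
              class = "impedance_matrix")
  })
  structure(list(matrices = matrices, labels = meta$label,
                 subject_ids = meta$subject_id,
                 seed = as.integer(header$seed),
                 geometry = geometry, grid = grid),
            class = "cohort_dataset")
}

#' Write an evaluation report as JSON (with ROC as CSV)
#'
#' @param report An `eval_report`.
#' @param path Path prefix; writes `<path>.json` and `<path>_roc.csv`.
#' @param config Optional configuration list echoed into the JSON for
#'   provenance.
#' @return `path`, invisibly.
#' @export
save_eval_report <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(partition = report$partition, n = report$n,
              accuracy = report$accuracy, auc = report$auc,
              confusion = unclass(report$confusion),
              misclassification = as.list(report$misclassification),
              threshold = report$threshold,
              subject_ids = report$subject_ids,
              scores = report$scores, labels = report$labels)
  if (!is.null(config)) out$config <- config
  jsonlite::write_json(out, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(report$roc, paste0(path, "_roc.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read or write an experiment configuration file
#'
#' Configurations are nested key/value structures stored as YAML.
#'
#' @param config Nested list (see [experiment_config()]).
#' @param path File path.
#' @return For `write_config`, `path` invisibly; for `read_config`, the
#'   configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
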