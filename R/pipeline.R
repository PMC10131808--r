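# I/O and orchestration: CSV record reading/writing with channel mapping,
# cohort manifests, resampling, flat key-value configs, and the end-to-end
# extract -> train -> evaluate pipeline.

#' Read one multichannel record from CSV
#'
#' The file is samples x channels with a header of channel names. Columns
#' are reordered to the canonical preset order; `mapping` (canonical label ->
#' file column name) handles non-canonical headers. Non-finite samples are
#' repaired by linear interpolation with a message.
#'
#' @param path CSV file path.
#' @param preset `"nox12"` or `"porti6"`.
#' @param mapping optional named character vector, names = canonical labels,
#'   values = column names in the file.
#' @param record_id,patient_id,institution,stage record metadata (stage may
#'   be NA for inference-only records).
#' @return a [MultichannelRecord-class].
#' @export
readRecord <- function(path, preset = c("nox12", "porti6"), mapping = NULL,
                       record_id = basename(path), patient_id = "unknown",
                       institution = "unknown", stage = NA_integer_) {
  preset <- match.arg(preset)
  if (!file.exists(path)) stop("cannot read record file: ", path)
  df <- read.csv(path, check.names = FALSE)
  want <- channelPreset(preset)
  cols <- if (is.null(mapping)) setNames(want, want)
          else setNames(as.character(mapping[want]), want)
  missing <- want[!(cols %in% names(df))]
  if (length(missing))
    stop("missing channel(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  M <- t(as.matrix(df[, cols[want]]))
  bad <- !is.finite(M)
  if (any(bad)) {
    message(sum(bad), " non-finite sample(s) repaired by linear interpolation")
    for (i in which(rowSums(bad) > 0)) {
      ok <- which(is.finite(M[i, ]))
      M[i, ] <- approx(ok, M[i, ok], xout = seq_len(ncol(M)),
                       rule = 2)$y
    }
  }
  dimnames(M) <- NULL
  new("MultichannelRecord", data = M, channels = want,
      recordId = record_id, patientId = patient_id,
      institution = institution, stage = as.integer(stage),
      samplingNote = "nominal")
}

#' Write a record to CSV (samples x channels)
#'
#' @param record a [MultichannelRecord-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRecordCsv <- function(record, path) {
  df <- as.data.frame(t(recordData(record)))
  names(df) <- channelLabels(record)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to disk with a manifest
#'
#' One CSV per record plus `manifest.csv` with columns record_id,
#' patient_id, institution, stage, path.
#'
#' @param records list of [MultichannelRecord-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    p <- file.path(dir, paste0(r@recordId, ".csv"))
    writeRecordCsv(r, p)
    data.frame(record_id = r@recordId, patient_id = patientId(r),
               institution = institution(r), stage = copdStage(r),
               path = p, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Resample every channel of a record to a fixed length
#'
#' Linear interpolation onto `target_len` equally spaced points. A record
#' already at the target length is returned unchanged (idempotent); a
#' shorter record is an error.
#'
#' @param record a [MultichannelRecord-class].
#' @param target_len output samples per channel.
#' @return resampled [MultichannelRecord-class] (samplingNote "resampled").
#' @export
resampleRecord <- function(record, target_len = 6000L) {
  X <- recordData(record)
  T <- ncol(X)
  if (T == target_len) return(record)
  if (T < target_len)
    stop("record shorter than target length (", T, " < ", target_len,
         "); pad the record upstream instead")
  grid <- seq(1, T, length.out = target_len)
  Y <- t(apply(X, 1L, function(ch) approx(seq_len(T), ch, xout = grid)$y))
  new("MultichannelRecord", data = Y, channels = channelLabels(record),
      recordId = record@recordId, patientId = patientId(record),
      institution = institution(record), stage = copdStage(record),
      samplingNote = "resampled")
}

#' Read a flat key = value configuration file
#'
#' Lines of `key = value`; blank lines and `#` comments ignored; values
#' parsed as numbers where possible.
#'
#' @param path config file.
#' @return named list.
#' @export
readConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1L], collapse = "="))
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  names(out) <- vapply(kv, function(x) trimws(x[1L]), character(1))
  out
}

.configHash <- function(config) {
  tmp <- tempfile()
  writeLines(paste(names(config), vapply(config, paste, character(1),
                                         collapse = ","), sep = "="), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

#' Run the full staging pipeline from a cohort manifest
#'
#' For each manifest row: read the record, resample to `target_len` when
#' longer, and extract the flattened coupling-matrix feature; then assemble
#' the staged dataset and evaluate under the configured protocol(s).
#' Per-record failures are skipped with a logged reason; more than 20%
#' skips aborts the run. Outputs (features CSV, JSON report, run log with
#' seed and config hash) go to `out_dir`; re-running into the same directory
#' with a different config refuses to overwrite unless `force = TRUE`.
#'
#' @param manifest path to a manifest CSV (see [writeCohort()]).
#' @param config named list (or path to a [readConfig()] file). Recognized
#'   keys: `preset` ("nox12"/"porti6"), `protocol` ("kfold", "holdout"),
#'   `k`, `group_by`, `holdout_institution`, `balance`, `epochs`, `seed`,
#'   `lr`, `p`, `target_len`.
#' @param out_dir artifacts directory; `NULL` disables file output.
#' @param force overwrite artifacts produced under a different config.
#' @return list with `dataset` ([StagedDataset-class]), `report`
#'   ([EvalReport-class]) and `skipped` (character log of skipped records).
#' @export
runPipeline <- function(manifest, config = list(), out_dir = NULL,
                        force = FALSE) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- modifyList(list(preset = "nox12", protocol = "kfold", k = 5,
                         group_by = "per_record", holdout_institution = "VB",
                         balance = "none", epochs = 100, seed = 1,
                         lr = 0.001, p = 0, target_len = 6000), config)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  skipped <- character(0)
  records <- list()
  for (i in seq_len(nrow(man))) {
    rec <- tryCatch({
      r <- readRecord(man$path[i], preset = cfg$preset,
                      record_id = man$record_id[i],
                      patient_id = man$patient_id[i],
                      institution = man$institution[i],
                      stage = man$stage[i])
      if (ncol(recordData(r)) > cfg$target_len)
        r <- resampleRecord(r, cfg$target_len)
      r
    }, error = function(e) {
      skipped <<- c(skipped, paste0(man$record_id[i], ": ",
                                    conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(skipped) > 0.2 * nrow(man))
    stop("more than 20% of records failed: aborting\n",
         paste(skipped, collapse = "\n"))
  dataset <- buildStagedDataset(records, preset = cfg$preset,
                                p = as.integer(cfg$p))
  spec <- netSpec(ncol(featureMatrix(dataset)),
                  learning_rate = cfg$lr, epochs = as.integer(cfg$epochs),
                  seed = as.integer(cfg$seed))
  report <- if (cfg$protocol == "holdout")
    holdoutEval(dataset, cfg$holdout_institution, spec = spec,
                balance = cfg$balance, seed = as.integer(cfg$seed))
  else
    kfoldEval(dataset, k = as.integer(cfg$k), grouping = cfg$group_by,
              spec = spec, seed = as.integer(cfg$seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- .configHash(cfg)
    hfile <- file.path(out_dir, "config_hash.txt")
    if (file.exists(hfile) && !identical(readLines(hfile)[1L], hash) &&
        !force)
      stop("out_dir holds artifacts from a different config; use force = TRUE")
    writeLines(hash, hfile)
    fdf <- data.frame(record_id = dataset@recordIds,
                      patient_id = dataset@patientIds,
                      institution = dataset@institutions,
                      stage = dataset@labels,
                      featureMatrix(dataset), check.names = FALSE)
    names(fdf)[-(1:4)] <- paste0("f_", seq_len(ncol(featureMatrix(dataset))) - 1L)
    write.csv(fdf, file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(protocol = report@protocol,
           accuracy_mean = report@accuracyMean,
           accuracy_sd = report@accuracySd,
           auroc = report@auroc,
           misclassified_fraction = report@misclassifiedFraction,
           confusion = unclass(report@confusion),
           per_class = unclass(report@perClass),
           config_hash = hash, seed = cfg$seed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(paste("config hash:", hash),
                 paste("seed:", cfg$seed),
                 paste("records:", length(records)),
                 paste("skipped:", length(skipped)),
                 skipped),
               file.path(out_dir, "run_log.txt"))
  }
  list(dataset = dataset, report = report, skipped = skipped)
}
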