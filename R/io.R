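#' @include behavior.R
NULL

## TSV with '# key: value' comment metadata. Times are stored in seconds,
## activities in kBq/mL; the in-memory representation uses minutes.

writeMeta <- function(con, meta) {
  for (nm in names(meta)) cat(sprintf("# %s: %s\n", nm, meta[[nm]]), file = con)
}

readMeta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Read and write framed TAC tables
#'
#' Tab-separated tables with commented header metadata; columns
#' \code{frame_start_s}, \code{frame_end_s}, then one activity column
#' (kBq/mL) per region.
#'
#' @param tacs A \linkS4class{TimeActivityCurve}.
#' @param path File path.
#' @return \code{readTacTable} returns a \linkS4class{TimeActivityCurve};
#'   \code{writeTacTable} returns \code{path} invisibly.
#' @export
writeTacTable <- function(tacs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeMeta(con, list(format = "fpetdopa TAC", time_unit = "s",
                      activity_unit = "kBq/mL"))
  df <- data.frame(frame_start_s = frameStart(tacs) * 60,
                   frame_end_s = frameEnd(tacs) * 60,
                   activity(tacs), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTacTable
#' @export
readTacTable <- function(path) {
  if (!file.exists(path)) stop("TAC table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  act <- as.matrix(df[, -(1:2), drop = FALSE])
  TimeActivityCurve(frameStart = df$frame_start_s / 60,
                    frameEnd = df$frame_end_s / 60, activity = act)
}

#' Read and write blood sample tables
#'
#' Tab-separated with columns \code{time_s}, \code{wholeblood_kBq_per_mL},
#' \code{plasma_kBq_per_mL}. The in-memory form is a data frame with
#' \code{time} (minutes), \code{whole_blood}, \code{plasma}.
#'
#' @param samples Data frame (\code{time}, \code{whole_blood}, \code{plasma}).
#' @param path File path.
#' @return \code{readBloodTable} returns the samples data frame.
#' @export
writeBloodTable <- function(samples, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeMeta(con, list(format = "fpetdopa blood samples", time_unit = "s",
                      activity_unit = "kBq/mL"))
  utils::write.table(
    data.frame(time_s = samples$time * 60,
               wholeblood_kBq_per_mL = samples$whole_blood,
               plasma_kBq_per_mL = samples$plasma),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBloodTable
#' @export
readBloodTable <- function(path) {
  if (!file.exists(path)) stop("blood table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  data.frame(time = df$time_s / 60, whole_blood = df$wholeblood_kBq_per_mL,
             plasma = df$plasma_kBq_per_mL)
}

#' Read and write motion-parameter tables
#'
#' Six columns (three translations in mm, three rotations in radians), one
#' row per frame, tab-separated.
#'
#' @param motion Matrix or data frame, frames x 6.
#' @param path File path.
#' @return \code{readMotionTable} returns a numeric matrix.
#' @export
writeMotionTable <- function(motion, path) {
  motion <- as.matrix(motion)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  con <- file(path, "w"); on.exit(close(con))
  writeMeta(con, list(format = "fpetdopa motion parameters",
                      units = "mm, rad"))
  utils::write.table(motion, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeMotionTable
#' @export
readMotionTable <- function(path) {
  if (!file.exists(path)) stop("motion table not found: ", path)
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#"))
}

#' Read and write MID trial logs
#'
#' Comma-separated trial logs as produced by
#' \code{\link{simulateMidSession}}.
#'
#' @param trialLog Trial log data frame.
#' @param path File path.
#' @return \code{readTrialLog} returns the data frame.
#' @export
writeTrialLog <- function(trialLog, path) {
  utils::write.csv(trialLog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrialLog
#' @export
readTrialLog <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path)
  utils::read.csv(path)
}

#' Write the ground-truth sidecar of a simulated session
#'
#' @param truth List of ground-truth values (per region and globally).
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the quantification results table
#'
#' One row per target region with baseline Ki, condition Ki (weighted and
#' unweighted), percent signal change and block weights.
#'
#' @param results Result list from \code{\link{runQuantification}}.
#' @param path TSV path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeMeta(con, list(format = "fpetdopa results", Ki_unit = "1/min",
                      PSC_unit = "percent",
                      config_hash = results$provenance$configHash))
  utils::write.table(results$table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
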