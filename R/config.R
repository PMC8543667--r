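#' @include io.R
NULL

#' Run configuration for simulation and quantification
#'
#' Bundles the acquisition and analysis constants: frame schedule, task
#' block timing, administration protocol, Patlak start time, filter cutoff,
#' blood volume fraction, region roles and the seed. Defaults equal the
#' protocol constants used throughout: 20:80 bolus:infusion, 60-s frames
#' over 50 min, blocks at 10/20/30/40 min lasting 5 min, t* = 25 min,
#' 2.5-min filter cutoff, 5\% blood volume.
#'
#' @slot frameLengthMin Frame length, minutes.
#' @slot scanDuration Scan duration, minutes.
#' @slot task A \linkS4class{TaskSchedule}.
#' @slot admin An \linkS4class{AdministrationSchedule}.
#' @slot tStar Patlak window start, minutes.
#' @slot filterCutoff Low-pass cutoff period, minutes.
#' @slot vB Whole-blood volume fraction.
#' @slot seed Integer seed for the simulator.
#' @slot targetRegions,referenceRegion,grayRegions Region names.
#' @slot excludeFromBaseline Regions excluded from the baseline average
#'   (the stand-in for the activation-based exclusion mask).
#' @slot combineTask Single task regressor (proof-of-concept design).
#'
#' @param ... Slot values overriding the defaults.
#' @return A \code{RunConfig}.
#' @examples
#' fpetConfig()
#' fpetConfig(tStar = 20, seed = 7L)
#' @export RunConfig
#' @exportClass RunConfig
RunConfig <- setClass("RunConfig",
  slots = c(frameLengthMin = "numeric", scanDuration = "numeric",
            task = "TaskSchedule", admin = "AdministrationSchedule",
            tStar = "numeric", filterCutoff = "numeric", vB = "numeric",
            seed = "integer", targetRegions = "character",
            referenceRegion = "character", grayRegions = "character",
            excludeFromBaseline = "character", combineTask = "logical"),
  prototype = prototype(
    frameLengthMin = 1, scanDuration = 50, task = TaskSchedule(),
    admin = AdministrationSchedule(), tStar = 25, filterCutoff = 2.5,
    vB = 0.05, seed = 1L, targetRegions = "striatum",
    referenceRegion = "occipital",
    grayRegions = paste0("gray", 1:4),
    excludeFromBaseline = "striatum", combineTask = FALSE))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@frameLengthMin <= 0) msg <- c(msg, "frameLengthMin must be > 0")
  if (object@scanDuration <= 0) msg <- c(msg, "scanDuration must be > 0")
  if (object@tStar < 0 || object@tStar >= object@scanDuration)
    msg <- c(msg, "tStar must lie within the scan")
  if (object@filterCutoff <= 0) msg <- c(msg, "filterCutoff must be > 0")
  if (object@vB < 0 || object@vB > 1) msg <- c(msg, "vB must be in [0, 1]")
  if (max(blockEnd(object@task)) > object@scanDuration)
    msg <- c(msg, "task blocks must end within the scan")
  if (object@admin@scanDuration != object@scanDuration)
    msg <- c(msg, "administration schedule and scan duration disagree")
  if (length(object@referenceRegion) != 1)
    msg <- c(msg, "exactly one reference region is required")
  if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @export
fpetConfig <- function(...) RunConfig(...)

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %g-min frames over %g min; t*=%g min; cutoff %g min; vB=%g; seed %d\n",
              object@frameLengthMin, object@scanDuration, object@tStar,
              object@filterCutoff, object@vB, object@seed))
  show(object@admin); show(object@task)
  cat(sprintf("  target: %s | reference: %s | gray: %s (excluding %s)\n",
              paste(object@targetRegions, collapse = ","),
              object@referenceRegion,
              paste(object@grayRegions, collapse = ","),
              paste(object@excludeFromBaseline, collapse = ",")))
})

#' Frame schedule of a configuration
#'
#' @param config A \linkS4class{RunConfig}.
#' @return List with \code{start} and \code{end} frame times, minutes.
#' @export
configFrames <- function(config) {
  defaultFrames(config@scanDuration, config@frameLengthMin * 60)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys (all optional; missing keys keep the defaults):
#' \code{frame_length_s}, \code{scan_duration_min}, \code{t_star_min},
#' \code{filter_cutoff_min}, \code{blood_volume_fraction}, \code{seed},
#' \code{combine_task}, \code{task} (\code{onsets_min},
#' \code{duration_min}, \code{conditions}), \code{admin}
#' (\code{bolus_fraction}, \code{infusion_duration_min},
#' \code{total_activity}), \code{regions} (\code{target},
#' \code{reference}, \code{gray}, \code{exclude_from_baseline}).
#' Unknown keys raise an error so unit or spelling mistakes surface.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return A \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("frame_length_s", "scan_duration_min", "t_star_min",
             "filter_cutoff_min", "blood_volume_fraction", "seed",
             "combine_task", "task", "admin", "regions")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- fpetConfig()
  if (!is.null(raw$frame_length_s)) cfg@frameLengthMin <- raw$frame_length_s / 60
  if (!is.null(raw$scan_duration_min)) cfg@scanDuration <- raw$scan_duration_min
  if (!is.null(raw$t_star_min)) cfg@tStar <- raw$t_star_min
  if (!is.null(raw$filter_cutoff_min)) cfg@filterCutoff <- raw$filter_cutoff_min
  if (!is.null(raw$blood_volume_fraction)) cfg@vB <- raw$blood_volume_fraction
  if (!is.null(raw$seed)) cfg@seed <- as.integer(raw$seed)
  if (!is.null(raw$combine_task)) cfg@combineTask <- isTRUE(raw$combine_task)
  if (!is.null(raw$task)) {
    tk <- raw$task
    cfg@task <- TaskSchedule(
      blockOnsets = as.numeric(tk$onsets_min),
      blockDuration = if (!is.null(tk$duration_min)) tk$duration_min else 5,
      blockCondition = if (!is.null(tk$conditions)) as.character(tk$conditions)
        else rep(c("gain", "loss"), length.out = length(tk$onsets_min)))
  }
  if (!is.null(raw$admin)) {
    ad <- raw$admin
    cur <- cfg@admin
    cfg@admin <- AdministrationSchedule(
      bolusFraction = if (!is.null(ad$bolus_fraction)) ad$bolus_fraction
        else cur@bolusFraction,
      infusionDuration = if (!is.null(ad$infusion_duration_min))
        ad$infusion_duration_min else cfg@scanDuration,
      totalActivity = if (!is.null(ad$total_activity)) ad$total_activity
        else cur@totalActivity,
      scanDuration = cfg@scanDuration)
  } else if (cfg@admin@scanDuration != cfg@scanDuration) {
    cfg@admin <- AdministrationSchedule(
      bolusFraction = cfg@admin@bolusFraction,
      infusionDuration = min(cfg@admin@infusionDuration, cfg@scanDuration),
      totalActivity = cfg@admin@totalActivity,
      scanDuration = cfg@scanDuration)
  }
  if (!is.null(raw$regions)) {
    rg <- raw$regions
    if (!is.null(rg$target)) cfg@targetRegions <- as.character(rg$target)
    if (!is.null(rg$reference)) cfg@referenceRegion <- as.character(rg$reference)
    if (!is.null(rg$gray)) cfg@grayRegions <- as.character(rg$gray)
    if (!is.null(rg$exclude_from_baseline))
      cfg@excludeFromBaseline <- as.character(rg$exclude_from_baseline)
  }
  validObject(cfg)
  cfg
}

## provenance hash of a configuration (md5 of its canonical JSON dump)
configHash <- function(config) {
  dump <- jsonlite::toJSON(list(
    frameLengthMin = config@frameLengthMin,
    scanDuration = config@scanDuration,
    task = list(onsets = config@task@blockOnsets,
                duration = config@task@blockDuration,
                conditions = config@task@blockCondition),
    admin = list(bolusFraction = config@admin@bolusFraction,
                 infusionDuration = config@admin@infusionDuration,
                 totalActivity = config@admin@totalActivity),
    tStar = config@tStar, filterCutoff = config@filterCutoff,
    vB = config@vB, seed = config@seed,
    targetRegions = config@targetRegions,
    referenceRegion = config@referenceRegion,
    grayRegions = config@grayRegions,
    excludeFromBaseline = config@excludeFromBaseline,
    combineTask = config@combineTask), digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(dump), tf)
  unname(tools::md5sum(tf))
}
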