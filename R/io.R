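# Trial-log I/O: headered CSV (UTF-8, '.' decimal) with per-task schema
# validation, and a run manifest (config + seed + package version) so
# every output is reproducible from its manifest alone.

trial_log_schema <- list(
  twostep = c("participant_id", "trial", "action1", "state2", "action2",
              "reward"),
  multigoal = c("participant_id", "trial", "goal", "action",
                "reached_reward", "reached_punish", "points"),
  onestep = c("participant_id", "block", "trial", "action", "state")
)

goal_vocabulary <- c("seek_reward", "avoid_punish")

#' Write a trial log to CSV
#'
#' @param trial_log tibble/data frame of trials.
#' @param path output file.
#' @param task schema to validate against: `"twostep"`, `"multigoal"` or
#'   `"onestep"`.
#' @return the path, invisibly.
#' @export
write_trial_log <- function(trial_log, path,
                            task = c("twostep", "multigoal", "onestep")) {
  task <- match.arg(task)
  validate_trial_log(trial_log, task)
  write.csv(trial_log, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial log from CSV
#'
#' @param path CSV file written by [write_trial_log()] (or matching its
#'   column dictionary).
#' @param task schema to validate against.
#' @return a validated tibble.
#' @export
read_trial_log <- function(path, task = c("twostep", "multigoal",
                                          "onestep")) {
  task <- match.arg(task)
  log <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_trial_log(log, task)
  log
}

validate_trial_log <- function(log, task) {
  req <- trial_log_schema[[task]]
  miss <- setdiff(req, names(log))
  if (length(miss))
    stop("trial log is missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(log), c(req, "common", "condition"))
  if (length(extra))
    warning("unknown trial-log column(s): ", paste(extra, collapse = ", "))
  if (task == "multigoal") {
    bad <- which(!log$goal %in% goal_vocabulary)
    if (length(bad))
      stop("invalid goal label(s) outside {",
           paste(goal_vocabulary, collapse = ", "), "} at row(s): ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
  }
  invisible(log)
}

#' Write a run manifest next to an output
#'
#' Records the configuration, seed and package version that produced an
#' output file, as JSON.
#'
#' @param path the output file the manifest describes; the manifest is
#'   written to `<path>.manifest.json`.
#' @param config named list of run settings.
#' @param seed the integer seed used.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA) {
  manifest <- list(
    output = basename(path),
    package = "stlearn",
    version = as.character(utils::packageVersion("stlearn")),
    seed = seed,
    config = config,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  mpath <- paste0(path, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
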