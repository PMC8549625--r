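#' Write a trajectory as CSV
#'
#' One row per generation with columns
#' `generation,n,mean_A,mean_E,mean_z,var_A,var_E,cov_AE,var_z,mean_fitness,cov_zw,S_z,S_A,S_E,delta_mean_A,heritability,angle_deg`.
#' Numbers are serialized with 17 significant digits so that reading the
#' file back reproduces every value exactly; rounding is for display only.
#'
#' @param traj an `eeipm_trajectory` (or its `records` data frame).
#' @param path output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  r <- if (inherits(traj, "eeipm_trajectory")) traj$records else traj
  cols <- c("generation", "n", "mean_A", "mean_E", "mean_z", "var_A",
            "var_E", "cov_AE", "var_z", "mean_fitness", "cov_zw", "S_z",
            "S_A", "S_E", "delta_mean_A", "heritability", "angle_deg")
  missing <- setdiff(cols, names(r))
  if (length(missing))
    stop("trajectory lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  r <- r[, cols]
  fmt <- vapply(r, function(col) {
    if (is.integer(col)) format(col) else sprintf("%.17g", col)
  }, character(nrow(r)))
  fmt <- matrix(fmt, nrow = nrow(r), dimnames = list(NULL, cols))
  fmt[fmt %in% c("NA", "nan")] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by [write_trajectory()].
#' @return data frame of per-generation records.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, header = TRUE,
                  colClasses = c("integer", rep("numeric", 16)))
}

#' Compare two trajectories generation by generation
#'
#' Differences (`a - b`) of the mean breeding value, mean environmental
#' component, mean phenotype and mean fitness at matched generations, with
#' a summary line stating which trajectory's mean breeding value advanced
#' further by the final generation.
#'
#' @param traj_a,traj_b trajectories (`eeipm_trajectory`, records data
#'   frames, or CSV paths).
#' @return data frame with columns `generation`, `d_mean_A`, `d_mean_E`,
#'   `d_mean_z`, `d_mean_fitness`; the summary is attached as attribute
#'   `summary` and printed.
#' @export
compare_trajectories <- function(traj_a, traj_b) {
  as_records <- function(x) {
    if (inherits(x, "eeipm_trajectory")) return(x$records)
    if (is.character(x)) return(read_trajectory(x))
    x
  }
  a <- as_records(traj_a); b <- as_records(traj_b)
  if (nrow(a) != nrow(b) || !all(a$generation == b$generation))
    stop("trajectories cover different generations", call. = FALSE)
  out <- data.frame(generation = a$generation,
                    d_mean_A = a$mean_A - b$mean_A,
                    d_mean_E = a$mean_E - b$mean_E,
                    d_mean_z = a$mean_z - b$mean_z,
                    d_mean_fitness = a$mean_fitness - b$mean_fitness)
  last <- nrow(out)
  adv <- out$d_mean_A[last]
  summary_line <- if (abs(adv) < 1e-12) {
    "mean breeding values advanced equally in both trajectories"
  } else sprintf(
    "the %s trajectory's mean breeding value advanced further (by %.6g at generation %d)",
    if (adv > 0) "first" else "second", abs(adv), a$generation[last])
  attr(out, "summary") <- summary_line
  out
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the fully resolved
#' configuration (all defaults materialized), the package version, the
#' seed, a timestamp and the output paths. Identical configurations and
#' seeds yield identical outputs (the projection is deterministic).
#'
#' @param config resolved `eeipm_config` of the run.
#' @param path manifest output path (JSON).
#' @param outputs named list/character of output file paths.
#' @export
write_manifest <- function(config, path, outputs = list()) {
  cfg <- resolve_config(config)
  manifest <- list(
    package = "eeipm",
    version = as.character(utils::packageVersion("eeipm")),
    seed = cfg$run$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs,
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
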