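#' Write lineage and trajectory artifacts to a directory
#'
#' Writes the standard diff-able output set: generation records and
#' division-time counts as CSV, diagnostics (and RAF results, if supplied)
#' as JSON, with a header comment carrying the configuration hash and seed
#' so that any output file identifies the run that produced it. Two runs
#' with the same configuration and seed produce byte-identical bodies.
#'
#' @param run a [run_lineage()] result.
#' @param dir output directory (created if needed).
#' @param seed the seed used for the run (recorded in headers).
#' @param raf optional `raf_result` to serialize alongside.
#' @return character vector of the files written, invisibly.
#' @export
write_lineage_outputs <- function(run, dir, seed = NA_integer_,
                                  raf = NULL) {
  stopifnot(inherits(run, "lineage_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- config_hash(list(chem = run$chem, geometry = run$geometry,
                           mode = run$mode,
                           partition_mode = run$partition_mode))
  header <- sprintf("# config_hash=%s seed=%s", hash, seed)
  files <- character()
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    files <<- c(files, path)
  }
  wcsv(run$generations, "generations.csv")
  wcsv(run$division_counts, "division_counts.csv")
  diag <- list(config_hash = hash, seed = seed,
               glance = as.list(glance(run)))
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(dir, "diagnostics.json"))
  if (!is.null(raf)) {
    rafdoc <- list(config_hash = hash, seed = seed,
                   max_raf = raf$max_raf,
                   irr_rafs = unclass(raf$irr_rafs),
                   closure = raf$closure, sccs = raf$sccs)
    jsonlite::write_json(rafdoc, file.path(dir, "raf.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(dir, "raf.json"))
  }
  invisible(files)
}

#' Hash of a run configuration
#'
#' Stable hash of any serializable configuration object; recorded in output
#' headers so results can be traced to the exact configuration.
#'
#' @param config any R object.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

#' Write a trajectory to CSV
#'
#' @param trajectory tibble from [simulate_segment()].
#' @param path output file.
#' @param seed,hash recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, seed = NA_integer_,
                                 hash = NA_character_) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%s", hash, seed), con)
  utils::write.csv(trajectory, con, row.names = FALSE)
  close(con)
  invisible(path)
}
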