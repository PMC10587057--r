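# Plain-text persistence: porosity matrices and summaries as CSV, run
# manifests as JSON.

#' Read / write porosity matrices as long-format CSV
#'
#' Columns `x`, `y`, `z` (1-based subunit indices) and `p` (porosity).
#'
#' @param m A [porosity_matrix()].
#' @param path CSV path.
#' @return Invisibly `path` (write) or a [porosity_matrix()] (read).
#' @export
write_porosity_csv <- function(m, path) {
  m <- as_porosity_matrix(m)
  s <- dim(m)[1]
  g <- expand.grid(x = seq_len(s), y = seq_len(s), z = seq_len(s))
  g$p <- as.vector(unclass(m))
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_porosity_csv
#' @export
read_porosity_csv <- function(path) {
  d <- utils::read.csv(path)
  s <- round(nrow(d)^(1 / 3))
  if (s^3 != nrow(d)) stop("porosity CSV must describe a cubic matrix")
  a <- array(NA_real_, c(s, s, s))
  a[cbind(d$x, d$y, d$z)] <- d$p
  porosity_matrix(a)
}

#' Write a run manifest next to command outputs
#'
#' Records enough metadata (configuration digest, seed, package version,
#' timestamp, timing) to rerun the command.
#'
#' @param path Output JSON path.
#' @param command Command or function name.
#' @param config The configuration list used.
#' @param seed Seed used.
#' @param elapsed_s Wall-clock seconds.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NA,
                           elapsed_s = NA) {
  digest <- if (is.null(config)) NA_character_ else
    paste0("sum", sum(utf8ToInt(paste(utils::capture.output(utils::str(config)),
                                      collapse = ""))))
  obj <- list(command = command, seed = seed,
              package = "gyrodesign",
              version = as.character(utils::packageVersion("gyrodesign")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              elapsed_s = elapsed_s, config_digest = digest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write / read an active-learning history table as CSV
#'
#' @param history Data frame as produced by [run_mall()].
#' @param path CSV path.
#' @return Invisibly `path` (write) or the data frame (read).
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) utils::read.csv(path)
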