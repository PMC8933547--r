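#' Write a frame stack to a plain-text CSV
#'
#' Interchange format for small stacks: a long table with columns
#' `frame, row, col, value` (all 1-based indices) preceded by a `# H W T`
#' header comment.  Intended for fixtures and cross-tool exchange; large
#' stacks are better persisted with [saveRDS()].
#'
#' @param stack A `frame_stack`.
#' @param path Output file.
#' @export
write_stack_csv <- function(stack, path) {
  d <- dim(stack$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %d", d[1], d[2], d[3]), con)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                     frame = seq_len(d[3]))
  df <- data.frame(frame = idx$frame, row = idx$row, col = idx$col,
                   value = as.vector(stack$frames))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a frame stack written by [write_stack_csv()]
#'
#' @param path CSV file.
#' @param config Optional `optical_config` to attach.
#' @return A `frame_stack`.
#' @export
read_stack_csv <- function(path, config = NULL) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  d <- as.integer(hdr[2:4])
  df <- utils::read.csv(path, skip = 1)
  arr <- array(0, d)
  arr[cbind(df$row, df$col, df$frame)] <- df$value
  structure(list(frames = arr, config = config), class = "frame_stack")
}

#' Write a recovery report (or any list of scalars) as JSON
#'
#' @param report A `recovery_report` or plain list.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$peaks <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the arguments of [pipeline_config()]; nested objects
#' `optical` and `deconv` are passed to [optical_config()] and
#' [deconv_config()].
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$optical)) j$optical <- do.call(optical_config, j$optical)
  if (!is.null(j$deconv)) j$deconv <- do.call(deconv_config, j$deconv)
  do.call(pipeline_config, j)
}
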