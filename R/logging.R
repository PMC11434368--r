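#' @keywords internal
.log_levels <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

#' Set the logging threshold
#'
#' Messages below the threshold are suppressed. Logging goes to stderr so
#' that piped tabular output on stdout stays clean.
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"error"`
#' @return the previous level, invisibly
#' @export
set_log_level <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- getOption("eetkit.log_level", "info")
  options(eetkit.log_level = level)
  invisible(old)
}

#' @keywords internal
eet_log <- function(level, ...) {
  thr <- .log_levels[[getOption("eetkit.log_level", "info")]]
  if (.log_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}
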