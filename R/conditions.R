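# Typed conditions and lightweight logging.
#
# Error taxonomy (also the pipeline status codes):
#   validation -> 2, io -> 3, degenerate -> 4, model -> 5

sm_status_codes <- c(validation = 2L, io = 3L, degenerate = 4L, model = 5L)

sm_abort <- function(type, msg, ...) {
  type <- match.arg(type, names(sm_status_codes))
  rlang::abort(
    sprintf(msg, ...),
    class = c(paste0("seedmorph_", type, "_error"), "seedmorph_error"),
    status = sm_status_codes[[type]]
  )
}

sm_log_levels <- c(debug = 10L, info = 20L, warn = 30L)

#' Set or query the package log level
#'
#' Messages emitted by the pipeline stages (`segment_seeds()`,
#' `extract_features()`, `run_pipeline()`, ...) are filtered by this level.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`.
#' @return the previous level, invisibly.
#' @export
seedmorph_log_level <- function(level = c("info", "debug", "warn")) {
  level <- match.arg(level)
  old <- getOption("seedmorph.log_level", "info")
  options(seedmorph.log_level = level)
  invisible(old)
}

sm_log <- function(level, msg, ...) {
  threshold <- sm_log_levels[[getOption("seedmorph.log_level", "info")]]
  if (sm_log_levels[[level]] >= threshold) {
    message(sprintf("[seedmorph %s] %s", level, sprintf(msg, ...)))
  }
  invisible(NULL)
}
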