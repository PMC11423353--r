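#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Classed conditions so callers (and the CLI) can distinguish user error
# (bad parameters, malformed input) from internal failure.
stop_validation <- function(msg, ...) {
  abort(msg, class = c("phagetools_validation_error", "phagetools_error"), ...)
}

stop_parameter <- function(msg, ...) {
  abort(msg, class = c("phagetools_parameter_error", "phagetools_error"), ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = c("phagetools_parse_error", "phagetools_error"), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_genomes <- function(genomes, arg = "genomes") {
  if (!is.data.frame(genomes) || !all(c("id", "sequence") %in% names(genomes))) {
    stop_parameter(sprintf(
      "`%s` must be a data frame with at least columns `id` and `sequence`", arg
    ))
  }
  if (anyDuplicated(genomes$id)) {
    dup <- unique(genomes$id[duplicated(genomes$id)])
    stop_validation(sprintf("duplicate genome id(s): %s", paste(dup, collapse = ", ")))
  }
  invisible(genomes)
}
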