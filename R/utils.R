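#' @keywords internal
"_PACKAGE"

# Classed error so callers/tests can distinguish failure modes.
abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "synergyscreen_error")))
}

warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "synergyscreen_warning")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Write a data frame as tab-separated text
#'
#' Thin wrapper used for all tabular outputs of the pipeline (QC tables,
#' score tables, rank tables, Fa-CI tables).
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
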