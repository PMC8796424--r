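#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish configuration, validation,
## parse, I/O and dependency failures programmatically.
rn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rnanet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

rn_config_error     <- function(msg, ...) rn_stop("rnanet_config_error", msg, ...)
rn_validation_error <- function(msg, ...) rn_stop("rnanet_validation_error", msg, ...)
rn_parse_error      <- function(msg, ...) rn_stop("rnanet_parse_error", msg, ...)
rn_io_error         <- function(msg, ...) rn_stop("rnanet_io_error", msg, ...)
rn_dependency_error <- function(msg, ...) rn_stop("rnanet_dependency_error", msg, ...)

## Read a tab-separated table with a header row, keeping ids as character.
read_tsv_table <- function(path, ...) {
  if (!file.exists(path)) rn_io_error("file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "", ...)
}

write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
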