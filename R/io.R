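# JSONL I/O. Clinical free text embeds every delimiter imaginable, so records
# travel as one JSON object per line (newlines escaped by the JSON encoder).
# Output files carry an optional header line with the run configuration hash
# for provenance.

#' Write records to a JSONL file
#'
#' One JSON object per line. If `header` is given it is written as a first
#' line of the form `{"_header": ...}` and skipped (but returned as an
#' attribute) by [read_jsonl()].
#'
#' @param records A data frame; each row becomes one JSON object.
#' @param path Output file path.
#' @param header Optional named list written as the header line.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header)) {
    lines <- jsonlite::toJSON(list(`_header` = header), auto_unbox = TRUE)
  }
  if (nrow(records) > 0L) {
    lines <- c(lines, vapply(seq_len(nrow(records)), function(i) {
      as.character(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                    auto_unbox = TRUE, null = "null",
                                    na = "null"))
    }, character(1)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read records from a JSONL file
#'
#' @param path Input file path.
#' @param required_fields Character vector of field names every record must
#'   have; a violation is an error naming the line.
#' @return A tibble (zero rows for an empty file), with attribute `"header"`
#'   if the file starts with a `{"_header": ...}` line. A malformed line is
#'   an error naming the line number.
#' @export
read_jsonl <- function(path, required_fields = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  header <- NULL
  offset <- 0L
  if (length(lines) > 0L) {
    first <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
    if (is.list(first) && identical(names(first), "_header")) {
      header <- first[["_header"]]
      lines <- lines[-1L]
      offset <- 1L
    }
  }
  lines <- lines[nzchar(trimws(lines))]
  records <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      stop("malformed JSONL at line ", i + offset, " of ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
    if (!is.list(rec) || is.null(names(rec))) {
      stop("malformed JSONL at line ", i + offset, " of ", path,
           ": not a JSON object", call. = FALSE)
    }
    miss <- setdiff(required_fields, names(rec))
    if (length(miss) > 0L) {
      stop("record at line ", i + offset, " of ", path,
           " is missing fields: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    tibble::as_tibble(rec[!vapply(rec, is.null, logical(1))])
  })
  out <- if (length(records) == 0L) tibble::tibble() else {
    dplyr::bind_rows(records)
  }
  attr(out, "header") <- header
  out
}

#' @rdname read_jsonl
#' @export
read_notes <- function(path) {
  read_jsonl(path, required_fields = c("note_id", "text"))
}

#' @rdname read_jsonl
#' @export
read_gold <- function(path) {
  read_jsonl(path, required_fields = c("note_id", "category", "span_text"))
}

#' Write final answers with config provenance
#'
#' @param answers Final-answer tibble (`note_id`, `category`, `text`,
#'   `selection_method`, ...).
#' @param path Output file path.
#' @param config Optional pipeline configuration; its hash is embedded in the
#'   file header.
#' @return `path`, invisibly.
#' @export
write_answers <- function(answers, path, config = NULL) {
  header <- NULL
  if (!is.null(config)) {
    header <- list(config_hash = config_hash(config),
                   package = "sudspanr")
  }
  write_jsonl(answers, path, header = header)
}

#' Hash a configuration object for provenance
#'
#' @param config Any serializable list.
#' @return Integer hash of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  det_hash(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                         digits = NA)))
}
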