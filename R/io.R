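#' Read and write response matrices as CSV
#'
#' Response matrices travel as comma-separated UTF-8 text with a mandatory
#' header row of item identifiers, one row per person, and empty cells for
#' missing responses. Values round-trip exactly (integer categories).
#'
#' @param responses integer matrix (or data.frame) of item responses; logical
#'   matrices (aid flags) are stored as 0/1.
#' @param path file path.
#' @return `read_responses()`: integer matrix with column names.
#' @export
write_responses <- function(responses, path) {
  m <- as.matrix(responses)
  if (is.logical(m)) storage.mode(m) <- "integer"
  if (is.null(colnames(m)))
    colnames(m) <- paste0("item", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  first <- readLines(path, n = 1L)
  if (!nzchar(first) || grepl("^[0-9.,]+$", first))
    stop("malformed response CSV (line 1): a header row of item identifiers ",
         "is required")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ""),
    error = function(e) stop("malformed response CSV: ", conditionMessage(e)))
  m <- as.matrix(df)
  bad <- which(!is.na(m) & (m != round(m)))
  if (length(bad)) {
    rows <- ((bad - 1L) %% nrow(m)) + 2L  # +1 header, +1 one-based
    stop("malformed response CSV: non-integer value(s) at data line(s) ",
         paste(utils::head(unique(rows), 5L), collapse = ", "))
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a dataset manifest
#'
#' JSON sidecar recording the generator configuration, seed and package
#' version next to every simulated dataset, so any artifact can be
#' regenerated.
#'
#' @param config a [sim_config()] (or any named list).
#' @param path output path (conventionally `<dataset>-manifest.json`).
#' @param extra further named fields to record.
#' @export
write_manifest <- function(config, path, extra = list()) {
  payload <- c(unclass(config), extra,
               list(package = "pfhaqlink",
                    version = as.character(utils::packageVersion("pfhaqlink")),
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
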