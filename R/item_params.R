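#' Item parameter sets for polytomous adjacent-category models
#'
#' A compact container for partial credit / generalized partial credit item
#' parameters: one row per item with its number of response categories
#' `n_cat` (categories are scored 0..`n_cat - 1`), discrimination `a` (> 0,
#' fixed at 1 under the PCM), latent dimension assignment `dim`, and
#' `n_cat - 1` thresholds `b1, b2, ...` (trailing `NA` for items with fewer
#' categories than the widest item).
#'
#' @param item character vector of item identifiers.
#' @param n_cat integer vector of response-category counts (>= 2).
#' @param b numeric matrix of thresholds, `length(item)` rows and
#'   `max(n_cat) - 1` columns, `NA`-padded; or a list of numeric vectors.
#' @param a numeric vector of discriminations (recycled), all > 0.
#' @param dim integer vector of dimension assignments (recycled).
#' @return data.frame of class `item_params`.
#' @examples
#' item_params(c("i1", "i2"), n_cat = c(3, 4),
#'             b = list(c(-1, 1), c(-1, 0, 1)))
#' @export
item_params <- function(item, n_cat, b, a = 1, dim = 1L) {
  n_cat <- as.integer(n_cat)
  if (any(n_cat < 2L)) stop("every item needs at least 2 response categories")
  if (is.list(b)) {
    kmax <- max(n_cat) - 1L
    b <- t(vapply(seq_along(b), function(i) {
      v <- as.numeric(b[[i]])
      if (length(v) != n_cat[i] - 1L)
        stop("item ", item[i], ": expected ", n_cat[i] - 1L,
             " thresholds, got ", length(v))
      c(v, rep(NA_real_, kmax - length(v)))
    }, numeric(max(n_cat) - 1L)))
  }
  b <- matrix(as.numeric(b), nrow = length(item))
  a <- rep_len(as.numeric(a), length(item))
  if (any(!is.finite(a) | a <= 0)) stop("discriminations must be finite and > 0")
  dim <- rep_len(as.integer(dim), length(item))
  out <- data.frame(item = as.character(item), n_cat = n_cat, a = a, dim = dim,
                    stringsAsFactors = FALSE)
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  out <- cbind(out, as.data.frame(b))
  for (i in seq_along(item)) {
    bi <- b[i, seq_len(n_cat[i] - 1L)]
    if (anyNA(bi)) stop("item ", item[i], ": missing threshold(s)")
  }
  class(out) <- c("item_params", "data.frame")
  out
}

#' @rdname item_params
#' @param x an `item_params` object.
#' @param i item index.
#' @export
thresholds <- function(x, i = NULL) {
  bcols <- grep("^b[0-9]+$", names(x), value = TRUE)
  out <- lapply(seq_len(nrow(x)), function(j) {
    as.numeric(x[j, bcols])[seq_len(x$n_cat[j] - 1L)]
  })
  names(out) <- x$item
  if (is.null(i)) out else out[[i]]
}

#' @export
print.item_params <- function(x, ...) {
  cat("Item parameters:", nrow(x), "item(s),",
      if (length(unique(x$dim)) > 1L)
        paste(length(unique(x$dim)), "dimensions") else "1 dimension", "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read and write item parameter tables
#'
#' Structured plain-text (CSV) serialisation of [item_params()] objects,
#' optionally carrying per-item fit columns (per-group effect sizes, fit
#' statistic, df, p) alongside the parameters, mirroring the layout of
#' published item-parameter supplements. Leading `# key: value` comment
#' lines hold metadata (model kind, latent correlation, creation info) and
#' round-trip through the reader.
#'
#' @param params an `item_params` object (or a data.frame extending one with
#'   fit columns).
#' @param path file path.
#' @param meta named list of scalar metadata written as comment lines.
#' @return `read_item_params()`: the `item_params` data.frame with a `meta`
#'   attribute.
#' @export
write_item_params <- function(params, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  }
  df <- as.data.frame(params)
  # full-precision text so parameter files round-trip every digit
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      df[[cl]] <- vapply(df[[cl]], function(v) {
        if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
      }, character(1))
    }
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_params
#' @export
read_item_params <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"),
                        stringsAsFactors = FALSE)
  df$n_cat <- as.integer(df$n_cat)
  df$dim <- as.integer(df$dim)
  class(df) <- c("item_params", "data.frame")
  attr(df, "meta") <- meta
  df
}
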