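#' Crosswalk objects
#'
#' A crosswalk is a pair of directional concordance maps between observed
#' total scores: every attainable HAQ-DI score (25 values, 0 to 3 by 0.125)
#' to a predicted PF-10 raw score (with its norm-based companion), and every
#' attainable PF-10 raw score (21 values, 0 to 100 by 5) to a predicted
#' HAQ-DI score. Both maps are total over the attainable sets, monotone
#' (worse observed function never maps to better predicted function), and
#' clip at the extremes rather than extrapolate.
#'
#' @param haq_to_pf10 data.frame with columns `haq`, `pf10`, `pf10_norm` (and
#'   optionally the underlying `eap_haq`, `eap_pf10`), 25 rows.
#' @param pf10_to_haq data.frame with columns `pf10`, `pf10_norm`, `haq` (and
#'   optionally EAP columns), 21 rows.
#' @param method HAQ scoring method the map applies to, `"SDI"` or `"ADI"`.
#' @param model IRT model the map was built under (or `"published"`).
#' @param meta named list of provenance metadata.
#' @return object of class `crosswalk`.
#' @export
new_crosswalk <- function(haq_to_pf10, pf10_to_haq, method, model = "PCM",
                          meta = list()) {
  method <- match.arg(method, c("SDI", "ADI"))
  haq_vals <- attainable_scores("HAQ_SDI")
  pf_vals <- attainable_scores("PF10_RAW", worst_first = TRUE)
  if (!setequal(haq_to_pf10$haq, haq_vals))
    stop("haq_to_pf10 must cover all 25 attainable HAQ scores")
  if (!setequal(pf10_to_haq$pf10, pf_vals))
    stop("pf10_to_haq must cover all 21 attainable PF-10 scores")
  if (any(!haq_to_pf10$pf10 %in% pf_vals) || any(!pf10_to_haq$haq %in% haq_vals))
    stop("predicted scores must lie in the attainable sets (clip, never extrapolate)")
  h2p <- haq_to_pf10[order(haq_to_pf10$haq), , drop = FALSE]
  p2h <- pf10_to_haq[order(pf10_to_haq$pf10, decreasing = TRUE), , drop = FALSE]
  if (any(diff(h2p$pf10) > 0))
    stop("haq_to_pf10 is not monotone: worse HAQ maps to better PF-10")
  if (any(diff(p2h$haq) < 0))
    stop("pf10_to_haq is not monotone: worse PF-10 maps to better HAQ")
  rownames(h2p) <- rownames(p2h) <- NULL
  structure(list(haq_to_pf10 = h2p, pf10_to_haq = p2h,
                 method = method, model = model, meta = meta),
            class = "crosswalk")
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("Crosswalk PF-10 <-> HAQ-", x$method, " (", x$model, " model",
      if (!is.null(x$meta$n)) paste0(", n = ", x$meta$n), ")\n", sep = "")
  cat("  HAQ -> PF-10: ", nrow(x$haq_to_pf10), " entries; PF-10 -> HAQ: ",
      nrow(x$pf10_to_haq), " entries\n", sep = "")
  invisible(x)
}

#' Convert an observed score through a crosswalk
#'
#' Table lookup in a [new_crosswalk()] object. The observed value must be an
#' attainable score of its scale; otherwise an error suggests the nearest
#' attainable value.
#'
#' @param crosswalk a `crosswalk` object.
#' @param observed observed score value(s).
#' @param from scale of the observed value: `"haq"` or `"pf10"` (raw, 0-100).
#' @return data.frame of predictions: for `from = "haq"`, columns `haq`
#'   (observed), `pf10` and `pf10_norm`; for `from = "pf10"`, columns `pf10`,
#'   `pf10_norm` (observed) and `haq`.
#' @examples
#' cw <- published_crosswalk("SDI")
#' apply_crosswalk(cw, 1.0, from = "haq")    # PF-10 55 (norm 38.1)
#' apply_crosswalk(cw, 80, from = "pf10")    # HAQ-SDI 0.25
#' @export
apply_crosswalk <- function(crosswalk, observed, from = c("haq", "pf10")) {
  from <- match.arg(from)
  stopifnot(inherits(crosswalk, "crosswalk"))
  tab <- if (from == "haq") crosswalk$haq_to_pf10 else crosswalk$pf10_to_haq
  key <- if (from == "haq") tab$haq else tab$pf10
  idx <- match(observed, key)
  if (anyNA(idx)) {
    bad <- observed[is.na(idx)][1]
    nearest <- key[which.min(abs(key - bad))]
    stop("observed ", from, " score ", bad, " is not attainable; ",
         "nearest attainable value is ", nearest)
  }
  cols <- if (from == "haq") c("haq", "pf10", "pf10_norm")
          else c("pf10", "pf10_norm", "haq")
  out <- tab[idx, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write crosswalk tables as CSV
#'
#' Plain-text serialisation of a crosswalk in the published-table layout:
#' leading `# key: value` comment lines (method, model, provenance), then one
#' row per map entry with a `direction` column (`haq_to_pf10` /
#' `pf10_to_haq`) and `observed`, `predicted`, `predicted_norm` columns
#' (`observed_norm` accompanies observed PF-10 scores). Values round-trip
#' bit-exactly through [read_crosswalk()].
#'
#' @param crosswalk a `crosswalk` object.
#' @param path file path.
#' @return `read_crosswalk()`: a `crosswalk` object.
#' @export
write_crosswalk <- function(crosswalk, path) {
  h2p <- crosswalk$haq_to_pf10; p2h <- crosswalk$pf10_to_haq
  rows <- rbind(
    data.frame(direction = "haq_to_pf10", observed = h2p$haq,
               observed_norm = NA_real_, predicted = h2p$pf10,
               predicted_norm = h2p$pf10_norm),
    data.frame(direction = "pf10_to_haq", observed = p2h$pf10,
               observed_norm = p2h$pf10_norm, predicted = p2h$haq,
               predicted_norm = NA_real_))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(method = crosswalk$method, model = crosswalk$model),
            crosswalk$meta)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    meta[[trimws(sub(":.*$", "", kv))]] <- trimws(sub("^[^:]*:", "", kv))
  }
  if (is.null(meta$method)) stop("crosswalk file lacks a `method` metadata line")
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  h2p <- df[df$direction == "haq_to_pf10",
            c("observed", "predicted", "predicted_norm")]
  names(h2p) <- c("haq", "pf10", "pf10_norm")
  p2h <- df[df$direction == "pf10_to_haq",
            c("observed", "observed_norm", "predicted")]
  names(p2h) <- c("pf10", "pf10_norm", "haq")
  model <- if (is.null(meta$model)) "published" else meta$model
  new_crosswalk(h2p, p2h, method = meta$method, model = model,
                meta = meta[setdiff(names(meta), c("method", "model"))])
}

#' The published rheumatoid-arthritis PF-10 / HAQ-DI crosswalk
#'
#' Loads the packaged crosswalk developed on the 1791-patient RA calibration
#' sample (partial credit model), as a working converter. Two variants exist,
#' one per HAQ scoring method. These tables ship as data; they are not
#' recomputed at install time.
#'
#' @param method `"SDI"` (standard HAQ scoring, aids/devices adjustment) or
#'   `"ADI"` (alternative scoring).
#' @return a `crosswalk` object.
#' @examples
#' cw <- published_crosswalk("SDI")
#' apply_crosswalk(cw, 1.0, from = "haq")
#' @export
published_crosswalk <- function(method = c("SDI", "ADI")) {
  method <- match.arg(method)
  path <- system.file("extdata",
                      paste0("crosswalk-published-", tolower(method), ".csv"),
                      package = "pfhaqlink", mustWork = TRUE)
  read_crosswalk(path)
}
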