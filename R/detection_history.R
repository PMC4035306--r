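#' Detection-history tables
#'
#' A detection history records, for each of `n` sites, the outcome of up to
#' `K` repeat surveys within one season: `1` (species detected), `0` (surveyed
#' but not detected) or `NA` (occasion not surveyed).  It is the data object
#' of the single-season occupancy/persistence likelihood.
#'
#' Sites whose rows are entirely `NA` are retained — they contribute a
#' constant factor 1 to the likelihood — but flagged, since they carry no
#' information about persistence or detection.
#'
#' @param y numeric or integer matrix, `n` sites by `K` occasions, entries in
#'   `{0, 1, NA}`.
#' @param site_ids character vector of unique site identifiers; defaults to
#'   the rownames of `y`, or `site1..siten`.
#' @return An object of class `detection_history` with elements `site_ids`,
#'   `y` (integer matrix with `NA` for missing occasions) and `all_missing`
#'   (logical flag per site).
#' @examples
#' h <- detection_history(rbind(c(1, 0, NA), c(0, 0, 0)), c("A", "B"))
#' n_sites(h)
#' @export
detection_history <- function(y, site_ids = NULL) {
  if (!is.matrix(y)) y <- as.matrix(y)
  if (nrow(y) < 1L || ncol(y) < 1L) {
    stopf("detection history must have at least one site and one occasion")
  }
  bad <- !(is.na(y) | y == 0 | y == 1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("invalid detection-history entry %s at site row %d, occasion %d (must be 0, 1 or missing)",
          format(y[bad][1L]), idx[1L], idx[2L])
  }
  if (is.null(site_ids)) site_ids <- rownames(y)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(y)))
  site_ids <- as.character(site_ids)
  if (length(site_ids) != nrow(y)) {
    stopf("site_ids length (%d) does not match number of rows (%d)",
          length(site_ids), nrow(y))
  }
  if (anyDuplicated(site_ids)) {
    stopf("duplicate site ids: %s",
          paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  }
  storage.mode(y) <- "integer"
  dimnames(y) <- list(site_ids, paste0("occ", seq_len(ncol(y))))
  all_missing <- rowSums(!is.na(y)) == 0L
  if (any(all_missing)) {
    warnf("%d site(s) have no surveyed occasions (kept, flagged): %s",
          sum(all_missing), paste(site_ids[all_missing], collapse = ", "))
  }
  structure(list(site_ids = site_ids, y = y,
                 all_missing = unname(all_missing)),
            class = "detection_history")
}

#' @rdname detection_history
#' @param h a `detection_history`.
#' @export
n_sites <- function(h) nrow(h$y)

#' @rdname detection_history
#' @export
n_occasions <- function(h) ncol(h$y)

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("Detection history: %d sites x %d occasions\n",
              n_sites(x), n_occasions(x)))
  cat(sprintf("  surveyed cells: %d of %d; sites with >=1 detection: %d\n",
              sum(!is.na(x$y)), length(x$y),
              sum(rowSums(x$y == 1, na.rm = TRUE) > 0)))
  invisible(x)
}

# Tokens accepted as "occasion not surveyed" on read; "." is always written.
MISSING_TOKENS <- c("", ".", "NA")

#' Read and write detection-history CSV files
#'
#' Wide format: a header `site,occ1,...,occK`, one row per site, cells `0`,
#' `1`, or one of `""`, `"."`, `"NA"` for an unsurveyed occasion.  On write
#' the missing token is always `"."`, the convention of existing occupancy
#' software file formats.
#'
#' @param path file path.
#' @return `read_detection_csv` returns a [detection_history];
#'   `write_detection_csv` returns `path` invisibly.
#' @export
read_detection_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 strip.white = TRUE, na.strings = character())
  if (ncol(df) < 2L) stopf("'%s': need a site column plus >=1 occasion column", path)
  if (tolower(names(df)[1L]) != "site") {
    stopf("'%s': first column must be named 'site', got '%s'", path, names(df)[1L])
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stopf("'%s': duplicate site ids: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  y <- matrix(NA_integer_, nrow(cells), ncol(cells))
  known <- matrix(cells %in% c("0", "1", MISSING_TOKENS), nrow(cells))
  if (!all(known)) {
    idx <- which(!known, arr.ind = TRUE)[1L, ]
    stopf("'%s': invalid cell value '%s' at row %d (site %s), column '%s'",
          path, cells[!known][1L], idx[1L], ids[idx[1L]],
          colnames(cells)[idx[2L]])
  }
  y[cells == "0"] <- 0L
  y[cells == "1"] <- 1L
  detection_history(y, ids)
}

#' @rdname read_detection_csv
#' @param h a `detection_history` to serialize.
#' @export
write_detection_csv <- function(h, path) {
  out <- h$y
  cells <- ifelse(is.na(out), ".", as.character(out))
  df <- data.frame(site = h$site_ids, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("site", colnames(h$y))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persistence labels from detection histories
#'
#' A site is labelled persisted (`z = 1`) if the species was detected on at
#' least one survey, extirpated (`z = 0`) otherwise.  This is the "seen or
#' heard during any of the surveys" rule, uncorrected for detection error.
#' Sites with no surveyed occasions get `z = 0` with a warning flag.
#'
#' @param h a [detection_history].
#' @return An object of class `persistence_labels`: `site_ids`, `z` (0/1
#'   integer vector) and `all_missing` flags.
#' @export
labels_from_histories <- function(h) {
  stopifnot(inherits(h, "detection_history"))
  z <- as.integer(rowSums(h$y == 1, na.rm = TRUE) > 0)
  if (any(h$all_missing)) {
    warnf("%d site(s) with no surveyed occasions labelled z = 0",
          sum(h$all_missing))
  }
  structure(list(site_ids = h$site_ids, z = z, all_missing = h$all_missing),
            class = "persistence_labels")
}

#' @export
print.persistence_labels <- function(x, ...) {
  cat(sprintf("Persistence labels: %d of %d sites persisted (%.0f%%)\n",
              sum(x$z), length(x$z), 100 * mean(x$z)))
  invisible(x)
}
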