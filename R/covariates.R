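#' Covariate bundles
#'
#' Holds the predictors aligned to a detection-history table: site-level
#' covariates (one value per site, e.g. proportion of shoreline bulrush) and
#' occasion-level covariates (one value per site x survey occasion, e.g.
#' Julian date of each visit).
#'
#' @param site_covs named list of numeric vectors, one value per site.
#' @param occasion_covs named list of numeric `n x K` matrices.
#' @param site_ids character site identifiers (canonical order).
#' @return An object of class `covariate_bundle`.
#' @export
covariate_bundle <- function(site_covs = list(), occasion_covs = list(),
                             site_ids = NULL) {
  if (is.null(site_ids)) {
    if (length(site_covs)) site_ids <- names(site_covs[[1L]])
    if (is.null(site_ids) && length(occasion_covs)) {
      site_ids <- rownames(occasion_covs[[1L]])
    }
  }
  if (is.null(site_ids)) stopf("site_ids required (could not be inferred)")
  site_ids <- as.character(site_ids)
  n <- length(site_ids)
  for (nm in names(site_covs)) {
    v <- site_covs[[nm]]
    if (!is.numeric(v)) stopf("site covariate '%s' is not numeric", nm)
    if (length(v) != n) {
      stopf("site covariate '%s' has length %d, expected %d", nm, length(v), n)
    }
    site_covs[[nm]] <- setNames(as.numeric(v), site_ids)
  }
  K <- NULL
  for (nm in names(occasion_covs)) {
    m <- occasion_covs[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stopf("occasion covariate '%s' must be a numeric matrix", nm)
    }
    if (nrow(m) != n) {
      stopf("occasion covariate '%s' has %d rows, expected %d", nm, nrow(m), n)
    }
    if (is.null(K)) K <- ncol(m)
    if (ncol(m) != K) stopf("occasion covariates disagree on K")
    dimnames(m) <- list(site_ids, paste0("occ", seq_len(ncol(m))))
    occasion_covs[[nm]] <- m
  }
  structure(list(site_ids = site_ids, site_covs = site_covs,
                 occasion_covs = occasion_covs),
            class = "covariate_bundle")
}

#' @export
print.covariate_bundle <- function(x, ...) {
  cat(sprintf("Covariate bundle: %d sites\n", length(x$site_ids)))
  cat("  site-level:    ", paste(names(x$site_covs), collapse = ", "), "\n")
  cat("  occasion-level:", paste(names(x$occasion_covs), collapse = ", "), "\n")
  invisible(x)
}

# Resolve a covariate by name; level = "site", "occasion" or "any".
get_covariate <- function(bundle, name, level = "any") {
  if (level %in% c("site", "any") && name %in% names(bundle$site_covs)) {
    return(list(level = "site", value = bundle$site_covs[[name]]))
  }
  if (level %in% c("occasion", "any") && name %in% names(bundle$occasion_covs)) {
    return(list(level = "occasion", value = bundle$occasion_covs[[name]]))
  }
  stopf("covariate '%s' not found%s in bundle", name,
        if (level == "any") "" else sprintf(" at %s level", level))
}

#' Read site- and occasion-covariate CSV files
#'
#' The site file is keyed by a `site` column with one numeric column per
#' covariate.  The optional occasion file is in long form, keyed by
#' `site,occasion`, with one numeric column per occasion-level covariate;
#' rows may be absent for unsurveyed occasions (those cells become `NA`).
#' Covariates are re-ordered to match the detection-history table's site
#' order, which is canonical.
#'
#' @param site_path path to the site-covariate CSV.
#' @param occasion_path optional path to the long-form occasion CSV.
#' @param histories a [detection_history] giving the canonical site order
#'   and the number of occasions.
#' @return A [covariate_bundle] aligned to `histories`.
#' @export
read_covariates_csv <- function(site_path, occasion_path = NULL, histories) {
  stopifnot(inherits(histories, "detection_history"))
  ids <- histories$site_ids
  df <- read.csv(site_path, check.names = FALSE, strip.white = TRUE,
                 colClasses = "character", na.strings = character())
  if (tolower(names(df)[1L]) != "site") {
    stopf("'%s': first column must be 'site'", site_path)
  }
  extra <- setdiff(df[[1L]], ids)
  if (length(extra)) {
    warnf("'%s': %d site(s) not in the detection table ignored: %s",
          site_path, length(extra), paste(extra, collapse = ", "))
  }
  miss <- setdiff(ids, df[[1L]])
  if (length(miss)) {
    stopf("'%s': sites present in histories but absent in covariates: %s",
          site_path, paste(miss, collapse = ", "))
  }
  row <- match(ids, df[[1L]])
  site_covs <- list()
  for (nm in names(df)[-1L]) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- is.na(v) & !(df[[nm]] %in% MISSING_TOKENS)
    if (any(bad)) {
      stopf("'%s': non-numeric value '%s' in covariate '%s' (site %s)",
            site_path, df[[nm]][bad][1L], nm, df[[1L]][bad][1L])
    }
    site_covs[[nm]] <- v[row]
  }
  occasion_covs <- list()
  if (!is.null(occasion_path)) {
    K <- n_occasions(histories)
    od <- read.csv(occasion_path, check.names = FALSE, strip.white = TRUE,
                   colClasses = "character", na.strings = character())
    if (!all(tolower(names(od)[1:2]) == c("site", "occasion"))) {
      stopf("'%s': first columns must be 'site,occasion'", occasion_path)
    }
    keep <- od[[1L]] %in% ids
    if (any(!keep)) {
      warnf("'%s': %d row(s) for unknown sites ignored", occasion_path,
            sum(!keep))
    }
    od <- od[keep, , drop = FALSE]
    occ <- suppressWarnings(as.integer(od[[2L]]))
    if (any(is.na(occ) | occ < 1L | occ > K)) {
      stopf("'%s': occasion indices must be integers in 1..%d", occasion_path, K)
    }
    ri <- match(od[[1L]], ids)
    for (nm in names(od)[-(1:2)]) {
      m <- matrix(NA_real_, length(ids), K)
      v <- suppressWarnings(as.numeric(od[[nm]]))
      bad <- is.na(v) & !(od[[nm]] %in% MISSING_TOKENS)
      if (any(bad)) {
        stopf("'%s': non-numeric value '%s' in covariate '%s'",
              occasion_path, od[[nm]][bad][1L], nm)
      }
      m[cbind(ri, occ)] <- v
      occasion_covs[[nm]] <- m
    }
  }
  covariate_bundle(site_covs, occasion_covs, ids)
}

#' Model specifications
#'
#' A model specification names the covariate terms entering the persistence
#' (psi) and detection (p) linear predictors.  Empty term lists denote
#' intercept-only structures, written `psi(.)` / `p(.)`.
#'
#' @param psi_terms character vector of site-covariate names for psi.
#' @param p_terms character vector of site- or occasion-covariate names for p.
#' @param name optional model label; derived from the terms if omitted.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("Develop", character())
#' @export
model_spec <- function(psi_terms = character(), p_terms = character(),
                       name = NULL) {
  psi_terms <- as.character(psi_terms)
  p_terms <- as.character(p_terms)
  if (anyDuplicated(psi_terms)) stopf("duplicate psi terms")
  if (anyDuplicated(p_terms)) stopf("duplicate p terms")
  if (is.null(name)) {
    name <- sprintf("psi(%s) p(%s)",
                    if (length(psi_terms)) paste(psi_terms, collapse = "+") else ".",
                    if (length(p_terms)) paste(p_terms, collapse = "+") else ".")
  }
  structure(list(name = name, psi_terms = psi_terms, p_terms = p_terms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$name, "\n")
  invisible(x)
}

#' @rdname model_spec
#' @param path JSON file with fields `name` (optional), `psi`, `p`.
#' @export
read_model_spec_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  model_spec(psi_terms = unlist(j$psi) %||% character(),
             p_terms = unlist(j$p) %||% character(),
             name = j$name %||% NULL)
}

# Check that all terms referenced by a spec resolve in the bundle, and that
# no referenced covariate is missing where y is surveyed.
validate_spec_against <- function(spec, bundle, histories) {
  obs <- !is.na(histories$y)
  for (t in spec$psi_terms) {
    v <- get_covariate(bundle, t, level = "site")
    if (any(is.na(v$value[rowSums(obs) > 0]))) {
      stopf("site covariate '%s' has missing values at surveyed sites", t)
    }
  }
  for (t in spec$p_terms) {
    v <- get_covariate(bundle, t)
    if (v$level == "occasion" && any(is.na(v$value[obs]))) {
      stopf("occasion covariate '%s' missing at surveyed (site, occasion) cells", t)
    }
    if (v$level == "site" && any(is.na(v$value[rowSums(obs) > 0]))) {
      stopf("site covariate '%s' has missing values at surveyed sites", t)
    }
  }
  invisible(TRUE)
}
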