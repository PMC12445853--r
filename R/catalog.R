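## Machine-readable catalog of reviewed leaf traits and their response
## timescales, with query helpers.

TRAIT_CATEGORIES <- c("stomata_hydraulics", "photosynthetic_biochemistry",
                      "morphology_lifespan")
TRAIT_MECHANISMS <- c("physiological", "phenotypic", "evolutionary")

#' Timescale bands and their log10-second midpoints
#'
#' The ordered time bands used by the trait catalog, each mapped to a
#' representative midpoint in log10 seconds (minutes -> 1.8, weeks -> 5.8,
#' ...) so that band comparisons reduce to ordinary arithmetic.
#'
#' @return A data frame with columns \code{band} and \code{log10_seconds}.
#' @examples
#' timescale_bands()
#' @export
timescale_bands <- function() {
  data.frame(
    band = c("seconds", "minutes", "hours", "days", "weeks", "months",
             "years", "decades", "centuries", "millennia",
             "millions_of_years"),
    log10_seconds = c(0, 1.8, 3.6, 4.9, 5.8, 6.4, 7.5, 8.5, 9.5, 10.5, 13.5),
    stringsAsFactors = FALSE)
}

band_midpoint <- function(band) {
  tb <- timescale_bands()
  idx <- match(band, tb$band)
  if (anyNA(idx))
    stop("unknown timescale band(s): ",
         paste(unique(band[is.na(idx)]), collapse = ", "), call. = FALSE)
  tb$log10_seconds[idx]
}

split_set <- function(x) strsplit(x, "|", fixed = TRUE)

#' Load the leaf-trait catalog
#'
#' Reads the bundled catalog of the 17 reviewed leaf traits (or a
#' user-supplied replacement with the same schema) and validates it:
#' unique names, known category/mechanism/band values, non-empty mechanism
#' and category sets, and \code{timescale_min <= timescale_max} on the band
#' ordering.
#'
#' @param source Path to a catalog CSV; \code{NULL} (default) loads the
#'   bundled catalog.
#' @return A data frame of class \code{trait_catalog} with columns
#'   name, symbol, category, mechanisms (both \code{|}-separated sets),
#'   timescale_min, timescale_max, description, units, key_refs.
#' @examples
#' nrow(load_trait_catalog())  # 17
#' @export
load_trait_catalog <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "trait_catalog.csv", package = "leaflapse",
                          mustWork = TRUE)
  cat <- utils::read.csv(source, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("name", "symbol", "category", "mechanisms", "timescale_min",
                "timescale_max", "description", "units", "key_refs")
  missing <- setdiff(required, names(cat))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  problems <- character()
  dup <- cat$name[duplicated(cat$name)]
  if (length(dup))
    problems <- c(problems, paste0("duplicate name(s): ",
                                   paste(unique(dup), collapse = ", ")))
  for (i in seq_len(nrow(cat))) {
    cats <- split_set(cat$category[i])[[1]]
    mech <- split_set(cat$mechanisms[i])[[1]]
    if (!length(cats) || any(!nzchar(cats)) || !all(cats %in% TRAIT_CATEGORIES))
      problems <- c(problems, paste0(cat$name[i], ": invalid category '",
                                     cat$category[i], "'"))
    if (!length(mech) || any(!nzchar(mech)) || !all(mech %in% TRAIT_MECHANISMS))
      problems <- c(problems, paste0(cat$name[i], ": invalid mechanisms '",
                                     cat$mechanisms[i], "'"))
    ok_bands <- cat$timescale_min[i] %in% timescale_bands()$band &&
                cat$timescale_max[i] %in% timescale_bands()$band
    if (!ok_bands) {
      problems <- c(problems, paste0(cat$name[i], ": unknown timescale band"))
    } else if (band_midpoint(cat$timescale_min[i]) >
               band_midpoint(cat$timescale_max[i])) {
      problems <- c(problems, paste0(cat$name[i],
                                     ": timescale_min above timescale_max"))
    }
  }
  if (length(problems))
    stop("invalid trait catalog:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  class(cat) <- c("trait_catalog", "data.frame")
  cat
}

#' Traits able to respond within an elapsed time
#'
#' Subsets the catalog to traits whose fastest response band (midpoint in
#' log10 seconds) is within the elapsed time, operationalizing the timescale
#' review for model time-stepping. Monotone: a longer elapsed time never
#' drops a trait.
#'
#' @param elapsed_seconds Elapsed time, seconds (> 0).
#' @param catalog A catalog from [load_trait_catalog()].
#' @return The responsive subset of the catalog.
#' @examples
#' traits_responsive_within(10 * 60)$name  # includes gs, ci, psi_leaf
#' @export
traits_responsive_within <- function(elapsed_seconds,
                                     catalog = load_trait_catalog()) {
  if (!is.numeric(elapsed_seconds) || length(elapsed_seconds) != 1L ||
      !is.finite(elapsed_seconds) || elapsed_seconds <= 0)
    stop("elapsed_seconds must be a positive number", call. = FALSE)
  keep <- band_midpoint(catalog$timescale_min) <= log10(elapsed_seconds)
  catalog[keep, , drop = FALSE]
}

#' Query the trait catalog by category and/or mechanism
#'
#' Set-intersection semantics: a record matches a filter if the filter value
#' is an element of the record's (possibly dual) category or mechanism set.
#' With no filters the full catalog is returned; an impossible combination
#' returns an empty subset without error.
#'
#' @param category Optional; one of \code{"stomata_hydraulics"},
#'   \code{"photosynthetic_biochemistry"}, \code{"morphology_lifespan"}.
#' @param mechanism Optional; one of \code{"physiological"},
#'   \code{"phenotypic"}, \code{"evolutionary"}.
#' @param catalog A catalog from [load_trait_catalog()].
#' @return The matching subset of the catalog.
#' @examples
#' query_traits(category = "stomata_hydraulics",
#'              mechanism = "physiological")$name
#' @export
query_traits <- function(category = NULL, mechanism = NULL,
                         catalog = load_trait_catalog()) {
  keep <- rep(TRUE, nrow(catalog))
  if (!is.null(category)) {
    if (!category %in% TRAIT_CATEGORIES)
      stop("unknown category '", category, "'; valid: ",
           paste(TRAIT_CATEGORIES, collapse = ", "), call. = FALSE)
    keep <- keep & vapply(split_set(catalog$category),
                          function(s) category %in% s, logical(1))
  }
  if (!is.null(mechanism)) {
    if (!mechanism %in% TRAIT_MECHANISMS)
      stop("unknown mechanism '", mechanism, "'; valid: ",
           paste(TRAIT_MECHANISMS, collapse = ", "), call. = FALSE)
    keep <- keep & vapply(split_set(catalog$mechanisms),
                          function(s) mechanism %in% s, logical(1))
  }
  catalog[keep, , drop = FALSE]
}
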