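# Community sensitivity catalogue and geomorphological reference values.

#' Default community sensitivity catalogue
#'
#' Returns the shipped catalogue of the 19 CARLIT community categories with
#' their sensitivity levels (SL, 20 = most sensitive to 1 = least sensitive).
#' The catalogue is stored as a plain CSV under `inst/extdata` so that it can
#' be replaced by a regionally recalibrated table without touching code.
#'
#' @return A `community_catalog`: a data frame with columns `Community`
#'   (acronym), `Description`, `SL` (numeric sensitivity level) and `Zone`
#'   (`"mediolittoral"` for the trottoir category, `"infralittoral"`
#'   otherwise).
#' @seealso [read_sensitivity_catalog()] to load a custom table,
#'   [sensitivity_level()] for scoring labels.
#' @export
#' @examples
#' cat <- default_sensitivity_catalog()
#' cat[cat$Community == "CA5", ]
default_sensitivity_catalog <- function() {
  path <- system.file("extdata", "sensitivity_levels.csv", package = "carlites",
                      mustWork = TRUE)
  read_sensitivity_catalog(path)
}

#' Read a community sensitivity table
#'
#' @param path CSV file with columns `Community`, `Description`, `SL` and
#'   optionally `Zone`.
#' @return A `community_catalog` data frame.
#' @export
read_sensitivity_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("Community", "Description", "SL")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sensitivity table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"Zone" %in% names(df)) df$Zone <- "infralittoral"
  df$Community <- trimws(df$Community)
  df$SL <- as.numeric(df$SL)
  if (anyDuplicated(toupper(df$Community))) {
    stop("duplicated community acronyms in sensitivity table", call. = FALSE)
  }
  if (any(!is.finite(df$SL)) || any(df$SL < 1) || any(df$SL > 20)) {
    stop("sensitivity levels must be finite and in [1, 20]", call. = FALSE)
  }
  class(df) <- c("community_catalog", "data.frame")
  df
}

#' Default geomorphological reference values (EQi)
#'
#' The six geomorphological relevant situations (GRS) — the cross of coastal
#' morphology (decimetric blocks, low coast, high coast) and substrate
#' (natural, artificial) — each carry a reference ecological quality value
#' EQi measured at reference (unimpacted) sites.  Sector quality ratios are
#' computed against the EQi of the sector's GRS.
#'
#' @return A `grs_reference` data frame with columns `GRS`, `Morphology`,
#'   `NatArt`, `EQi`.
#' @export
default_reference_eqi <- function() {
  path <- system.file("extdata", "reference_eqi.csv", package = "carlites",
                      mustWork = TRUE)
  read_reference_eqi(path)
}

#' Read a GRS reference table
#'
#' @param path CSV file with columns `GRS`, `Morphology`, `NatArt`, `EQi`.
#' @return A `grs_reference` data frame.
#' @export
read_reference_eqi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("GRS", "Morphology", "NatArt", "EQi")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("reference table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$EQi <- as.numeric(df$EQi)
  if (any(!is.finite(df$EQi)) || any(df$EQi <= 0)) {
    stop("EQi reference values must be positive", call. = FALSE)
  }
  key <- paste(tolower(trimws(df$Morphology)), tolower(trimws(df$NatArt)))
  if (anyDuplicated(key)) {
    stop("duplicated (Morphology, NatArt) pair in reference table", call. = FALSE)
  }
  class(df) <- c("grs_reference", "data.frame")
  df
}

#' Parse a community label into catalogue categories
#'
#' Sector labels record the dominant community category; sectors equally
#' dominated by two categories are recorded as a compound label joined by
#' `"+"` (e.g. `"Cor+Mgal"` for co-dominance of Corallina and mussels).
#' Matching is case-insensitive after trimming whitespace.
#'
#' @param label Character scalar, e.g. `"CA5"` or `"Cor+Mgal"`.
#' @param catalog A `community_catalog`; defaults to the shipped table.
#' @return Character vector of canonical acronyms, in the order given.
#' @export
#' @examples
#' parse_community_label("Cor+Mgal")
parse_community_label <- function(label, catalog = default_sensitivity_catalog()) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label))) {
    stop("community label must be a single non-empty string", call. = FALSE)
  }
  parts <- trimws(strsplit(label, "+", fixed = TRUE)[[1L]])
  if (any(!nzchar(parts))) {
    stop("malformed community label: ", sQuote(label), call. = FALSE)
  }
  idx <- match(toupper(parts), toupper(catalog$Community))
  if (anyNA(idx)) {
    bad <- parts[is.na(idx)]
    stop("unknown community acronym(s): ", paste(sQuote(bad), collapse = ", "),
         " in label ", sQuote(label), call. = FALSE)
  }
  catalog$Community[idx]
}

#' Sensitivity level of a (possibly compound) community label
#'
#' A single category scores its catalogue SL.  A sector equally dominated by
#' two categories scores the arithmetic mean of the two SLs (e.g. Cor+Mgal:
#' (8 + 6) / 2 = 7).  Labels carrying rare scattered *Cystoseira amentacea*
#' over a dominant community (`"CA1+<dominant>"`) are scored by the same
#' averaging rule.  Labels with more than two components are averaged over
#' all components with a warning, since field protocols only define pairs.
#'
#' @inheritParams parse_community_label
#' @return Numeric sensitivity level.
#' @export
#' @examples
#' sensitivity_level("Cor+Mgal")  # 7
#' sensitivity_level("CA5")       # 20
sensitivity_level <- function(label, catalog = default_sensitivity_catalog()) {
  parts <- parse_community_label(label, catalog)
  if (length(parts) > 2L) {
    warning("label ", sQuote(label), " has ", length(parts),
            " components; averaging over all of them (the co-dominance rule ",
            "is only defined for pairs)", call. = FALSE)
  }
  sl <- catalog$SL[match(parts, catalog$Community)]
  mean(sl)
}

#' Reference EQi for a coastal morphology and substrate
#'
#' @param morphology One of `"Decimetric blocks"`, `"Low coast"`,
#'   `"High coast"` (case-insensitive).
#' @param substrate `"Natural"` or `"Artificial"` (case-insensitive).
#' @param refs A `grs_reference` table; defaults to the shipped values.
#' @return The positive reference value EQi of the matching GRS.
#' @export
#' @examples
#' reference_eq("Low coast", "Natural")  # 16.6
reference_eq <- function(morphology, substrate, refs = default_reference_eqi()) {
  key <- paste(tolower(trimws(refs$Morphology)), tolower(trimws(refs$NatArt)))
  want <- paste(tolower(trimws(morphology)), tolower(trimws(substrate)))
  idx <- match(want, key)
  if (anyNA(idx)) {
    bad <- want[is.na(idx)]
    stop("no geomorphological relevant situation for: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  refs$EQi[idx]
}
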