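# Sector quality ratios, length-weighted water-body EQR, WFD classification,
# community dominance profiles and intra-seasonal consistency.

#' WFD rating scale for EQR values
#'
#' Builds the five-class rating scale used to translate an Ecological Quality
#' Ratio into a Water Framework Directive ecological-status class.  The
#' default cut points partition \[0, 1\] as: bad \[0, 0.25\],
#' poor (0.25, 0.40\], moderate (0.40, 0.60\], good (0.60, 0.75\],
#' high (0.75, 1\].  Boundaries belong to the lower class.
#'
#' @param boundaries Strictly increasing internal cut points in (0, 1).
#' @param classes Class names, ordered worst to best; one more than
#'   `boundaries`.
#' @return A `rating_scale` object.
#' @export
rating_scale <- function(boundaries = c(0.25, 0.40, 0.60, 0.75),
                         classes = c("bad", "poor", "moderate", "good", "high")) {
  boundaries <- as.numeric(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries <= 0) || any(boundaries >= 1)) {
    stop("boundaries must be strictly increasing and inside (0, 1)", call. = FALSE)
  }
  if (length(classes) != length(boundaries) + 1L) {
    stop("need exactly one more class name than boundaries", call. = FALSE)
  }
  structure(list(boundaries = boundaries, classes = as.character(classes)),
            class = "rating_scale")
}

#' Quality ratio of one survey sector
#'
#' The elementary CARLIT quantity: the sensitivity level of the sector's
#' dominant community divided by the reference value EQi of the sector's
#' geomorphological relevant situation.  The ratio may exceed 1 (SL 20 on a
#' low natural coast with EQi 16.6 gives 1.2048...); capping is applied at
#' the water-body level, not here.
#'
#' @param community Community label (possibly compound, e.g. `"CC+Cor"`).
#' @param morphology,substrate Sector geomorphology, see [reference_eq()].
#' @param catalog Sensitivity catalogue.
#' @param refs GRS reference table.
#' @return Numeric ratio SL / EQi.
#' @export
sector_quality_ratio <- function(community, morphology, substrate,
                                 catalog = default_sensitivity_catalog(),
                                 refs = default_reference_eqi()) {
  sl <- vapply(community, sensitivity_level, numeric(1), catalog = catalog,
               USE.NAMES = FALSE)
  eqi <- reference_eq(morphology, substrate, refs)
  sl / eqi
}

#' Length-weighted EQR of a water body
#'
#' Aggregates sector quality ratios into the water-body Ecological Quality
#' Ratio: the length-weighted mean of per-sector SL/EQi ratios over all
#' sectors of the water body, optionally capped at 1.  Each sector is scored
#' against its own geomorphological reference, so mixed-morphology water
#' bodies aggregate cleanly.
#'
#' @param sectors Survey data frame with columns `Site`, `Morphology`,
#'   `NatArt`, `Length`, `Community` (one water body; mixed `Site` values
#'   are an error).
#' @param catalog Sensitivity catalogue.
#' @param refs GRS reference table.
#' @param cap Cap the aggregated EQR at 1 (default `TRUE`; the ratio scale
#'   is defined on \[0, 1\]).
#' @param cap_sectors Cap each per-sector ratio at 1 before averaging
#'   (default `FALSE`; the conventional computation caps only the
#'   aggregate).
#' @param scale Rating scale used for the ES class.
#' @return An `eqr_result` list: `site`, `eqr`, `es_class`, `total_length`,
#'   and `sector_ratios` (per-sector SL, EQi, ratio and length weight).
#' @export
#' @examples
#' s <- data.frame(Site = "WB1", Morphology = "Low coast", NatArt = "Natural",
#'                 Length = c(100, 50), Community = c("CA1", "CC"))
#' waterbody_eqr(s)
waterbody_eqr <- function(sectors,
                          catalog = default_sensitivity_catalog(),
                          refs = default_reference_eqi(),
                          cap = TRUE, cap_sectors = FALSE,
                          scale = rating_scale()) {
  sectors <- validate_survey(sectors, refs = refs)
  site <- unique(sectors$Site)
  if (length(site) != 1L) {
    stop("waterbody_eqr() expects sectors from a single water body; got sites: ",
         paste(sQuote(site), collapse = ", "), call. = FALSE)
  }
  sl <- vapply(seq_len(nrow(sectors)), function(i) {
    tryCatch(sensitivity_level(sectors$Community[i], catalog),
             error = function(e) stop("sector ", i, " (site ", site, "): ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  eqi <- reference_eq(sectors$Morphology, sectors$NatArt, refs)
  ratio <- sl / eqi
  if (cap_sectors) ratio <- pmin(ratio, 1)
  w <- sectors$Length / sum(sectors$Length)
  eqr <- sum(ratio * w)
  if (cap) eqr <- min(eqr, 1)
  structure(list(
    site = site,
    eqr = eqr,
    es_class = classify_es(min(eqr, 1), scale),
    total_length = sum(sectors$Length),
    sector_ratios = data.frame(
      Site = sectors$Site, Community = sectors$Community,
      Morphology = sectors$Morphology, NatArt = sectors$NatArt,
      Length = sectors$Length, SL = sl, EQi = eqi, ratio = ratio, weight = w,
      stringsAsFactors = FALSE)
  ), class = "eqr_result")
}

#' @export
print.eqr_result <- function(x, ...) {
  cat(sprintf("Water body %s: EQR = %.4f (%s), %d sectors, %.0f m surveyed\n",
              x$site, x$eqr, x$es_class, nrow(x$sector_ratios),
              x$total_length))
  invisible(x)
}

#' EQR for every water body in a survey
#'
#' @inheritParams waterbody_eqr
#' @return Data frame with one row per site: `Site`, `EQR`, `ES`,
#'   `TotalLength`, `Sectors`.
#' @export
survey_eqr <- function(sectors,
                       catalog = default_sensitivity_catalog(),
                       refs = default_reference_eqi(),
                       cap = TRUE, cap_sectors = FALSE,
                       scale = rating_scale()) {
  sectors <- validate_survey(sectors, refs = refs)
  res <- lapply(split(sectors, sectors$Site), waterbody_eqr,
                catalog = catalog, refs = refs, cap = cap,
                cap_sectors = cap_sectors, scale = scale)
  out <- data.frame(
    Site = vapply(res, `[[`, character(1), "site"),
    EQR = vapply(res, `[[`, numeric(1), "eqr"),
    ES = vapply(res, `[[`, character(1), "es_class"),
    TotalLength = vapply(res, `[[`, numeric(1), "total_length"),
    Sectors = vapply(res, function(r) nrow(r$sector_ratios), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$Site), , drop = FALSE]
}

#' Ecological-status class of an EQR value
#'
#' @param eqr Numeric vector of EQR values in \[0, 1\].
#' @param scale A [rating_scale()].
#' @return Character vector of class names.
#' @export
#' @examples
#' classify_es(c(0.50, 0.61, 0.88))
classify_es <- function(eqr, scale = rating_scale()) {
  if (any(!is.finite(eqr)) || any(eqr < 0) || any(eqr > 1)) {
    stop("EQR values must lie in [0, 1]", call. = FALSE)
  }
  # boundaries belong to the lower class: bad is [0, b1], others (b, b']
  idx <- findInterval(eqr, scale$boundaries, left.open = TRUE) + 1L
  scale$classes[idx]
}

#' Community dominance profile of a survey
#'
#' Percent of surveyed coastline length dominated by each community label.
#' Compound co-dominance labels (e.g. `"CC+Cor"`) are kept as their own
#' category, mirroring how interannual dominance shifts are reported.
#'
#' @param sectors Survey data frame (one or more sites pooled as given).
#' @return Data frame with columns `Community`, `Length`, `Percent`, sorted
#'   by decreasing percent.  Percentages sum to 100.
#' @export
dominance_profile <- function(sectors) {
  if (!is.data.frame(sectors) || nrow(sectors) == 0L) {
    stop("need at least one sector", call. = FALSE)
  }
  if (!all(c("Length", "Community") %in% names(sectors))) {
    stop("sectors must have Length and Community columns", call. = FALSE)
  }
  len <- tapply(sectors$Length, sectors$Community, sum)
  out <- data.frame(Community = names(len), Length = as.numeric(len),
                    Percent = 100 * as.numeric(len) / sum(sectors$Length),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$Percent, out$Community), , drop = FALSE]
}

#' Intra-seasonal consistency of monthly status assessments
#'
#' Checks whether repeated assessments of one site within a season (e.g.
#' monthly from March to June) fall in the same ecological-status class.
#' Reports the modal class and the months deviating from it.  Ties on the
#' mode are broken by dropping the earliest month and recomputing until the
#' tie resolves (seasonal surveys treat later months, nearer the macroalgal
#' growth peak, as more representative); a tie is flagged in the output.
#'
#' @param classes Character vector of ES classes, in chronological order, or
#'   a list of `eqr_result` objects.
#' @param months Optional labels for the assessments (defaults to positions).
#' @return List with `consistent` (logical), `modal_class`,
#'   `deviating_months` (character vector) and `tie` (logical).
#' @export
#' @examples
#' intra_seasonal_consistency(c("good", "high", "high", "high"),
#'                            months = c("Mar", "Apr", "May", "Jun"))
intra_seasonal_consistency <- function(classes, months = NULL) {
  if (is.list(classes)) {
    classes <- vapply(classes, function(x) {
      if (inherits(x, "eqr_result")) x$es_class else as.character(x)
    }, character(1))
  }
  n <- length(classes)
  if (n < 2L) stop("need at least two assessments", call. = FALSE)
  if (is.null(months)) months <- as.character(seq_len(n))
  if (length(months) != n) stop("months must match classes in length", call. = FALSE)

  modal_of <- function(x) {
    tab <- table(x)
    names(tab)[tab == max(tab)]
  }
  modal <- modal_of(classes)
  tie <- length(modal) > 1L
  drop <- 1L
  while (length(modal) > 1L && drop < n) {
    modal <- modal_of(classes[(drop + 1L):n])
    drop <- drop + 1L
  }
  modal <- modal[length(modal)]  # last resort: latest class among those tied
  deviating <- months[classes != modal]
  list(consistent = length(deviating) == 0L,
       modal_class = modal,
       deviating_months = deviating,
       tie = tie)
}
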