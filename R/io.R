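# CSV readers/writers for the survey, panel and pressure dialects, plus an
# optional GeoJSON export.  All files are UTF-8, comma-separated, "." decimal.

survey_columns <- c("Site", "Morphology", "NatArt", "Length", "Community")

# shared validation for survey tables, with row numbers in every message
validate_survey <- function(sectors, refs = default_reference_eqi(),
                            where = "survey") {
  if (!is.data.frame(sectors) || nrow(sectors) == 0L) {
    stop(where, ": need at least one sector row", call. = FALSE)
  }
  missing <- setdiff(survey_columns, names(sectors))
  if (length(missing) > 0L) {
    stop(where, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sectors$Length <- as.numeric(sectors$Length)
  bad <- which(!is.finite(sectors$Length) | sectors$Length <= 0)
  if (length(bad) > 0L) {
    stop(where, ": Length must be a positive number; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(tolower(trimws(refs$Morphology)), tolower(trimws(refs$NatArt)))
  got <- paste(tolower(trimws(sectors$Morphology)),
               tolower(trimws(sectors$NatArt)))
  bad <- which(!(got %in% key))
  if (length(bad) > 0L) {
    stop(where, ": Morphology/NatArt not in the reference table; ",
         "offending row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  sectors
}

#' Read a sector survey table
#'
#' Reads the field-survey CSV dialect: columns `Site`, `Morphology`,
#' `NatArt`, `Length`, `Community` (any column order; names exact).  Extra
#' annotation columns other than `Area` are ignored with a warning.  Rows
#' failing validation are reported by row number.
#'
#' @param path CSV file path.
#' @param refs GRS reference table used to validate the geomorphology
#'   vocabulary.
#' @return Validated survey data frame.
#' @export
read_survey <- function(path, refs = default_reference_eqi()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  extra <- setdiff(names(df), c(survey_columns, "Area"))
  if (length(extra) > 0L) {
    warning("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  validate_survey(df, refs = refs, where = path)
}

#' Write a sector survey table
#'
#' @param sectors Survey data frame.
#' @param path Output CSV path.
#' @export
write_survey <- function(sectors, path) {
  utils::write.csv(sectors, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EQR panel (WB x Year x Surveyor)
#'
#' @param path CSV file with columns `WB`, `Year`, `Surveyor`, `EQR`.
#' @return Validated panel data frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_panel(df)
}

#' Read a pressure-component table
#'
#' @param path CSV file with columns `WB`, `Urb`, `Ind`, `Agr`, `FW`,
#'   `Coast` and optionally `MA-LUSI-WB` (passthrough metadata).
#' @return Data frame ready for [compute_lusi()].
#' @export
read_pressures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("WB", "Urb", "Ind", "Agr", "FW", "Coast")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(path, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Export survey sectors as GeoJSON
#'
#' Sectors are abstract one-dimensional stretches of coastline; for use in a
#' GIS they are laid out as consecutive LineStrings along the x axis (one
#' unit per metre, one row of y per site), each carrying its survey fields
#' and, when a catalogue is supplied, its SL/EQi/ratio diagnostics as
#' properties.  Purely a convenience export — nothing in the pipeline needs
#' geometry.
#'
#' @param sectors Survey data frame.
#' @param path Output file; when `NULL` the GeoJSON string is returned.
#' @param catalog,refs Optional catalogue/reference tables; when both are
#'   given, ratio diagnostics are attached to each feature.
#' @return `path` (invisibly) or the GeoJSON string.
#' @export
survey_to_geojson <- function(sectors, path = NULL, catalog = NULL,
                              refs = NULL) {
  sectors <- validate_survey(sectors, refs = if (is.null(refs))
    default_reference_eqi() else refs)
  sites <- unique(sectors$Site)
  feats <- vector("list", nrow(sectors))
  offset <- stats::setNames(rep(0, length(sites)), sites)
  for (i in seq_len(nrow(sectors))) {
    site <- sectors$Site[i]
    x0 <- offset[[site]]
    x1 <- x0 + sectors$Length[i]
    offset[[site]] <- x1
    y <- match(site, sites) * 100
    props <- as.list(sectors[i, , drop = FALSE])
    if (!is.null(catalog) && !is.null(refs)) {
      props$ratio <- sector_quality_ratio(sectors$Community[i],
                                          sectors$Morphology[i],
                                          sectors$NatArt[i],
                                          catalog = catalog, refs = refs)
    }
    feats[[i]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = list(c(x0, y), c(x1, y))),
      properties = props)
  }
  gj <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(gj)
  writeLines(gj, path)
  invisible(path)
}

# variance-component table in the conventional report layout
varcomp_table <- function(fit) {
  fr <- variance_fractions(fit, rounding = "integer")
  slope_names <- if (length(fit$var_wb_in_year) > 0)
    paste0("Year:", names(fit$var_wb_in_year)) else character(0)
  rows <- data.frame(
    Groups = c("WB", "Year", "Surveyor", slope_names, "Residual"),
    Std.dev. = sqrt(c(fit$var_wb, fit$var_year, fit$var_surveyor,
                      fit$var_wb_in_year, fit$var_residual)),
    Variance = c(fit$var_wb, fit$var_year, fit$var_surveyor,
                 fit$var_wb_in_year, fit$var_residual),
    P_samp = unname(c(fr[["wb"]], fr[["year"]], fr[["surveyor"]],
                      fr[grepl("^wb_in_year:", names(fr))],
                      fr[["residual"]])),
    stringsAsFactors = FALSE, row.names = NULL)
  rows
}
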