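# Land Uses Simplified Index (LUSI) for coastal anthropogenic pressure.

#' Land Uses Simplified Index
#'
#' LUSI summarises land-based anthropogenic pressure on a coastal water body
#' as the sum of four ordinal component scores — urban (`urb`), industrial
#' (`ind`), agricultural (`agr`) land use and freshwater inputs (`fw`) —
#' multiplied by a coastline-shape correction factor (0.75 for convex coast,
#' 1 for straight, a larger value for concave coast; the factor is accepted
#' as a number so regional calibrations can be supplied).
#'
#' @param urb,ind,agr,fw Non-negative integer component scores (vectorised).
#' @param coast_factor Positive coastline-shape multiplier.
#' @return Numeric LUSI value(s): `(urb + ind + agr + fw) * coast_factor`.
#' @export
#' @examples
#' lusi(1, 0, 2, 0, 0.75)  # 2.25
lusi <- function(urb, ind, agr, fw, coast_factor = 1) {
  scores <- cbind(urb, ind, agr, fw)
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop("pressure component scores must be non-negative numbers", call. = FALSE)
  }
  if (any(!is.finite(coast_factor)) || any(coast_factor <= 0)) {
    stop("coast_factor must be positive", call. = FALSE)
  }
  (urb + ind + agr + fw) * coast_factor
}

#' Add the computed LUSI column to a pressure table
#'
#' @param pressures Data frame with columns `WB`, `Urb`, `Ind`, `Agr`, `FW`,
#'   `Coast` and optionally `MA-LUSI-WB` (a mariculture-adjusted variant of
#'   LUSI; it is carried through as metadata, never computed here).
#' @return The input with a `LUSI` column appended (recomputed if present).
#' @export
compute_lusi <- function(pressures) {
  required <- c("WB", "Urb", "Ind", "Agr", "FW", "Coast")
  missing <- setdiff(required, names(pressures))
  if (length(missing) > 0L) {
    stop("pressure table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pressures$LUSI <- lusi(pressures$Urb, pressures$Ind, pressures$Agr,
                         pressures$FW, pressures$Coast)
  pressures
}
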