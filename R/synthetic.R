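# Seeded generators: survey cartographies with quality-conditioned community
# composition, and EQR panels drawn from the crossed random-effects model.

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# community categories a survey draws from (upper-infralittoral pool)
survey_pool <- c("CA5", "CA4", "CA3", "CA2", "CA1", "CC", "Cor", "EC",
                 "Mgal", "Ulva", "GA", "BG")

# softmax over sensitivity levels with inverse temperature b, numerically
# stable; b -> -Inf collapses on the least sensitive category, b -> +Inf on
# the most sensitive one
community_probs <- function(quality, sl) {
  target <- min(sl) + quality * (max(sl) - min(sl))
  if (quality <= 0) return(as.numeric(sl == min(sl)) / sum(sl == min(sl)))
  if (quality >= 1) return(as.numeric(sl == max(sl)) / sum(sl == max(sl)))
  esl <- function(b) {
    w <- exp(b * (sl - max(sl)))
    sum(sl * w) / sum(w)
  }
  lo <- -3; hi <- 3
  if (target <= esl(lo)) return(as.numeric(sl == min(sl)) / sum(sl == min(sl)))
  if (target >= esl(hi)) return(as.numeric(sl == max(sl)) / sum(sl == max(sl)))
  b <- stats::uniroot(function(b) esl(b) - target, c(lo, hi),
                      tol = 1e-10)$root
  w <- exp(b * (sl - max(sl)))
  w / sum(w)
}

#' Simulate a sector cartography survey
#'
#' Generates a synthetic rocky-shore survey: each water body is split into
#' three areas (West, Central, East) of `sectors_per_area` sectors of
#' `sector_length` metres.  Each sector draws a geomorphological relevant
#' situation from `grs_mix` and a dominant community from a multinomial over
#' the upper-infralittoral categories whose probabilities are a softmax over
#' sensitivity levels: the softmax temperature is solved so that the
#' expected SL equals `1 + quality * 19`, making the expected sector ratio
#' increase monotonically with the latent quality.  `quality` 0 and 1 are
#' degenerate (all blue-greens, all continuous *Cystoseira* belt).
#'
#' @param wb_count Number of water bodies.
#' @param quality Latent quality in \[0, 1\]; scalar or one value per WB.
#' @param areas_per_wb Areas per water body (default 3: West/Central/East).
#' @param sectors_per_area Sectors per area (default 25; field protocols use
#'   20-30).
#' @param sector_length Sector length in metres (default 50).
#' @param grs_mix Probability over the six GRS ids of [default_reference_eqi()],
#'   in table order.  Default: predominantly natural low and high coast with
#'   small artificial and blocky fractions.
#' @param catalog Sensitivity catalogue (SLs drive the composition model).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return Survey data frame with columns `Site`, `Area`, `Morphology`,
#'   `NatArt`, `Length`, `Community`.
#' @export
#' @examples
#' sv <- simulate_survey(wb_count = 2, quality = c(0.9, 0.4), seed = 42)
#' survey_eqr(sv)
simulate_survey <- function(wb_count = 1, quality = 0.8, areas_per_wb = 3,
                            sectors_per_area = 25, sector_length = 50,
                            grs_mix = c(0.05, 0.40, 0.35, 0.02, 0.10, 0.08),
                            catalog = default_sensitivity_catalog(),
                            seed = NULL) {
  stopifnot(wb_count >= 1, areas_per_wb >= 1, sectors_per_area >= 1,
            sector_length > 0)
  if (any(quality < 0) || any(quality > 1)) {
    stop("quality must lie in [0, 1]", call. = FALSE)
  }
  quality <- rep_len(quality, wb_count)
  refs <- default_reference_eqi()
  if (length(grs_mix) != nrow(refs) || any(grs_mix < 0) ||
      abs(sum(grs_mix) - 1) > 1e-8) {
    stop("grs_mix must be ", nrow(refs),
         " non-negative weights summing to 1", call. = FALSE)
  }
  pool <- survey_pool
  sl <- catalog$SL[match(pool, catalog$Community)]
  area_names <- if (areas_per_wb == 3) c("West", "Central", "East")
                else paste0("A", seq_len(areas_per_wb))
  n_sec <- areas_per_wb * sectors_per_area

  with_seed(seed, {
    rows <- lapply(seq_len(wb_count), function(w) {
      p <- community_probs(quality[w], sl)
      grs <- sample.int(nrow(refs), n_sec, replace = TRUE, prob = grs_mix)
      data.frame(
        Site = sprintf("WB%02d", w),
        Area = rep(area_names, each = sectors_per_area),
        Morphology = refs$Morphology[grs],
        NatArt = refs$NatArt[grs],
        Length = sector_length,
        Community = pool[sample.int(length(pool), n_sec, replace = TRUE,
                                    prob = p)],
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate an EQR panel from the crossed random-effects model
#'
#' Draws a water-body x year panel of EQR values from the generative form of
#' the variance-partitioning model fitted by [fit_reml()]:
#' `EQR = mu + u_wb + w_year + s_surveyor + b_(wb, year) + e`, all
#' components independent zero-mean Gaussians.  Surveyors are assigned to
#' contiguous blocks of campaign years (a surveyor runs several consecutive
#' campaigns), so surveyor is crossed with WB and aligned with year blocks.
#'
#' @param n_wb,n_year,n_surveyor Panel dimensions.  Defaults mirror a
#'   regional monitoring design: 7 water bodies, 4 campaign years, 2
#'   surveyors.
#' @param grand_mean Mean EQR level (default 0.7, a good-status coastline).
#' @param var_wb,var_year,var_surveyor Variances of the crossed intercepts.
#'   Defaults put almost all variance between water bodies
#'   (`var_wb = 0.03`) with none across years or surveyors.
#' @param var_wb_in_year Per-WB year-to-year variance; scalar or one value
#'   per WB (default 0).
#' @param var_residual Residual variance (default 0.004).
#' @param clip_to_unit Clip simulated values into \[0, 1\] (default `FALSE`:
#'   clipping truncates the Gaussian components and biases downstream
#'   variance estimates; a warning is issued when values are clipped).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return Panel data frame with columns `WB`, `Year`, `Surveyor`, `EQR`.
#' @export
#' @examples
#' panel <- simulate_eqr_panel(seed = 7)
#' head(panel)
simulate_eqr_panel <- function(n_wb = 7, n_year = 4, n_surveyor = 2,
                               grand_mean = 0.7,
                               var_wb = 0.03, var_year = 0, var_surveyor = 0,
                               var_wb_in_year = 0, var_residual = 0.004,
                               clip_to_unit = FALSE, seed = NULL) {
  stopifnot(n_wb >= 1, n_year >= 1, n_surveyor >= 1)
  vars <- c(var_wb, var_year, var_surveyor, var_wb_in_year, var_residual)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop("variances must be finite and non-negative", call. = FALSE)
  }
  var_wb_in_year <- rep_len(var_wb_in_year, n_wb)
  wb_levels <- sprintf("WB%02d", seq_len(n_wb))
  year_levels <- seq_len(n_year)
  # contiguous year blocks per surveyor
  surv_of_year <- ceiling(year_levels / (n_year / n_surveyor))
  surv_of_year <- pmin(surv_of_year, n_surveyor)

  with_seed(seed, {
    u_wb <- stats::rnorm(n_wb, 0, sqrt(var_wb))
    w_year <- stats::rnorm(n_year, 0, sqrt(var_year))
    s_surv <- stats::rnorm(n_surveyor, 0, sqrt(var_surveyor))
    grid <- expand.grid(wb = seq_len(n_wb), year = seq_len(n_year))
    b <- stats::rnorm(nrow(grid), 0, sqrt(var_wb_in_year[grid$wb]))
    eps <- stats::rnorm(nrow(grid), 0, sqrt(var_residual))
    eqr <- grand_mean + u_wb[grid$wb] + w_year[grid$year] +
      s_surv[surv_of_year[grid$year]] + b + eps
    if (clip_to_unit) {
      n_clip <- sum(eqr < 0 | eqr > 1)
      if (n_clip > 0) {
        warning(n_clip, " simulated EQR value(s) clipped into [0, 1]; ",
                "clipping biases variance-component estimates", call. = FALSE)
      }
      eqr <- pmin(pmax(eqr, 0), 1)
    }
    data.frame(WB = wb_levels[grid$wb],
               Year = sprintf("Y%02d", grid$year),
               Surveyor = sprintf("S%d", surv_of_year[grid$year]),
               EQR = eqr, stringsAsFactors = FALSE)
  })
}
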