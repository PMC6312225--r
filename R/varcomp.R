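# REML estimation of crossed variance components for EQR panels, and the
# P_samp variance partitioning built on top of it.
#
# The model is a Gaussian variance-components model
#   eqr = mu + u_surveyor + v_wb + w_year + s_(wb, year) + e
# with independent components; the per-water-body year effects s use a
# diagonal covariance (one variance per WB).  Estimation maximises the
# restricted likelihood directly: the criterion and its analytic gradient
# are evaluated through the Woodbury identity, so each evaluation costs
# O(q^3) in the total number of random-effect levels q, not O(n^3).

panel_columns <- c("WB", "Year", "Surveyor", "EQR")

validate_panel <- function(panel) {
  if (!is.data.frame(panel)) stop("panel must be a data frame", call. = FALSE)
  missing <- setdiff(panel_columns, names(panel))
  if (length(missing) > 0L) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  panel$EQR <- as.numeric(panel$EQR)
  if (any(!is.finite(panel$EQR))) {
    stop("panel EQR values must be finite numbers", call. = FALSE)
  }
  for (col in c("WB", "Year", "Surveyor")) panel[[col]] <- factor(panel[[col]])
  panel
}

# Build the list of random-effect indicator matrices for a structure.
# "wb_in_year" expands into one component per WB level (a year-level effect
# switched on only for that WB's rows) — the diagonal random-slope layout.
build_design <- function(panel, structure) {
  known <- c("wb", "year", "surveyor", "wb_in_year")
  bad <- setdiff(structure, known)
  if (length(bad) > 0L) {
    stop("unknown structure term(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  fac <- list(wb = panel$WB, year = panel$Year, surveyor = panel$Surveyor)
  Z <- list()
  for (term in intersect(c("wb", "year", "surveyor"), structure)) {
    f <- droplevels(fac[[term]])
    if (nlevels(f) < 2L) {
      stop("factor ", sQuote(term), " needs at least 2 levels", call. = FALSE)
    }
    Z[[term]] <- stats::model.matrix(~ 0 + f)
  }
  if ("wb_in_year" %in% structure) {
    wb <- droplevels(panel$WB)
    yr <- droplevels(panel$Year)
    if (nlevels(yr) < 2L) {
      stop("factor 'year' needs at least 2 levels for wb_in_year", call. = FALSE)
    }
    if (!any(duplicated(paste(wb, yr)))) {
      warning("no replicated (WB, Year) cells: per-water-body year variances ",
              "are only weakly identified against the residual variance; ",
              "interpret these components with caution", call. = FALSE)
    }
    Y <- stats::model.matrix(~ 0 + yr)
    for (lev in levels(wb)) {
      Z[[paste0("wb_in_year:", lev)]] <- Y * as.numeric(wb == lev)
    }
  }
  # flag one-to-one aliased factor pairs (e.g. surveyor relabelling year)
  plain <- intersect(c("wb", "year", "surveyor"), structure)
  if (length(plain) > 1L) {
    for (i in seq_len(length(plain) - 1L)) for (j in (i + 1L):length(plain)) {
      a <- droplevels(fac[[plain[i]]]); b <- droplevels(fac[[plain[j]]])
      if (nlevels(a) == nlevels(b) &&
          nlevels(interaction(a, b, drop = TRUE)) == nlevels(a)) {
        warning("factors ", sQuote(plain[i]), " and ", sQuote(plain[j]),
                " are completely confounded; their variances are not ",
                "separately identifiable", call. = FALSE)
      }
    }
  }
  Z
}

# REML deviance (-2 restricted log-likelihood) and gradient on the
# log-variance scale.  `pre` carries the pre-computed cross-products.
reml_objective <- function(theta, pre) {
  s2 <- exp(theta)
  K <- length(s2) - 1L
  r2 <- s2[K + 1L]
  a <- 1 / r2
  d <- rep(s2[seq_len(K)], pre$qsizes)
  A <- a * pre$ZtZ
  diag(A) <- diag(A) + 1 / d
  cholA <- chol(A)
  logdetA <- 2 * sum(log(diag(cholA)))
  logdetV <- pre$n * log(r2) + sum(log(d)) + logdetA

  Ainv_Zty <- backsolve(cholA, forwardsolve(t(cholA), pre$Zty))
  Ainv_ZtX <- backsolve(cholA, forwardsolve(t(cholA), pre$ZtX))
  XtVX <- a * pre$XtX - a^2 * crossprod(pre$ZtX, Ainv_ZtX)
  XtVy <- a * pre$Xty - a^2 * crossprod(pre$ZtX, Ainv_Zty)
  ytVy <- a * pre$yty - a^2 * crossprod(pre$Zty, Ainv_Zty)
  cholX <- chol(XtVX)
  beta <- backsolve(cholX, forwardsolve(t(cholX), XtVy))
  quad <- drop(ytVy - crossprod(beta, XtVy))
  dev <- drop(logdetV + 2 * sum(log(diag(cholX))) + quad +
              (pre$n - pre$p) * log(2 * pi))

  # gradient: d dev / d sigma2_k = tr(P Gk) - u' Gk u, chain-ruled to logs
  Ainv_ZtZ <- backsolve(cholA, forwardsolve(t(cholA), pre$ZtZ))
  W <- a * pre$ZtZ - a^2 * pre$ZtZ %*% Ainv_ZtZ          # Z' Vinv Z
  XtVZ <- a * t(pre$ZtX) - a^2 * crossprod(pre$ZtX, Ainv_ZtZ)  # p x q
  XtVXinv_XtVZ <- backsolve(cholX, forwardsolve(t(cholX), XtVZ))
  trPZZ_diag <- diag(W) - colSums(XtVZ * XtVXinv_XtVZ)   # diag of Z'PZ

  Vinv_y <- a * pre$y - a^2 * (pre$Z %*% Ainv_Zty)
  Vinv_X <- a * pre$X - a^2 * (pre$Z %*% Ainv_ZtX)
  u <- drop(Vinv_y - Vinv_X %*% beta)                    # P y
  Ztu <- drop(crossprod(pre$Z, u))

  grp <- rep(seq_len(K), pre$qsizes)
  grad <- numeric(K + 1L)
  for (k in seq_len(K)) {
    idx <- grp == k
    grad[k] <- sum(trPZZ_diag[idx]) - sum(Ztu[idx]^2)
  }
  trVinv <- a * pre$n - a^2 * sum(diag(Ainv_ZtZ))
  trP <- trVinv - sum(diag(backsolve(cholX, forwardsolve(t(cholX),
                                                         crossprod(Vinv_X)))))
  grad[K + 1L] <- trP - sum(u^2)
  list(dev = dev, grad = grad * s2, beta = drop(beta), u = u)
}

#' Fit a crossed random-effects model of EQR by REML
#'
#' Estimates the variance components of the Gaussian model
#' `EQR = mu + surveyor + WB + year + WB-within-year + residual` (or any
#' subset of those terms) by restricted maximum likelihood.  The
#' WB-within-year term gives every water body its own year-to-year variance
#' (diagonal covariance), which is what a per-water-body partition of
#' interannual variability reports.  Optimisation runs a bounded
#' quasi-Newton search on the log-variance scale with analytic gradients
#' from three fixed starting points, so boundary estimates (a variance of
#' exactly zero) are reachable; estimates below `1e-7 * var(EQR)` are
#' reported as exactly 0.
#'
#' @param panel Data frame with columns `WB`, `Year`, `Surveyor`, `EQR`.
#' @param structure Character vector of random terms to retain, a subset of
#'   `c("wb", "year", "surveyor", "wb_in_year")`.
#' @return A `carlit_varcomp` object: `grand_mean`, `var_wb`, `var_year`,
#'   `var_surveyor`, `var_wb_in_year` (named vector, one entry per WB),
#'   `var_residual`, `total`, `fractions` (P_samp percentages, unrounded),
#'   `criterion` (REML deviance, -2 restricted log-likelihood), `aic`,
#'   `npar`, `converged`, plus the data needed by [residuals_vs_fitted()].
#' @seealso [variance_fractions()], [residuals_vs_fitted()],
#'   [compare_models()], [simulate_eqr_panel()]
#' @export
#' @examples
#' panel <- simulate_eqr_panel(n_wb = 8, n_year = 6, var_wb = 0.02,
#'                             var_residual = 0.004, seed = 1)
#' fit <- fit_reml(panel, structure = c("wb", "year", "surveyor"))
#' round(fit$fractions)
fit_reml <- function(panel,
                     structure = c("wb", "year", "surveyor", "wb_in_year")) {
  panel <- validate_panel(panel)
  y <- panel$EQR
  n <- length(y)
  X <- matrix(1, n, 1)
  vy <- stats::var(y)

  Zlist <- build_design(panel, structure)
  K <- length(Zlist)
  comp_names <- names(Zlist)

  if (vy == 0) {
    # constant response: every component sits at the zero boundary
    s2 <- stats::setNames(numeric(K + 1L), c(comp_names, "residual"))
    return(new_varcomp(mean(y), s2, comp_names, panel, Zlist,
                       criterion = NA_real_, converged = TRUE,
                       note = "constant response", structure = structure))
  }

  Z <- do.call(cbind, Zlist)
  pre <- list(
    n = n, p = ncol(X), y = y, X = X, Z = Z,
    qsizes = vapply(Zlist, ncol, integer(1)),
    ZtZ = crossprod(Z), ZtX = crossprod(Z, X), Zty = drop(crossprod(Z, y)),
    XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2))

  starts <- list(rep(vy / (K + 1), K + 1L),
                 c(rep(0.1 * vy / K, K), 0.9 * vy),
                 c(rep(0.9 * vy / K, K), 0.1 * vy))
  lower <- log(1e-12 * vy)
  upper <- log(100 * vy)
  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(
      par = pmin(pmax(log(s), lower), upper),
      fn = function(th) reml_objective(th, pre)$dev,
      gr = function(th) reml_objective(th, pre)$grad,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(factr = 1e2, pgtol = 0, maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
  }
  if (is.null(best)) {
    stop("REML optimisation failed to converge from any start", call. = FALSE)
  }

  s2 <- exp(best$par)
  s2[s2 < 1e-7 * vy] <- 0
  names(s2) <- c(comp_names, "residual")
  final <- reml_objective(pmax(log(pmax(s2, 1e-12 * vy)), lower), pre)
  new_varcomp(final$beta, s2, comp_names, panel, Zlist,
              criterion = best$value, converged = best$convergence == 0,
              note = best$message, structure = structure)
}

new_varcomp <- function(grand_mean, s2, comp_names, panel = NULL, Zlist = NULL,
                        criterion = NA_real_, converged = NA, note = NULL,
                        structure = NULL) {
  slope_idx <- grepl("^wb_in_year:", comp_names)
  slopes <- s2[comp_names[slope_idx]]
  names(slopes) <- sub("^wb_in_year:", "", names(slopes))
  out <- list(
    grand_mean = unname(grand_mean),
    var_wb = unname(if ("wb" %in% comp_names) s2[["wb"]] else 0),
    var_year = unname(if ("year" %in% comp_names) s2[["year"]] else 0),
    var_surveyor = unname(if ("surveyor" %in% comp_names) s2[["surveyor"]] else 0),
    var_wb_in_year = slopes,
    var_residual = unname(s2[["residual"]]),
    criterion = criterion,
    npar = length(s2) + 1L,  # variances + grand mean
    converged = converged,
    note = note,
    structure = structure,
    panel = panel,
    Zlist = Zlist,
    s2 = s2)
  out$total <- out$var_wb + out$var_year + out$var_surveyor +
    sum(out$var_wb_in_year) + out$var_residual
  out$aic <- if (is.na(criterion)) NA_real_ else criterion + 2 * out$npar
  class(out) <- "carlit_varcomp"
  out$fractions <- if (out$total > 0) variance_fractions(out) else NULL
  out
}

#' Assemble variance components by hand
#'
#' Builds a `carlit_varcomp` object from known variance values, e.g. from a
#' published variance-decomposition table, so that [variance_fractions()]
#' can be applied without refitting.
#'
#' @param var_wb,var_year,var_surveyor,var_residual Non-negative variances.
#' @param var_wb_in_year Named numeric vector of per-WB year variances.
#' @param grand_mean Optional grand mean.
#' @return A `carlit_varcomp` object.
#' @export
variance_components <- function(var_wb = 0, var_year = 0, var_surveyor = 0,
                                var_wb_in_year = numeric(0), var_residual = 0,
                                grand_mean = NA_real_) {
  vals <- c(var_wb, var_year, var_surveyor, var_wb_in_year, var_residual)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("variances must be finite and non-negative", call. = FALSE)
  }
  if (length(var_wb_in_year) > 0 && is.null(names(var_wb_in_year))) {
    names(var_wb_in_year) <- paste0("WB", seq_along(var_wb_in_year))
  }
  slopes <- if (length(var_wb_in_year) > 0)
    stats::setNames(var_wb_in_year,
                    paste0("wb_in_year:", names(var_wb_in_year)))
  else NULL
  s2 <- c(wb = var_wb, year = var_year, surveyor = var_surveyor, slopes,
          residual = var_residual)
  comp_names <- setdiff(names(s2), "residual")
  new_varcomp(grand_mean, s2, comp_names, converged = NA)
}

#' P_samp: percentage of total variance per component
#'
#' For each variance component x, computes `P_samp = 100 * s2_x / s2_T`
#' where the total `s2_T` is the sum of all component variances including
#' the residual.  Presentation rounding to integer percent uses
#' round-half-away-from-zero.
#'
#' @param components A `carlit_varcomp` from [fit_reml()] or
#'   [variance_components()].
#' @param rounding `"none"` (default) for raw percentages or `"integer"`
#'   for whole-percent presentation.
#' @return Named numeric vector of percentages (`wb`, `year`, `surveyor`,
#'   one `wb_in_year:` entry per WB, `residual`), summing to 100.
#' @export
variance_fractions <- function(components, rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(components, "carlit_varcomp"))
  x <- components
  total <- x$var_wb + x$var_year + x$var_surveyor +
    sum(x$var_wb_in_year) + x$var_residual
  if (total <= 0) {
    stop("total variance is zero: fractions are undefined", call. = FALSE)
  }
  vals <- c(wb = x$var_wb, year = x$var_year, surveyor = x$var_surveyor,
            stats::setNames(x$var_wb_in_year,
                            if (length(x$var_wb_in_year))
                              paste0("wb_in_year:", names(x$var_wb_in_year))
                            else character(0)),
            residual = x$var_residual)
  pct <- 100 * vals / total
  if (rounding == "integer") pct <- round_half_away(pct)
  pct
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Conditional residuals against fitted values
#'
#' Computes best linear unbiased predictions (BLUPs) of the random effects
#' under the fitted variances, and returns the conditional fitted values
#' (grand mean plus predicted random effects) paired with the residuals
#' `EQR - fitted`.  The standard model-validation plot is
#' `plot(rf$fitted, rf$residual)`.
#'
#' @param fit A `carlit_varcomp` returned by [fit_reml()].
#' @return Data frame with columns `fitted` and `residual`.
#' @export
residuals_vs_fitted <- function(fit) {
  stopifnot(inherits(fit, "carlit_varcomp"))
  if (is.null(fit$panel)) {
    stop("this object was built by hand and carries no data", call. = FALSE)
  }
  y <- fit$panel$EQR
  n <- length(y)
  mu <- fit$grand_mean
  s2 <- fit$s2
  K <- length(s2) - 1L
  r2 <- s2[["residual"]]
  if (K == 0L || all(s2[seq_len(K)] == 0)) {
    return(data.frame(fitted = rep(mu, n), residual = y - mu))
  }
  keep <- which(s2[seq_len(K)] > 0)
  Z <- do.call(cbind, fit$Zlist[keep])
  d <- rep(s2[keep], vapply(fit$Zlist[keep], ncol, integer(1)))
  r <- y - mu
  if (r2 == 0) {
    # V = Z D Z' singular in general; predict via ridge-free limit
    V <- Z %*% (d * t(Z))
    u <- d * drop(crossprod(Z, solve(V + 1e-12 * mean(d) * diag(n), r)))
  } else {
    a <- 1 / r2
    A <- a * crossprod(Z)
    diag(A) <- diag(A) + 1 / d
    u <- d * drop(a * crossprod(Z, r) -
                  a^2 * crossprod(Z, Z %*% solve(A, crossprod(Z, r))))
  }
  fitted <- mu + drop(Z %*% u)
  data.frame(fitted = fitted, residual = y - fitted)
}

#' Compare candidate random-effect structures by AIC
#'
#' Fits each candidate structure to the same panel by REML and ranks them by
#' the Akaike information criterion computed from the REML criterion
#' (`-2 restricted log-likelihood + 2 * npar`).  Comparing random-effect
#' structures on REML fits is a pragmatic convention; the restricted
#' likelihoods of models with different fixed effects are not comparable,
#' but all candidates here share the single grand-mean fixed effect.
#' Candidates that fail to converge are ranked last and flagged.
#'
#' @param panel An EQR panel data frame.
#' @param structures List of character vectors, each a valid `structure`
#'   argument for [fit_reml()].
#' @return Data frame with `structure`, `npar`, `criterion`, `aic`,
#'   `converged`, `rank`, ordered best first; ties share a rank.
#' @export
compare_models <- function(panel, structures) {
  if (length(structures) < 2L) {
    stop("need at least two candidate structures", call. = FALSE)
  }
  rows <- lapply(structures, function(st) {
    fit <- tryCatch(suppressWarnings(fit_reml(panel, structure = st)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(structure = paste(st, collapse = "+"), npar = NA_integer_,
                 criterion = NA_real_, aic = NA_real_, converged = FALSE)
    } else {
      data.frame(structure = paste(st, collapse = "+"), npar = fit$npar,
                 criterion = fit$criterion, aic = fit$aic,
                 converged = isTRUE(fit$converged))
    }
  })
  out <- do.call(rbind, rows)
  key <- ifelse(out$converged, out$aic, Inf)
  out <- out[order(key), , drop = FALSE]
  out$rank <- rank(ifelse(out$converged, out$aic, Inf), ties.method = "min")[
    order(key)]
  rownames(out) <- NULL
  out
}

#' @export
print.carlit_varcomp <- function(x, ...) {
  cat("Variance components (REML)\n")
  if (!is.na(x$grand_mean)) cat(sprintf("  grand mean: %.4f\n", x$grand_mean))
  fr <- if (!is.null(x$fractions)) x$fractions else NULL
  show <- function(name, v) {
    p <- if (!is.null(fr)) sprintf("  P_samp %3.0f%%", fr[[name]]) else ""
    cat(sprintf("  %-28s %.6f%s\n", name, v, p))
  }
  show("wb", x$var_wb); show("year", x$var_year); show("surveyor", x$var_surveyor)
  for (nm in names(x$var_wb_in_year)) {
    show(paste0("wb_in_year:", nm), x$var_wb_in_year[[nm]])
  }
  show("residual", x$var_residual)
  cat(sprintf("  total                        %.6f\n", x$total))
  if (!is.na(x$criterion)) {
    cat(sprintf("  REML criterion %.4f  AIC %.4f  converged: %s\n",
                x$criterion, x$aic, x$converged))
  }
  invisible(x)
}
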