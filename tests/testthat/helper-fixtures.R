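# in-code fixtures shared across the suite

# a small mixed-geomorphology survey for one water body
make_survey <- function(site = "WB1",
                        communities = c("CA5", "Cor", "CC"),
                        lengths = c(50, 100, 50),
                        morphology = "Low coast",
                        natart = "Natural") {
  data.frame(Site = site,
             Morphology = morphology,
             NatArt = natart,
             Length = lengths,
             Community = communities,
             stringsAsFactors = FALSE)
}

# balanced one-way layout (g groups x r replicates) with fixed group effects
# and residuals, so the ANOVA moment estimator can be computed by hand
make_oneway_panel <- function(g = 7, r = 4, seed = 11,
                              sd_group = 0.15, sd_resid = 0.06) {
  set.seed(seed)
  grp <- rep(seq_len(g), each = r)
  y <- 0.7 + rnorm(g, 0, sd_group)[grp] + rnorm(g * r, 0, sd_resid)
  data.frame(WB = sprintf("W%02d", grp),
             Year = rep(sprintf("Y%d", seq_len(r)), g),
             Surveyor = "S1",
             EQR = y, stringsAsFactors = FALSE)
}

# closed-form balanced one-way ANOVA moment estimators (the REML oracle)
oneway_anova_oracle <- function(panel) {
  y <- panel$EQR
  g <- factor(panel$WB)
  r <- as.integer(table(g))[1]
  means <- tapply(y, g, mean)
  msb <- r * stats::var(means)
  msw <- sum((y - stats::ave(y, g))^2) / (length(y) - nlevels(g))
  list(between = (msb - msw) / r, within = msw, r = r,
       grand = mean(y), means = means)
}

# the published decade-scale variance decomposition of the Ligurian panel
liguria_varcomp <- function() {
  variance_components(
    var_wb = 0.031683, var_year = 0, var_surveyor = 0,
    var_wb_in_year = c("Capo Mortola" = 0.001691,
                       "Laigueglia-Albenga" = 0.003284,
                       "Genova-Camogli" = 0.013276,
                       "Portofino" = 0.001302,
                       "Punta Mesco" = 0.003444,
                       "Cinque Terre" = 0.004810,
                       "Portovenere" = 0.003429),
    var_residual = 0.004404)
}
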