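test_that("sector quality ratio divides SL by the GRS reference", {
  expect_equal(sector_quality_ratio("CA5", "Low coast", "Natural"), 20 / 16.6)
  expect_equal(sector_quality_ratio("Cor", "Low coast", "Natural"), 8 / 16.6)
  expect_equal(sector_quality_ratio("BG", "High coast", "Artificial"), 0.125)
  # compound labels score through the averaging rule
  expect_equal(sector_quality_ratio("Cor+Mgal", "Low coast", "Natural"),
               7 / 16.6)
})

test_that("water-body EQR is the length-weighted mean of sector ratios", {
  # hand-computed weighted mean: (0.3 * 100 + 0.9 * 50) / 150 = 0.5
  # CA1/Low/Nat has ratio 10/16.6; engineer exact ratios with a custom table
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Community,Description,SL", "LOW,r 0.3,3", "HIGH,r 0.9,9"), tmp)
  cat2 <- read_sensitivity_catalog(tmp)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("GRS,Morphology,NatArt,EQi", "1,Low coast,Natural,10"), tmp2)
  refs2 <- read_reference_eqi(tmp2)
  s <- make_survey(communities = c("LOW", "HIGH"), lengths = c(100, 50))
  res <- waterbody_eqr(s, catalog = cat2, refs = refs2)
  expect_equal(res$eqr, 0.5)
  expect_identical(res$es_class, "moderate")
  expect_equal(res$total_length, 150)
  # equal-weight mean of two 50 m sectors
  s2 <- make_survey(communities = c("LOW", "HIGH"), lengths = c(50, 50))
  expect_equal(waterbody_eqr(s2, catalog = cat2, refs = refs2)$eqr, 0.6)
})

test_that("capping: aggregate cap is the default, sector cap is opt-in", {
  s <- make_survey(communities = "CA5", lengths = 50)  # ratio 20/16.6 > 1
  expect_equal(waterbody_eqr(s)$eqr, 1.0)
  expect_equal(waterbody_eqr(s, cap = FALSE)$eqr, 20 / 16.6)
  expect_equal(waterbody_eqr(s, cap = FALSE, cap_sectors = TRUE)$eqr, 1.0)
  # with cap off, EQR is a convex combination of sector ratios
  s3 <- make_survey(communities = c("CA5", "BG", "Cor"),
                    lengths = c(30, 120, 50))
  res <- waterbody_eqr(s3, cap = FALSE)
  r <- res$sector_ratios$ratio
  expect_gte(res$eqr, min(r))
  expect_lte(res$eqr, max(r))
})

test_that("waterbody_eqr validates its input", {
  s <- make_survey()
  expect_error(waterbody_eqr(s[0, ]), "at least one sector")
  expect_error(waterbody_eqr(rbind(s, within(s, Site <- "WB2"))),
               "single water body")
  bad <- s; bad$Length[2] <- 0
  expect_error(waterbody_eqr(bad), "row\\(s\\): 2")
  bad2 <- s; bad2$Community[3] <- "QQ"
  expect_error(waterbody_eqr(bad2), "sector 3")
})

test_that("EQR is invariant to sector order and to splitting a sector", {
  s <- make_survey(communities = c("CA3", "Cor", "CC+Cor"),
                   lengths = c(80, 120, 40),
                   morphology = c("Low coast", "High coast", "Low coast"),
                   natart = c("Natural", "Artificial", "Natural"))
  base <- waterbody_eqr(s)$eqr
  expect_equal(waterbody_eqr(s[c(3, 1, 2), ])$eqr, base)
  split <- rbind(s[1, ], s[1, ], s[2:3, ])
  split$Length[1:2] <- c(30, 50)  # 80 m sector split in two
  expect_equal(waterbody_eqr(split)$eqr, base)
})

test_that("raising every sector's sensitivity never lowers the EQR", {
  set.seed(7)
  cat <- default_sensitivity_catalog()
  for (i in 1:10) {
    comms <- sample(c("BG", "GA", "Ulva", "Cor", "CA1", "CC"), 5, replace = TRUE)
    s <- make_survey(communities = comms, lengths = runif(5, 10, 100))
    upgraded <- s
    upgraded$Community <- "CA4"  # SL 19, above every community drawn
    expect_gte(waterbody_eqr(upgraded, cap = FALSE)$eqr,
               waterbody_eqr(s, cap = FALSE)$eqr)
  }
})

test_that("classification follows the WFD bands, boundaries to the lower class", {
  expect_identical(classify_es(0.50), "moderate")
  expect_identical(classify_es(0.61), "good")
  expect_identical(classify_es(0.88), "high")
  expect_identical(classify_es(0.25), "bad")
  expect_identical(classify_es(c(0, 0.2500001, 0.40, 0.60, 0.75, 0.7500001, 1)),
                   c("bad", "poor", "poor", "moderate", "good", "high", "high"))
  expect_error(classify_es(1.2), "\\[0, 1\\]")
  expect_error(classify_es(-0.1), "\\[0, 1\\]")
})

test_that("classification is monotone in EQR", {
  eqr <- sort(runif(200))
  rank <- match(classify_es(eqr), rating_scale()$classes)
  expect_true(all(diff(rank) >= 0))
})

test_that("rating scale rejects malformed bands", {
  expect_error(rating_scale(c(0.4, 0.25, 0.6, 0.75)), "increasing")
  expect_error(rating_scale(c(0.25, 0.4), classes = c("a", "b")), "one more")
})

test_that("dominance profile reports percent of length per label", {
  s <- make_survey(communities = c("CA3", "Cor"), lengths = c(50, 50))
  p <- dominance_profile(s)
  expect_equal(p$Percent[p$Community == "CA3"], 50)
  s2 <- make_survey(communities = c("CC+Cor", "Mgal"), lengths = c(150, 50))
  p2 <- dominance_profile(s2)
  expect_equal(p2$Percent[p2$Community == "CC+Cor"], 75)
  expect_equal(p2$Percent[p2$Community == "Mgal"], 25)
  s3 <- make_survey(communities = rep("CA5", 3), lengths = c(10, 20, 30))
  expect_equal(dominance_profile(s3)$Percent, 100)
  # percentages always sum to 100
  set.seed(3)
  for (i in 1:10) {
    s4 <- make_survey(communities = sample(c("CA5", "Cor", "CC", "BG"), 8,
                                           replace = TRUE),
                      lengths = runif(8, 5, 200))
    expect_equal(sum(dominance_profile(s4)$Percent), 100, tolerance = 1e-9)
  }
})

test_that("intra-seasonal consistency flags deviating months", {
  mo <- c("Mar", "Apr", "May", "Jun")
  r <- intra_seasonal_consistency(c("good", "high", "high", "high"), mo)
  expect_false(r$consistent)
  expect_identical(r$modal_class, "high")
  expect_identical(r$deviating_months, "Mar")
  r2 <- intra_seasonal_consistency(rep("high", 4), mo)
  expect_true(r2$consistent)
  expect_length(r2$deviating_months, 0)
  # modal tie: resolved by dropping the earliest months, and flagged
  r3 <- intra_seasonal_consistency(c("moderate", "good", "good", "moderate"), mo)
  expect_false(r3$consistent)
  expect_true(r3$tie)
  expect_identical(r3$modal_class, "good")
  expect_setequal(r3$deviating_months, c("Mar", "Jun"))
  expect_error(intra_seasonal_consistency("high"), "at least two")
})

test_that("survey_eqr scores every water body in a pooled survey", {
  s <- rbind(make_survey("A", c("CA5", "CA4"), c(50, 50)),
             make_survey("B", c("BG", "GA"), c(50, 50)))
  res <- survey_eqr(s)
  expect_identical(res$Site, c("A", "B"))
  expect_equal(res$EQR[1], min(1, mean(c(20, 19)) / 16.6))
  expect_equal(res$EQR[2], mean(c(1, 3)) / 16.6)
  expect_identical(res$ES, c("high", "bad"))
})
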