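test_that("nutrient yield is catch times concentration times 1e4, summed over species", {
  prof <- data.frame(species = c("a", "b"), iron = c(2, 4), zinc = c(0, 0))
  y <- nutrient_yield(c(a = 100, b = 50), prof)
  expect_equal(unname(y["iron"]), (100 * 2 + 50 * 4) * 1e4) # 4e6 mg/yr
  expect_equal(unname(y["zinc"]), 0)
  # equal concentrations: proportional to total catch
  prof2 <- data.frame(species = c("a", "b"), iron = c(3, 3))
  expect_equal(unname(nutrient_yield(c(a = 7, b = 13), prof2)["iron"]),
               3 * 20 * 1e4)
  expect_error(nutrient_yield(c(a = 1, missing_fish = 1), prof),
               "missing_fish")
})

test_that("curve summary arithmetic: argmax refinement, classification, fractions", {
  efforts <- seq(0, 2, by = 0.25)
  total <- c(0, 2, 3.5, 4.4, 4.9, 4.95, 4.5, 3.8, 3)
  cv <- toy_curve(efforts, total, nutrient_conc = c(iron = 2))
  sm <- summarise_curve(cv)
  # identical concentrations across species: nutrient curve is proportional
  # to the catch curve, ratio exactly 1 and neutral
  expect_identical(which.max(cv$nutrient_yield[, "iron"]), which.max(total))
  expect_equal(sm$nutrients$ratio, 1, tolerance = 1e-12)
  expect_equal(sm$nutrients$classification, "neutral")
  expect_equal(sm$nutrients$yield_at_mMSY_fraction, 1)
  expect_true(sm$F_mMSY > 1 && sm$F_mMSY < 1.5)
  expect_true(sm$mMSY >= max(total))

  # an infinite neutrality tolerance makes everything neutral
  cv2 <- toy_curve(efforts, total)
  cv2$nutrient_yield[, 1] <- c(0, 4, 4.9, 4.4, 3.5, 3, 2.5, 2, 1.5) # peaks early
  smo <- summarise_curve(cv2)
  expect_equal(smo$nutrients$classification, "overfished")
  expect_true(smo$nutrients$ratio < 1)
  expect_true(smo$nutrients$yield_at_mMSY_fraction < 1)
  expect_equal(summarise_curve(cv2, tolerance = Inf)$nutrients$classification,
               "neutral")
  expect_error(summarise_curve(toy_curve(c(0, 1), c(0, 1))), "at least 3")
})

test_that("scaling a nutrient's concentrations scales its peak but not its location", {
  efforts <- seq(0, 2, by = 0.25)
  total <- c(0, 2, 3.5, 4.4, 4.9, 4.95, 4.5, 3.8, 3)
  cv <- toy_curve(efforts, total, nutrient_conc = c(iron = 1.7))
  cvk <- cv
  cvk$nutrient_yield <- cv$nutrient_yield * 3.7
  s1 <- summarise_curve(cv)$nutrients
  s2 <- summarise_curve(cvk)$nutrients
  expect_equal(s2$mMNY, 3.7 * s1$mMNY, tolerance = 1e-12)
  expect_equal(s2$F_mMNY, s1$F_mMNY, tolerance = 1e-12)
})

test_that("rescaled series have maximum exactly one; zero series become missing", {
  cv <- toy_curve(seq(0, 1, 0.25), c(2, 4, 3, 2.5, 1),
                  nutrient_conc = c(iron = 1, zinc = 0))
  rs <- rescale_curves(cv)
  expect_equal(rs$total_catch, c(0.5, 1, 0.75, 0.625, 0.25))
  for (s in c("total_catch", "yield_iron", "community_biomass",
              "fishable_biomass", "mean_max_size"))
    expect_equal(max(rs[[s]]), 1)
  expect_true(all(is.na(rs$yield_zinc)))
  # a constant series rescales to all ones
  expect_equal(rs$mean_max_size, rep(1, 5))
})

test_that("effort sweeps start unfished, truncate on the collapse rule, and store consistent flags", {
  m <- fx_model3()
  com <- fx_com3()
  rp <- fx_rp3()
  curve <- fixture("curve3", function()
    sweep_effort(fx_model3(), fx_rp3(), fx_com3()$nutrients,
                 effort_max = 4, effort_step = 0.25))
  df <- as.data.frame(curve)
  # unfished first row
  expect_equal(df$total_catch[1], 0)
  expect_equal(unname(curve$nutrient_yield[1, ]),
               rep(0, ncol(curve$nutrient_yield)))
  expect_equal(curve$n_collapsed[1], 0)
  expect_equal(df$community_biomass[1], sum(attr(curve, "B0")))

  # collapse flags equal an independent recomputation from stored biomasses
  B0 <- attr(curve, "B0")
  expl <- df$total_catch / df$community_biomass
  expect_equal(df$exploitation_rate, expl, tolerance = 1e-12)

  # truncation: the last row is the first to satisfy the stop rule, and no
  # earlier row satisfies it
  thr <- m$thresholds$collapse
  stop_rows <- df$community_biomass < thr * sum(B0) |
    curve$n_collapsed > 0.5 * nrow(com$species)
  if (attr(curve, "truncated")) {
    expect_true(stop_rows[nrow(df)])
    expect_false(any(stop_rows[-nrow(df)]))
  }
  expect_error(sweep_effort(m, rp, com$nutrients,
                            efforts = c(0.5, 1)), "start at 0")
  expect_error(sweep_effort(m, rp, com$nutrients,
                            efforts = c(0, 1, 0.5)), "increasing")
})

test_that("collapse flags recomputed from stored biomasses match exactly", {
  curve <- fixture("curve3", function()
    sweep_effort(fx_model3(), fx_rp3(), fx_com3()$nutrients,
                 effort_max = 4, effort_step = 0.25))
  B0 <- attr(curve, "B0")
  # per-species biomass is not stored directly; recompute flags from catch
  # and yield identities is not possible, so re-run two grid points cold
  m <- fx_model3()
  fmsy <- attr(curve, "fmsy")
  for (k in c(2, length(curve$efforts))) {
    st <- project_to_equilibrium(m, fmsy * curve$efforts[k])
    b <- species_biomass(m, st)
    expect_equal(unname(b < m$thresholds$collapse * B0),
                 unname(curve$collapsed[k, ]))
  }
})

test_that("nutrient yields along a sweep equal the dot-product recomputation", {
  com <- fx_com3()
  curve <- fixture("curve3", function()
    sweep_effort(fx_model3(), fx_rp3(), fx_com3()$nutrients,
                 effort_max = 4, effort_step = 0.25))
  nut <- intersect(nutrient_names(), names(com$nutrients))
  for (nu in nut) {
    conc <- com$nutrients[[nu]][match(colnames(curve$catch),
                                      com$nutrients$species)]
    expect_equal(unname(curve$nutrient_yield[, nu]),
                 unname(as.vector(curve$catch %*% conc) * 1e4),
                 tolerance = 1e-12)
  }
})

test_that("estimated F_MSY is an interior maximum of the focal species' yield", {
  m <- fx_model3()
  com <- fx_com3()
  rp <- fx_rp3()
  expect_true(attr(rp, "converged"))
  expect_true(all(rp$F_MSY > 0 & rp$B0 > 0))
  # definition check: perturbing the focal F away from F_MSY does not
  # increase that species' equilibrium yield (others held at their F_MSY)
  base <- setNames(rp$F_MSY, rp$species)
  for (i in seq_len(nrow(rp))) {
    y_at <- function(f) {
      fv <- base; fv[i] <- f
      st <- project_to_equilibrium(m, fv, tol = 1e-4, t_max = 150,
                                   window = 5)
      species_yield(m, st, fv)[i]
    }
    y0 <- y_at(rp$F_MSY[i])
    expect_gte(y0 * 1.005, y_at(0.5 * rp$F_MSY[i]))
    expect_gte(y0 * 1.005, y_at(1.5 * rp$F_MSY[i]))
  }
})

test_that("species without fishable selectivity are rejected", {
  com <- fx_com3()
  gears <- com$gears
  gears$Q[2] <- 0
  m <- nym_model(com$species, gears, numerics = small_numerics())
  expect_error(estimate_fmsy(m), "no fishable selectivity.*species_02")
})

test_that("a single-species sweep aligns catch and nutrient maxima", {
  m <- fx_model1()
  com <- fx_com1()
  rp <- fx_rp1()
  curve <- sweep_effort(m, rp, com$nutrients, effort_max = 3,
                        effort_step = 0.25)
  sm <- summarise_curve(curve)
  expect_equal(sm$nutrients$F_mMNY,
               rep(sm$F_mMSY, nrow(sm$nutrients)), tolerance = 1e-9)
  expect_true(all(sm$nutrients$classification == "neutral"))
})
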