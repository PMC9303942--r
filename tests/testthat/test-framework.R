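test_that("Pielou evenness matches hand values and conventions", {
  expect_equal(pielou_evenness(rep(2, 4)), 1)
  expect_equal(pielou_evenness(c(1, 0, 0)), 0) # single contributing taxon
  expect_equal(pielou_evenness(c(0.5, 0.25, 0.25)),
               -sum(c(.5, .25, .25) * log(c(.5, .25, .25))) / log(3))
  expect_equal(pielou_evenness(c(0.5, 0.25, 0.25)), 0.946, tolerance = 1e-3)
  # invariant under rescaling of the weights
  w <- c(3, 1, 8, 0, 2)
  expect_equal(pielou_evenness(w * 1e6), pielou_evenness(w))
  expect_error(pielou_evenness(c(0, 0)), "positive")
  expect_error(pielou_evenness(c(-1, 2)), "non-negative")
})

test_that("weighted vulnerability is the weight-normalised mean within score bounds", {
  expect_equal(as.numeric(weighted_vulnerability(c(100, 50), c(30, 60))), 40)
  expect_equal(as.numeric(weighted_vulnerability(rep(1, 3), c(10, 20, 60))),
               30)
  expect_equal(as.numeric(weighted_vulnerability(c(0, 0, 5), c(10, 20, 60))),
               60)
  # scale invariance and bounds
  w <- c(2, 0, 7, 1); v <- c(10, 99, 55, 20)
  V <- as.numeric(weighted_vulnerability(w, v))
  expect_equal(as.numeric(weighted_vulnerability(w * 3.3, v)), V)
  expect_true(V >= min(v[w > 0]) && V <= max(v[w > 0]))
  expect_error(weighted_vulnerability(c(1, 1), c(10, NA)), "missing vulnerability")
  expect_error(weighted_vulnerability(c(0, 0), c(1, 2)), "positive")
  expect_equal(attr(weighted_vulnerability(1, 2, mode = "fmsy"), "mode"),
               "fmsy")
})

test_that("taxonomic fallback assigns genus/family mean concentrations", {
  prof <- data.frame(
    species = c("Gadus morhua", "Gadus ogac", "Clupea harengus"),
    genus = c("Gadus", "Gadus", "Clupea"),
    family = c("Gadidae", "Gadidae", "Clupeidae"),
    iron = c(2, 4, 8), zinc = c(1, 1, 5))
  rec <- data.frame(
    region = "r1",
    taxon = c("Gadus morhua", "Gadus", "Gadidae", "Scombridae"),
    rank = c("species", "genus", "family", "family"),
    catch_tonnes = c(10, 5, 2, 1),
    vulnerability = c(40, 40, 40, 70))
  out <- resolve_profiles(rec, prof, quiet = TRUE)
  expect_equal(out$iron, c(2, 3, 3, NA)) # genus mean of (2, 4) = 3
  expect_equal(out$zinc[2], 1)
  expect_equal(out$resolved, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(out, "n_excluded"), 1)
  # species-rank records keep their own profile untouched
  expect_equal(out$catch_tonnes, rec$catch_tonnes)
  # nutrient weights follow catch x concentration
  w <- nutrient_weights(out[out$resolved, ], "iron")
  expect_equal(w, c(10 * 2, 5 * 3, 2 * 3) * 1e4)
  expect_error(nutrient_weights(out, "iron"), "unresolved")
  expect_error(nutrient_weights(rec, "iron"), "resolve_profiles")
})

test_that("model-mode classification follows the sign rule", {
  expect_equal(classify_nutrient_model(1.2, 0.8), "resilient")
  expect_equal(classify_nutrient_model(0.5, 0.8), "vulnerable")
  expect_equal(classify_nutrient_model(0.8, 0.8), "neutral")
  expect_error(classify_nutrient_model(-1, 0.8), "positive")
})

test_that("regional summaries match a spreadsheet-style recomputation", {
  ct <- make_catch_table(n_regions = 3, taxa_per_region = c(5, 5),
                         rank_missing_rate = 0, seed = 9)
  rec <- resolve_profiles(ct$catch, ct$profiles, quiet = TRUE)
  fw <- regional_summary(rec)
  expect_s3_class(fw, "mny_framework")
  for (rg in unique(rec$region)) {
    rr <- rec[rec$region == rg, ]
    vtot <- sum(rr$catch_tonnes * rr$vulnerability) / sum(rr$catch_tonnes)
    for (nu in c("iron", "calcium")) {
      wts <- rr$catch_tonnes * rr[[nu]] * 1e4
      vn <- sum(wts * rr$vulnerability) / sum(wts)
      row <- fw[fw$region == rg & fw$nutrient == nu, ]
      expect_equal(row$vulnerability, vn, tolerance = 1e-12)
      expect_equal(row$delta_vulnerability, vn - vtot, tolerance = 1e-12)
      p <- wts / sum(wts)
      expect_equal(row$evenness, -sum(p * log(p)) / log(length(p)),
                   tolerance = 1e-12)
    }
    tot <- fw[fw$region == rg & fw$nutrient == "total", ]
    expect_equal(tot$delta_vulnerability, 0)
    # region mean and 2 SEM across the six nutrients
    nr <- fw[fw$region == rg & fw$nutrient != "total", ]
    expect_equal(nrow(nr), 6)
    expect_equal(unique(nr$mean_vulnerability), mean(nr$vulnerability))
    expect_equal(unique(nr$sem2_vulnerability),
                 2 * sd(nr$vulnerability) / sqrt(6))
  }
})

test_that("a one-species region is maximally uneven with the species' own vulnerability", {
  prof <- data.frame(species = "Solo fish", genus = "Solo",
                     family = "Solidae", iron = 2, calcium = 10, zinc = 1,
                     selenium = 5, vitamin_a = 3, omega3 = 0.4)
  rec <- data.frame(region = "r", taxon = "Solo fish", rank = "species",
                    catch_tonnes = 100, vulnerability = 42)
  fw <- regional_summary(resolve_profiles(rec, prof, quiet = TRUE))
  nr <- fw[fw$nutrient != "total", ]
  expect_equal(nr$evenness, rep(0, 6))
  expect_equal(nr$vulnerability, rep(42, 6))
  expect_equal(nr$delta_vulnerability, rep(0, 6))
})

test_that("identical regions give identical results; merging duplicate taxa changes nothing", {
  ct <- make_catch_table(n_regions = 1, taxa_per_region = c(6, 6),
                         rank_missing_rate = 0, seed = 4)
  rec1 <- ct$catch
  rec2 <- rec1; rec2$region <- "copy"
  both <- resolve_profiles(rbind(rec1, rec2), ct$profiles, quiet = TRUE)
  fw <- regional_summary(both)
  a <- fw[fw$region == unique(rec1$region), -1]
  b <- fw[fw$region == "copy", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  # split one record into two half-catch records of the same taxon
  rec3 <- rbind(rec1, rec1[1, ])
  rec3$catch_tonnes[c(1, nrow(rec3))] <- rec1$catch_tonnes[1] / 2
  fw3 <- regional_summary(resolve_profiles(rec3, ct$profiles, quiet = TRUE))
  expect_equal(fw3[, -1], a)
})

test_that("global deviation fractions are direct counts over regions", {
  fw <- data.frame(region = rep(c("a", "b", "c"), each = 2),
                   nutrient = rep(c("iron", "zinc"), 3),
                   delta_vulnerability = c(-1, 2, -3, 1, -2, -1))
  g <- global_deviation_summary(fw)
  expect_equal(g[g$nutrient == "iron", "frac_negative"], 1)
  expect_equal(g[g$nutrient == "iron", "frac_positive"], 0)
  expect_equal(g[g$nutrient == "zinc", "frac_negative"], 1 / 3)
  expect_equal(g[g$nutrient == "zinc", "frac_positive"], 2 / 3)
  expect_true(all(g$frac_negative + g$frac_positive + g$frac_zero == 1))
  # a single region gives fractions of exactly zero or one
  g1 <- global_deviation_summary(fw[fw$region == "a", ])
  expect_true(all(unlist(g1[, c("frac_negative", "frac_positive")]) %in%
                    c(0, 1)))
})
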