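# shared fixtures, computed lazily once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# reduced numerics for small oracle fixtures: fewer bins, looser equilibrium
# tolerance, shorter horizon
small_numerics <- function() {
  list(n_bins = 50, res_decades = 2, tol = 1e-4, t_max = 150, window = 5)
}

fx_com1 <- function() fixture("com1", function() {
  make_generic_community(n_species = 1, w_inf_range = c(50, 5e3), seed = 2)
})

fx_model1 <- function() fixture("model1", function() {
  com <- fx_com1()
  nym_model(com$species, com$gears, numerics = small_numerics())
})

fx_rp1 <- function() fixture("rp1", function() {
  estimate_fmsy(fx_model1(), f_range = c(0.01, 2))
})

fx_com3 <- function() fixture("com3", function() {
  make_generic_community(n_species = 3, w_inf_range = c(50, 5e3), seed = 2)
})

fx_model3 <- function() fixture("model3", function() {
  com <- fx_com3()
  nym_model(com$species, com$gears, numerics = small_numerics())
})

fx_rp3 <- function() fixture("rp3", function() {
  estimate_fmsy(fx_model3(), f_range = c(0.01, 2))
})

fx_eq3 <- function() fixture("eq3", function() {
  project_to_equilibrium(fx_model3())
})

# the default 15-species generic community under default numerics
fx_com15 <- function() fixture("com15", function() {
  make_generic_community(n_species = 15, seed = 1)
})

fx_model15 <- function() fixture("model15", function() {
  com <- fx_com15()
  nym_model(com$species, com$gears)
})

fx_rp15 <- function() fixture("rp15", function() {
  estimate_fmsy(fx_model15())
})

fx_curve15 <- function() fixture("curve15", function() {
  com <- fx_com15()
  sweep_effort(fx_model15(), fx_rp15(), com$nutrients)
})

# forage + piscivores fixture for the directional tests (one community, two
# nutrient loadings)
fx_loading <- function() fixture("loading", function() {
  res <- make_nutrient_loading_fixture("resilient")
  vul <- make_nutrient_loading_fixture("vulnerable")
  m <- nym_model(res$species, res$gears, interaction = res$interaction,
                 resource = res$resource)
  rp <- estimate_fmsy(m)
  curve <- sweep_effort(m, rp, res$nutrients)
  curve_vul <- curve
  curve_vul$nutrient_yield <- nutrient_yield(curve$catch, vul$nutrients)
  list(res = res, vul = vul, model = m, rp = rp,
       curve_res = curve, curve_vul = curve_vul)
})

# degenerate single-species model with feeding and reproduction switched off
# and constant background mortality mu: pure exponential decay
decay_model <- function(mu = 0.5) {
  com <- make_generic_community(n_species = 1, seed = 1)
  sp <- com$species
  sp$gamma <- 0
  sp$h <- 1e-9
  sp$ks <- 0
  sp$mu_b0 <- mu / sp$w_inf^(sp$n - 1)
  nym_model(sp, com$gears, numerics = list(n_bins = 50))
}

# hand-assembled yield-curve object for summary arithmetic tests
toy_curve <- function(efforts, total, nutrient_conc = c(iron = 1),
                      n_species = 2) {
  catch <- outer(total / n_species, rep(1, n_species))
  colnames(catch) <- paste0("sp", seq_len(n_species))
  prof <- data.frame(species = colnames(catch))
  for (nu in names(nutrient_conc)) prof[[nu]] <- nutrient_conc[[nu]]
  ny <- nutrient_yield(catch, prof)
  structure(list(efforts = efforts, catch = catch, nutrient_yield = ny,
                 community_biomass = rev(seq_along(efforts)) + 10,
                 fishable_biomass = rev(seq_along(efforts)) + 5,
                 mean_max_size = rep(30, length(efforts)),
                 exploitation_rate = total / (rev(seq_along(efforts)) + 10),
                 n_collapsed = rep(0, length(efforts)),
                 collapsed = matrix(FALSE, length(efforts), n_species),
                 converged = rep(TRUE, length(efforts))),
            B0 = rep(1, n_species), fmsy = rep(1, n_species),
            truncated = FALSE, class = "mny_yield_curve")
}
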