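# state construction helpers local to these tests
empty_state <- function(m) {
  st <- initial_state(m)
  st$N[] <- 0
  st$N_res[] <- 0
  st
}

test_that("feeding level is zero without food, saturates with food, and matches a one-bin hand computation", {
  m <- fx_model3()
  com <- fx_com3()
  st <- empty_state(m)
  expect_true(all(encounter_feeding(m, st) == 0))

  # a single prey size class: encounter integral reduces to one term
  w <- m$grid$w; dw <- m$grid$dw
  jp <- 20 # prey bin (fish grid)
  st$N[2, jp] <- 4.2e3
  f <- encounter_feeding(m, st)
  sp <- com$species[1, ]
  k <- 35 # predator bin
  phi <- feeding_kernel(w[k], w[jp], sp$beta, sp$sigma)
  e_avail <- phi * st$N[2, jp] * w[jp] * dw[jp] # theta = 1
  e_enc <- sp$gamma * w[k]^sp$q * e_avail
  expect_equal(unname(f[1, k]),
               unname(e_enc / (e_enc + sp$h * w[k]^sp$n)),
               tolerance = 1e-12)

  # saturation: enormous prey density drives f to 1
  st$N[2, jp] <- 1e30
  expect_equal(max(encounter_feeding(m, st)[1, ]), 1, tolerance = 1e-6)
  expect_true(all(encounter_feeding(m, st) >= 0 &
                    encounter_feeding(m, st) <= 1))
})

test_that("growth is assimilation minus metabolism times the adult allocation, floored at zero", {
  m <- fx_model3()
  com <- fx_com3()
  st <- empty_state(m) # f = 0 everywhere
  r <- community_rates(m, st)
  expect_true(all(r$g == 0)) # negative net energy is floored

  st2 <- initial_state(m)
  r2 <- community_rates(m, st2)
  w <- m$grid$w
  for (i in 1:3) {
    sp <- com$species[i, ]
    # juveniles well below w_mat: allocation ~ 0, g = alpha f h w^n - ks w^p
    j <- which(w > 2 * sp$w_min & w < 0.01 * sp$w_mat)[1]
    expect_equal(r2$g[i, j],
                 sp$alpha * r2$f[i, j] * sp$h * w[j]^sp$n - sp$ks * w[j]^sp$p,
                 tolerance = 1e-3)
    # at and above the asymptotic mass growth is exactly zero
    expect_true(all(r2$g[i, w >= sp$w_inf] == 0))
  }
})

test_that("mortality decomposes into background, predation and fishing", {
  m <- fx_model3()
  com <- fx_com3()
  st <- empty_state(m)
  r <- community_rates(m, st)
  mu_b <- com$species$mu_b0 * com$species$w_inf^(com$species$n - 1)
  for (i in 1:3) # empty unfished community: background only
    expect_equal(unname(r$mu[i, ]), rep(mu_b[i], ncol(r$mu)), tolerance = 1e-12)

  # a single predator cohort adds hand-computable predation on prey sizes
  w <- m$grid$w; dw <- m$grid$dw
  k <- 40
  st$N[3, k] <- 7e2
  r2 <- community_rates(m, st)
  sp <- com$species[3, ]
  jp <- 12
  pred <- feeding_kernel(w[k], w[jp], sp$beta, sp$sigma) *
    (1 - r2$f[3, k]) * sp$gamma * w[k]^sp$q * st$N[3, k] * dw[k]
  expect_equal(unname(r2$mu[1, jp] - mu_b[1]), unname(pred),
               tolerance = 1e-10)
  expect_true(all(r2$mu >= r$mu - 1e-12)) # adding a predator never lowers mortality

  # fishing adds on top
  fv <- setNames(c(0.3, 0, 0), com$species$name)
  r3 <- community_rates(m, st, fv)
  expect_equal(r3$mu[1, ] - r2$mu[1, ], resolve_F(m, fv)[1, ],
               tolerance = 1e-12)
})

test_that("recruitment follows the Beverton-Holt cap", {
  m <- fx_model3()
  com <- fx_com3()
  expect_true(all(recruitment(m, empty_state(m)) == 0))

  st <- initial_state(m)
  rdi <- community_rates(m, st)$rdi
  expect_true(all(rdi > 0))
  # rebuild with R_max equal to the realised egg production: R = R_max / 2
  sp2 <- com$species
  sp2$R_max <- unname(rdi)
  m2 <- nym_model(sp2, com$gears, numerics = small_numerics())
  expect_equal(unname(recruitment(m2, st)), unname(rdi) / 2,
               tolerance = 1e-10)
  # R_di = 3 R_max: R = 0.75 R_max
  sp3 <- com$species
  sp3$R_max <- unname(rdi) / 3
  m3 <- nym_model(sp3, com$gears, numerics = small_numerics())
  expect_equal(unname(recruitment(m3, st)), 0.75 * sp3$R_max,
               tolerance = 1e-10)
  # the cap is never exceeded along a projection
  r <- community_rates(m, project_to_equilibrium(m))
  expect_true(all(r$R <= com$species$R_max))
})

test_that("a step with no growth, mortality or recruitment leaves the state unchanged", {
  m0 <- decay_model(mu = 0)
  st <- initial_state(m0)
  st2 <- step_community(m0, st, dt = 0.1)
  expect_equal(st2$N, st$N, tolerance = 1e-14)
  expect_error(step_community(m0, st, dt = -0.1), "positive")
})

test_that("pure decay follows exp(-mu t) and blow-ups raise errors", {
  m <- decay_model(mu = 0.5)
  st <- initial_state(m)
  st1 <- st
  for (k in 1:10) st1 <- step_community(m, st1) # 1 year at dt = 0.1
  keep <- st$N[1, ] > 0
  expect_equal(st1$N[1, keep] / st$N[1, keep],
               rep(exp(-0.5), sum(keep)), tolerance = 1e-12)
  stbad <- st
  stbad$N[1, 3] <- NaN
  expect_error(step_community(m, stbad, dt = 0.1), "non-finite")
})

test_that("equilibria are reached and do not depend on the starting state", {
  m <- fx_model3()
  eq <- fx_eq3()
  expect_true(eq$converged)
  eq2 <- project_to_equilibrium(m, state = initial_state(m, scale = 5))
  expect_true(eq2$converged)
  b1 <- species_biomass(m, eq)
  b2 <- species_biomass(m, eq2)
  expect_equal(b1, b2, tolerance = 10 * m$numerics$tol)
  # zero-horizon projection returns the input unconverged
  st0 <- project_to_equilibrium(m, t_max = 0)
  expect_false(st0$converged)
  expect_equal(st0$t, 0)
})

test_that("abundances, catches and biomasses stay non-negative while fishing", {
  m <- fx_model3()
  com <- fx_com3()
  st <- fx_eq3()
  for (Fu in c(0.5, 2)) {
    fv <- setNames(rep(Fu, 3), com$species$name)
    st <- project_to_equilibrium(m, fv, state = st)
    expect_true(all(st$N >= 0))
    expect_true(all(st$N_res >= 0))
    expect_true(all(species_yield(m, st, fv) >= 0))
    expect_true(all(species_biomass(m, st) >= 0))
  }
})

test_that("single-species equilibrium biomass declines with fishing pressure", {
  m <- fx_model1()
  com <- fx_com1()
  st <- NULL
  b <- sapply(c(0, 0.3, 0.6, 1, 1.5), function(Fu) {
    st <<- project_to_equilibrium(m, setNames(Fu, com$species$name),
                                  state = if (is.null(st))
                                    initial_state(m) else st)
    species_biomass(m, st)
  })
  expect_true(all(diff(b) < 0))
})

test_that("catch is F N w integrated, zero when unfished, linear in abundance", {
  m <- fx_model3()
  com <- fx_com3()
  st <- fx_eq3()
  expect_true(all(species_yield(m, st) == 0))
  fv <- setNames(c(0.4, 0.2, 0.1), com$species$name)
  y1 <- species_yield(m, st, fv)
  st2 <- st; st2$N <- st$N * 2
  expect_equal(species_yield(m, st2, fv), 2 * y1, tolerance = 1e-12)
  # one-bin state: C = F(w) N w dw, in tonnes
  st3 <- empty_state(m)
  j <- 30
  st3$N[1, j] <- 123
  Fm <- resolve_F(m, fv)
  expect_equal(unname(species_yield(m, st3, fv)[1]),
               Fm[1, j] * 123 * m$grid$w[j] * m$grid$dw[j] * 1e-6,
               tolerance = 1e-12)
})

test_that("biomass indicators: empty community, single species, weighted mean size", {
  m <- fx_model3()
  ind0 <- biomass_indicators(m, empty_state(m))
  expect_equal(ind0$community_biomass, 0)
  expect_equal(ind0$fishable_biomass, 0)
  expect_true(is.na(ind0$mean_max_size))

  com <- fx_com3()
  st <- empty_state(m)
  st$N[2, 25] <- 10
  expect_equal(biomass_indicators(m, st)$mean_max_size, com$species$L_inf[2])

  # two species with biomasses 1:3 and L_inf 10 and 50 cm: mean is 40 cm
  sp <- com$species[1:2, ]
  sp$L_inf <- c(10, 50)
  m2 <- nym_model(sp, com$gears[1:2, ], numerics = small_numerics())
  st2 <- initial_state(m2); st2$N[] <- 0; st2$N_res[] <- 0
  wdw <- m2$grid$w * m2$grid$dw
  j <- 30
  st2$N[1, j] <- 1 / wdw[j]
  st2$N[2, j] <- 3 / wdw[j]
  expect_equal(biomass_indicators(m2, st2)$mean_max_size, 40)
})
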