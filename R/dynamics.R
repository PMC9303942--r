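# projection of the community model: states, rates, stepping, equilibrium

#' Initial community state
#'
#' Power-law initial abundance for each species on `[w_min, w_inf]`, with the
#' background resource at carrying capacity. Any positive state works as a
#' starting point for [project_to_equilibrium()]; this one is a conventional,
#' deterministic default.
#'
#' @param model A `mny_model`.
#' @param scale Multiplier on the fish abundances (useful for testing that
#'   equilibria do not depend on the starting state).
#' @return An object of class `mny_state`: list with `N` (species x size
#'   abundance density, numbers per g), `N_res` (resource density on the full
#'   grid), `t` (yr) and `converged`.
#' @export
initial_state <- function(model, scale = 1) {
  stopifnot(inherits(model, "mny_model"))
  w <- model$grid$w
  lam <- model$resource$lambda
  S <- n_species(model)
  N <- matrix(0, S, length(w), dimnames = list(model$species$name, NULL))
  for (i in seq_len(S)) {
    keep <- w >= model$species$w_min[i] & w <= model$species$w_inf[i]
    N[i, keep] <- scale * model$resource$kappa / S * w[keep]^(-lam)
  }
  cc <- model$cpp$cc
  structure(list(N = N, N_res = cc, t = 0, converged = NA),
            class = "mny_state")
}

#' @export
print.mny_state <- function(x, ...) {
  cat("Community state at t =", x$t, "yr; total fish biomass",
      format(sum(x$N %*% rep(1, ncol(x$N))), digits = 4),
      "(density units); converged:", x$converged, "\n")
  invisible(x)
}

#' Instantaneous community rates
#'
#' Computes, for a given state and fishing policy, each species' feeding level,
#' somatic growth rate, total mortality at size, the resource mortality, and
#' recruitment.
#'
#' @param model A `mny_model`.
#' @param state A `mny_state`.
#' @param F Fishing mortality: `NULL` (unfished), a named per-species fishing
#'   level vector, or a full species x size matrix (see [fishing_mortality()]).
#' @return List with `f` (feeding level in `[0, 1]`), `g` (g/yr), `mu` (1/yr),
#'   `mu_res` (1/yr on the full grid), `R` (recruitment, numbers/yr, capped by
#'   Beverton-Holt at `R_max`), and `rdi` (density-independent egg production,
#'   numbers/yr).
#' @export
community_rates <- function(model, state, F = NULL) {
  stopifnot(inherits(model, "mny_model"), inherits(state, "mny_state"))
  Fm <- resolve_F(model, F)
  if (!all(dim(state$N) == dim(Fm))) stop("state dimensions do not match model")
  r <- rates_cpp(model$cpp, state$N, state$N_res, Fm)
  rownames(r$f) <- rownames(r$g) <- rownames(r$mu) <- model$species$name
  names(r$R) <- names(r$rdi) <- model$species$name
  r
}

#' Feeding level at size
#'
#' Realised intake as a fraction of maximum intake,
#' `f = E_enc / (E_enc + h w^n)`, where encounter `E_enc` integrates the
#' interaction-weighted prey and resource biomass through the size-preference
#' kernel times the allometric search volume.
#'
#' @inheritParams community_rates
#' @return Species x size matrix of feeding levels in `[0, 1]`.
#' @export
encounter_feeding <- function(model, state) {
  community_rates(model, state)$f
}

#' Somatic growth rate at size
#'
#' `g(w) = max(0, alpha f h w^n - ks w^p) (1 - psi(w))`, i.e. assimilated
#' intake net of standard metabolism, floored at zero, times the fraction of
#' net energy not allocated to reproduction. Zero at and above `w_inf`.
#'
#' @inheritParams community_rates
#' @return Species x size matrix of growth rates (g/yr).
#' @export
growth_rate <- function(model, state) {
  community_rates(model, state)$g
}

#' Total mortality at size
#'
#' Predation mortality (integral of predator intake pressure through the
#' kernels) plus constant allometric background mortality
#' `mu_b0 w_inf^(n - 1)` plus fishing mortality.
#'
#' @inheritParams community_rates
#' @return Species x size matrix of total mortality (1/yr).
#' @export
total_mortality <- function(model, state, F = NULL) {
  community_rates(model, state, F)$mu
}

#' Recruitment
#'
#' Density-independent egg production `R_di` (reproductive output divided by
#' twice the offspring mass, for an even sex ratio, times `erepro`) capped by
#' the Beverton-Holt form `R = R_max R_di / (R_max + R_di)`.
#'
#' @inheritParams community_rates
#' @return Named vector of recruitment rates (numbers/yr), never above `R_max`.
#' @export
recruitment <- function(model, state) {
  community_rates(model, state)$R
}

#' Advance the community by one time step
#'
#' One operator-split step: exact exponential mortality decay, implicit upwind
#' growth transport with the recruitment boundary flux, and exact semi-chemostat
#' resource relaxation, all with rates frozen at the start of the step.
#'
#' @inheritParams community_rates
#' @param dt Step length (yr), positive.
#' @return The advanced `mny_state`.
#' @export
step_community <- function(model, state, F = NULL, dt = model$numerics$dt) {
  stopifnot(inherits(model, "mny_model"), inherits(state, "mny_state"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be positive")
  Fm <- resolve_F(model, F)
  out <- project_cpp(model$cpp, state$N, state$N_res, Fm, dt, dt,
                     tol = 0, window = .Machine$integer.max)
  rownames(out$N) <- model$species$name
  structure(list(N = out$N, N_res = out$N_res, t = state$t + dt,
                 converged = NA), class = "mny_state")
}

#' Project the community to equilibrium
#'
#' Runs the model forward until the community settles: converged when the
#' maximum relative biomass change per year, across species, averaged over a
#' trailing window, drops below `tol`. Otherwise returns the state at `t_max`
#' with `converged = FALSE`.
#'
#' @inheritParams community_rates
#' @param state Starting state; defaults to [initial_state()].
#' @param tol Convergence tolerance (relative biomass change per year).
#' @param t_max Maximum projection time (yr).
#' @param window Trailing window (yr) over which the yearly change is averaged.
#' @param quiet Suppress the per-projection convergence message.
#' @return The equilibrium `mny_state`, with fields `converged`, `t`,
#'   `final_change` and yearly per-species biomass `trace`.
#' @export
project_to_equilibrium <- function(model, F = NULL,
                                   state = initial_state(model),
                                   tol = model$numerics$tol,
                                   t_max = model$numerics$t_max,
                                   window = model$numerics$window,
                                   quiet = TRUE) {
  stopifnot(inherits(model, "mny_model"), inherits(state, "mny_state"))
  if (tol <= 0) stop("tol must be positive")
  if (t_max < 0) stop("t_max must be non-negative")
  Fm <- resolve_F(model, F)
  if (t_max == 0) {
    state$converged <- FALSE
    return(state)
  }
  out <- project_cpp(model$cpp, state$N, state$N_res, Fm,
                     model$numerics$dt, t_max, tol, as.integer(window))
  rownames(out$N) <- model$species$name
  if (!quiet)
    message(sprintf("projection: %.0f yr, converged = %s, final change = %.3g",
                    out$t, out$converged, out$final_change))
  structure(list(N = out$N, N_res = out$N_res, t = state$t + out$t,
                 converged = out$converged, final_change = out$final_change,
                 trace = out$trace), class = "mny_state")
}

#' Per-species biomass
#'
#' @inheritParams community_rates
#' @param unit `"tonnes"` or `"g"`.
#' @return Named vector of species biomasses.
#' @export
species_biomass <- function(model, state, unit = c("tonnes", "g")) {
  unit <- match.arg(unit)
  b <- as.vector(state$N %*% (model$grid$w * model$grid$dw))
  if (unit == "tonnes") b <- b * 1e-6
  setNames(b, model$species$name)
}

#' Equilibrium catch by species
#'
#' Catch rate `C_i = int F_i(w) N_i(w) w dw`, converted from g/yr to
#' tonnes/yr.
#'
#' @inheritParams community_rates
#' @return Named vector of catch rates (tonnes/yr).
#' @export
species_yield <- function(model, state, F = NULL) {
  stopifnot(inherits(model, "mny_model"), inherits(state, "mny_state"))
  Fm <- resolve_F(model, F)
  y <- as.vector((Fm * state$N) %*% (model$grid$w * model$grid$dw)) * 1e-6
  setNames(y, model$species$name)
}

#' Community biomass indicators
#'
#' Community fish biomass, fishable biomass (biomass weighted by the maximum
#' gear selectivity at size), biomass-weighted mean maximum size, and
#' per-species biomass.
#'
#' @inheritParams community_rates
#' @param weighting Weighting for mean maximum size: `"biomass"` (default) or
#'   `"catch"` (requires `F`).
#' @return List with `community_biomass` (tonnes), `fishable_biomass`
#'   (tonnes), `mean_max_size` (cm, `NA` for an empty community), and
#'   `biomass` (per-species, tonnes).
#' @export
biomass_indicators <- function(model, state, F = NULL,
                               weighting = c("biomass", "catch")) {
  weighting <- match.arg(weighting)
  wdw <- model$grid$w * model$grid$dw
  b <- as.vector(state$N %*% wdw) * 1e-6
  fishable <- as.vector((model$Smax * state$N) %*% wdw) * 1e-6
  wts <- if (weighting == "catch") species_yield(model, state, F) else b
  mean_max <- if (sum(wts) > 0)
    sum(wts * model$species$L_inf) / sum(wts) else NA_real_
  list(community_biomass = sum(b), fishable_biomass = sum(fishable),
       mean_max_size = mean_max,
       biomass = setNames(b, model$species$name))
}
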