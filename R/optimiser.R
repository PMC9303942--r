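# constrained optimisation of per-species fishing mortality for the
# equilibrium yield of a single nutrient

#' Optimise per-species fishing mortality for one nutrient
#'
#' Searches for the per-species fishing-mortality vector that maximises the
#' equilibrium yield of a single nutrient, subject to no stock collapsing
#' (every equilibrium biomass at least the collapse threshold - by default
#' 10% - of its unfished biomass). The search is a bounded quasi-Newton ascent
#' (`optim` L-BFGS-B) on the equilibrium nutrient yield with fishing
#' mortalities bounded in `[0.01, 2]`; evaluations that collapse a stock are
#' penalised smoothly so the search remains informative, and the returned
#' optimum is re-verified against the hard constraint without any penalty.
#' Multiple seeded starts (baseline plus a Latin hypercube over the bounds)
#' guard against local maxima; the best feasible optimum is returned.
#'
#' @param model A `mny_model`.
#' @param nutrient One of [nutrient_names()].
#' @param profiles Nutrient concentration table (see [nutrient_yield()]).
#' @param baseline Named per-species fishing levels used as the first start
#'   and as the reference policy for [deltas_vs_baseline()].
#' @param bounds Box bounds on each species' fishing mortality (1/yr).
#' @param starts Number of optimisation starts (>= 1).
#' @param seed Integer seed controlling the random starts.
#' @param eq_control List overriding equilibrium `tol`, `t_max`, `window` for
#'   the inner evaluations.
#' @param penalty_weight Weight of the collapse penalty relative to the
#'   baseline nutrient-yield scale.
#' @param quiet Suppress progress messages.
#' @return Object of class `mny_optim`: list with `nutrient`, `F_star` (named
#'   vector, 1/yr), `yield_star` (amount/yr), `feasible`, `biomass_ratio`
#'   (equilibrium/unfished per species at the optimum), `n_evaluations`,
#'   `starts` (per-start diagnostics), `baseline`, and `deltas` (filled by
#'   [deltas_vs_baseline()]).
#' @export
optimise_nutrient <- function(model, nutrient, profiles, baseline,
                              bounds = c(0.01, 2), starts = 5, seed = 1,
                              eq_control = list(tol = 1e-4, t_max = 150,
                                                window = 5),
                              penalty_weight = 10, quiet = TRUE) {
  stopifnot(inherits(model, "mny_model"))
  if (!nutrient %in% NUTRIENTS)
    stop("unknown nutrient: ", nutrient, " (see nutrient_names())")
  if (!nutrient %in% names(profiles))
    stop("profiles lack a '", nutrient, "' column")
  sp <- model$species$name
  S <- length(sp)
  if (is.null(names(baseline))) {
    if (length(baseline) != S) stop("baseline must cover every species")
    names(baseline) <- sp
  }
  baseline <- baseline[sp]
  if (anyNA(baseline)) stop("baseline must cover every species")
  ec <- modifyList(list(tol = 1e-4, t_max = 150, window = 5), eq_control)
  thr <- model$thresholds$collapse

  eq0 <- project_to_equilibrium(model)
  B0 <- species_biomass(model, eq0)
  base_state <- project_to_equilibrium(model, baseline, state = eq0,
                                       tol = ec$tol, t_max = ec$t_max,
                                       window = ec$window)
  conc_one <- profiles[match(sp, profiles$species), nutrient]
  if (anyNA(conc_one))
    stop("missing nutrient profile for species: ",
         paste(sp[is.na(match(sp, profiles$species))], collapse = ", "))
  degenerate <- all(conc_one == 0)

  n_eval <- 0L
  eval_policy <- function(fvec) {
    n_eval <<- n_eval + 1L
    st <- project_to_equilibrium(model, fvec, state = base_state,
                                 tol = ec$tol, t_max = ec$t_max,
                                 window = ec$window)
    b <- species_biomass(model, st)
    y <- sum(species_yield(model, st, fvec) * conc_one) * 1e4
    list(yield = y, bratio = b / B0)
  }

  base_eval <- eval_policy(baseline)
  yscale <- max(base_eval$yield, 1e-12)
  Mpen <- penalty_weight * yscale
  objective <- function(fvec) {
    ev <- eval_policy(fvec)
    pen <- Mpen * sum(pmax(0, thr - ev$bratio))
    ev$yield - pen
  }

  start_pts <- with_seed(seed, {
    pts <- matrix(rep(pmin(pmax(baseline, bounds[1]), bounds[2]), 1),
                  nrow = 1)
    if (starts > 1) {
      lh <- lhs::randomLHS(starts - 1, S)
      pts <- rbind(pts, bounds[1] + lh * (bounds[2] - bounds[1]))
    }
    pts
  })

  runs <- vector("list", starts)
  for (s in seq_len(starts)) {
    fit <- tryCatch(
      optim(start_pts[s, ], objective, method = "L-BFGS-B",
            lower = bounds[1], upper = bounds[2],
            control = list(fnscale = -yscale, ndeps = rep(1e-3, S),
                           maxit = 60)),
      error = function(e) NULL)
    if (is.null(fit)) { runs[[s]] <- list(feasible = FALSE); next }
    # re-verify the hard constraint without the penalty
    chk <- eval_policy(fit$par)
    feas <- all(chk$bratio >= thr * (1 - 1e-9))
    runs[[s]] <- list(par = setNames(fit$par, sp), yield = chk$yield,
                      bratio = chk$bratio, feasible = feas,
                      value = fit$value, convergence = fit$convergence)
    if (!quiet)
      message(sprintf("start %d: yield %.4g feasible %s", s, chk$yield, feas))
  }

  feas_runs <- Filter(function(r) isTRUE(r$feasible), runs)
  if (!length(feas_runs)) {
    return(structure(list(nutrient = nutrient, F_star = NULL,
                          yield_star = NA_real_, feasible = FALSE,
                          biomass_ratio = NULL, degenerate = degenerate,
                          n_evaluations = n_eval, starts = runs,
                          baseline = baseline, baseline_yield = base_eval$yield,
                          deltas = NULL),
                     class = "mny_optim"))
  }
  best <- feas_runs[[which.max(vapply(feas_runs, `[[`, numeric(1), "yield"))]]
  structure(list(nutrient = nutrient, F_star = best$par,
                 yield_star = best$yield, feasible = TRUE,
                 biomass_ratio = best$bratio, degenerate = degenerate,
                 n_evaluations = n_eval, starts = runs, baseline = baseline,
                 baseline_yield = base_eval$yield, deltas = NULL),
            class = "mny_optim")
}

#' @export
print.mny_optim <- function(x, ...) {
  cat("Nutrient-yield optimisation:", x$nutrient, "\n")
  if (!x$feasible) {
    cat("  no feasible optimum found (", x$n_evaluations, "evaluations )\n")
    return(invisible(x))
  }
  cat(sprintf("  yield %.4g /yr after %d evaluations%s\n", x$yield_star,
              x$n_evaluations,
              if (x$degenerate) " [degenerate: all concentrations zero]" else ""))
  print(round(x$F_star, 3))
  invisible(x)
}

#' Changes relative to a baseline fishing policy
#'
#' Runs the baseline policy and the optimised policy to equilibrium and
#' reports relative changes `(optimised - baseline) / baseline` in the target
#' nutrient's yield, total catch and fishable biomass, plus the per-species
#' relative change in fishing mortality. A delta against a zero baseline
#' value is reported as `NA`.
#'
#' @param result A `mny_optim` from [optimise_nutrient()].
#' @param model The same `mny_model`.
#' @param profiles The nutrient concentration table.
#' @param eq_control Equilibrium settings, as in [optimise_nutrient()].
#' @return The `mny_optim` with its `deltas` field populated: list with
#'   `nutrient_yield`, `total_catch`, `fishable_biomass`, `F_species` (named
#'   vector).
#' @export
deltas_vs_baseline <- function(result, model, profiles,
                               eq_control = list(tol = 1e-4, t_max = 150,
                                                 window = 5)) {
  stopifnot(inherits(result, "mny_optim"), inherits(model, "mny_model"))
  if (!result$feasible) stop("no feasible optimum to compare")
  ec <- modifyList(list(tol = 1e-4, t_max = 150, window = 5), eq_control)
  run <- function(fvec) {
    st <- project_to_equilibrium(model, fvec, tol = ec$tol,
                                 t_max = ec$t_max, window = ec$window)
    catch <- species_yield(model, st, fvec)
    list(ny = sum(nutrient_yield(catch, profiles)[result$nutrient]),
         catch = sum(catch),
         fishable = biomass_indicators(model, st, fvec)$fishable_biomass)
  }
  b <- run(result$baseline)
  o <- run(result$F_star)
  rel <- function(opt, base) if (base == 0) NA_real_ else (opt - base) / base
  dF <- ifelse(result$baseline == 0, NA_real_,
               (result$F_star - result$baseline) / result$baseline)
  result$deltas <- list(nutrient_yield = rel(o$ny, b$ny),
                        total_catch = rel(o$catch, b$catch),
                        fishable_biomass = rel(o$fishable, b$fishable),
                        F_species = setNames(dF, names(result$baseline)))
  result
}
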