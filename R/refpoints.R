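# yield curves over a community exploitation gradient and the mMSY / mMNY
# reference points derived from them

#' Per-species fishing mortality at maximum sustainable yield
#'
#' Estimates each species' fishing mortality at maximum equilibrium yield
#' (F_MSY) inside the interacting community: species are taken one at a time,
#' the focal species' fishing level is varied while all other species are held
#' at their current F_MSY estimates, and the procedure is iterated across
#' species until the F_MSY vector changes by less than `round_tol` between
#' rounds. Each single-species maximisation scans a coarse grid and refines
#' the best bracket by golden-section search.
#'
#' @param model A `mny_model`.
#' @param f_range Search range for the fishing level (1/yr).
#' @param f_init Background fishing level all species start at.
#' @param coarse_n Number of coarse grid points in the first round.
#' @param gs_tol Golden-section interval width at which to stop (1/yr).
#' @param round_tol Relative change in the F_MSY vector below which iteration
#'   stops.
#' @param max_rounds Maximum number of across-species rounds.
#' @param eq_control List overriding the equilibrium settings used for the
#'   many inner evaluations (`tol`, `t_max`, `window`); defaults trade a
#'   little equilibrium precision for speed.
#' @param quiet Suppress progress messages.
#' @return Object of class `mny_refpoints`: data.frame with columns `species`,
#'   `F_MSY` (1/yr), `yield_at_FMSY` (tonnes/yr), `B0` (unfished biomass,
#'   tonnes), plus attributes `rounds` and `converged`.
#' @export
estimate_fmsy <- function(model, f_range = c(0.01, 4), f_init = 0.5,
                          coarse_n = 8, gs_tol = 0.002, round_tol = 0.01,
                          max_rounds = 10,
                          eq_control = list(tol = 1e-4, t_max = 150,
                                            window = 5),
                          quiet = TRUE) {
  stopifnot(inherits(model, "mny_model"))
  sp <- model$species$name
  S <- length(sp)
  uncatchable <- rowSums(model$Funit) == 0
  if (any(uncatchable))
    stop("no fishable selectivity for species: ",
         paste(sp[uncatchable], collapse = ", "))
  ec <- modifyList(list(tol = 1e-4, t_max = 150, window = 5), eq_control)

  eq0 <- project_to_equilibrium(model)
  B0 <- species_biomass(model, eq0)
  state <- eq0
  evaluate <- function(fvec, i) {
    st <- project_to_equilibrium(model, fvec, state = state, tol = ec$tol,
                                 t_max = ec$t_max, window = ec$window)
    state <<- st
    species_yield(model, st, fvec)[i]
  }

  fmsy <- setNames(rep(f_init, S), sp)
  rounds <- 0L
  converged <- FALSE
  phi <- (sqrt(5) - 1) / 2
  for (round in seq_len(max_rounds)) {
    rounds <- round
    f_prev <- fmsy
    for (i in seq_len(S)) {
      fvec <- fmsy
      yield_at <- function(f) { fvec[i] <- f; evaluate(fvec, i) }
      if (round == 1) {
        grid <- seq(f_range[1], f_range[2], length.out = coarse_n)
      } else {
        grid <- sort(unique(pmin(pmax(
          fmsy[i] * c(0.6, 0.85, 1, 1.2, 1.6), f_range[1]), f_range[2])))
      }
      ys <- vapply(grid, yield_at, numeric(1))
      k <- which.max(ys)
      lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
      # golden-section refinement of the bracket
      x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
      y1 <- yield_at(x1); y2 <- yield_at(x2)
      # stop when the bracket is narrow in absolute AND relative terms, so
      # low-F species are resolved as finely as high-F ones
      while (hi - lo > max(gs_tol, 0.5 * round_tol * (lo + hi))) {
        if (y1 >= y2) {
          hi <- x2; x2 <- x1; y2 <- y1
          x1 <- hi - phi * (hi - lo); y1 <- yield_at(x1)
        } else {
          lo <- x1; x1 <- x2; y1 <- y2
          x2 <- lo + phi * (hi - lo); y2 <- yield_at(x2)
        }
      }
      fmsy[i] <- (lo + hi) / 2
    }
    ch <- max(abs(fmsy - f_prev) / pmax(f_prev, 1e-12))
    if (!quiet)
      message(sprintf("F_MSY round %d: max change %.3f", round, ch))
    if (ch < round_tol) { converged <- TRUE; break }
  }

  yfin <- vapply(seq_len(S), function(i) evaluate(fmsy, i), numeric(1))
  out <- data.frame(species = sp, F_MSY = unname(fmsy),
                    yield_at_FMSY = unname(yfin), B0 = unname(B0))
  structure(out, rounds = rounds, converged = converged,
            class = c("mny_refpoints", "data.frame"))
}

#' Nutrient yield from catches and concentration profiles
#'
#' Multiplies each species' catch by its nutrient concentrations and sums
#' across species: `Y_n = sum_i C_i c_in * 1e4`. The factor 1e4 converts
#' (amount per 100 g) x (tonnes) into an absolute amount per year (1 tonne =
#' 1e4 x 100 g), so e.g. mg/100 g concentrations and tonne catches give mg/yr.
#'
#' @param catch Named vector of catches (tonnes/yr), or a matrix with one
#'   column per species (columns named by species).
#' @param profiles Data.frame with column `species` and one column per
#'   nutrient (any subset of [nutrient_names()]).
#' @return Named vector of per-nutrient yields (amount/yr), or a matrix with
#'   one row per row of `catch`.
#' @export
#' @examples
#' prof <- data.frame(species = c("a", "b"), iron = c(2, 4))
#' nutrient_yield(c(a = 100, b = 50), prof)  # (100*2 + 50*4) * 1e4 mg/yr
nutrient_yield <- function(catch, profiles) {
  mat <- is.matrix(catch)
  if (!mat) catch <- matrix(catch, nrow = 1,
                            dimnames = list(NULL, names(catch)))
  if (is.null(colnames(catch))) stop("catch must be named by species")
  nut_cols <- intersect(NUTRIENTS, names(profiles))
  if (!length(nut_cols)) stop("profiles contain no recognised nutrient columns")
  idx <- match(colnames(catch), profiles$species)
  if (anyNA(idx))
    stop("missing nutrient profile for species: ",
         paste(colnames(catch)[is.na(idx)], collapse = ", "))
  conc <- as.matrix(profiles[idx, nut_cols, drop = FALSE])
  if (any(conc < 0)) stop("nutrient concentrations must be non-negative")
  out <- catch %*% conc * 1e4
  colnames(out) <- nut_cols
  if (mat) out else out[1, ]
}

#' Sweep a community exploitation gradient
#'
#' Builds the yield curve underlying the mMSY / mMNY reference points: for
#' each effort multiplier `E` on the grid, every species is fished at
#' `E x F_MSY_i`, the community is run to equilibrium (warm-started from the
#' previous grid point), and catches, nutrient yields, biomass indicators,
#' exploitation rate (total catch / total biomass) and stock-collapse flags
#' are recorded. A species is collapsed when its equilibrium biomass falls
#' below the collapse threshold (default 10%) of its unfished biomass; the
#' sweep truncates after the first effort at which community biomass falls
#' below that same fraction of unfished community biomass or more than half
#' the stocks are collapsed.
#'
#' @param model A `mny_model`.
#' @param refpoints A `mny_refpoints` from [estimate_fmsy()] (or a data.frame
#'   with `species` and `F_MSY`).
#' @param profiles Nutrient concentration table (see [nutrient_yield()]).
#' @param effort_max,effort_step Effort grid `seq(0, effort_max, effort_step)`.
#' @param efforts Explicit effort grid overriding the above; must start at 0
#'   and increase.
#' @param eq_control Optional list overriding equilibrium `tol`, `t_max`,
#'   `window` for the per-row projections (defaults to the model numerics).
#' @param quiet Suppress progress messages.
#' @return Object of class `mny_yield_curve`: list with `efforts`,
#'   `catch` (effort x species, tonnes/yr), `nutrient_yield` (effort x
#'   nutrient), `community_biomass`, `fishable_biomass`, `mean_max_size`,
#'   `exploitation_rate`, `n_collapsed`, `collapsed` (logical effort x
#'   species), `converged`, and attributes `B0`, `fmsy`, `truncated`.
#' @export
sweep_effort <- function(model, refpoints, profiles,
                         effort_max = 4, effort_step = 0.05, efforts = NULL,
                         eq_control = list(), quiet = TRUE) {
  stopifnot(inherits(model, "mny_model"))
  if (is.null(efforts)) efforts <- seq(0, effort_max, by = effort_step)
  if (efforts[1] != 0) stop("effort grid must start at 0 (unfished)")
  if (any(diff(efforts) <= 0)) stop("effort grid must be strictly increasing")
  sp <- model$species$name
  idx <- match(sp, refpoints$species)
  if (anyNA(idx)) stop("refpoints must cover every species")
  fmsy <- setNames(refpoints$F_MSY[idx], sp)
  ec <- modifyList(model$numerics[c("tol", "t_max", "window")], eq_control)
  thr <- model$thresholds$collapse

  nE <- length(efforts)
  catch <- matrix(NA_real_, nE, length(sp), dimnames = list(NULL, sp))
  collapsed <- matrix(NA, nE, length(sp), dimnames = list(NULL, sp))
  comm_b <- fish_b <- mean_sz <- expl <- numeric(nE)
  conv <- logical(nE)

  state <- initial_state(model)
  B0 <- NULL
  last <- nE
  for (k in seq_len(nE)) {
    fvec <- fmsy * efforts[k]
    state <- project_to_equilibrium(model, fvec, state = state,
                                    tol = ec$tol, t_max = ec$t_max,
                                    window = ec$window)
    conv[k] <- state$converged
    ind <- biomass_indicators(model, state, fvec)
    if (k == 1) B0 <- ind$biomass
    catch[k, ] <- species_yield(model, state, fvec)
    comm_b[k] <- ind$community_biomass
    fish_b[k] <- ind$fishable_biomass
    mean_sz[k] <- ind$mean_max_size
    expl[k] <- if (ind$community_biomass > 0)
      sum(catch[k, ]) / ind$community_biomass else NA_real_
    collapsed[k, ] <- ind$biomass < thr * B0
    if (!quiet)
      message(sprintf("E = %.2f: catch %.3g, %d collapsed", efforts[k],
                      sum(catch[k, ]), sum(collapsed[k, ])))
    stop_now <- comm_b[k] < thr * sum(B0) ||
      sum(collapsed[k, ]) > 0.5 * length(sp)
    if (stop_now) { last <- k; break }
  }
  keep <- seq_len(last)
  ny <- nutrient_yield(catch[keep, , drop = FALSE], profiles)

  structure(list(efforts = efforts[keep],
                 catch = catch[keep, , drop = FALSE],
                 nutrient_yield = ny,
                 community_biomass = comm_b[keep],
                 fishable_biomass = fish_b[keep],
                 mean_max_size = mean_sz[keep],
                 exploitation_rate = expl[keep],
                 n_collapsed = rowSums(collapsed[keep, , drop = FALSE]),
                 collapsed = collapsed[keep, , drop = FALSE],
                 converged = conv[keep]),
            B0 = B0, fmsy = fmsy, truncated = last < nE,
            class = "mny_yield_curve")
}

#' @export
print.mny_yield_curve <- function(x, ...) {
  cat("Yield curve:", length(x$efforts), "effort levels (0 -",
      max(x$efforts), "),", ncol(x$catch), "species,",
      ncol(x$nutrient_yield), "nutrients",
      if (attr(x, "truncated")) "[truncated by collapse rule]" else "", "\n")
  invisible(x)
}

#' Tidy data.frame view of a yield curve
#'
#' @param x A `mny_yield_curve`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Long data.frame: one row per effort level per series.
#' @export
as.data.frame.mny_yield_curve <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  base <- data.frame(effort = x$efforts,
                     exploitation_rate = x$exploitation_rate,
                     total_catch = rowSums(x$catch),
                     community_biomass = x$community_biomass,
                     fishable_biomass = x$fishable_biomass,
                     mean_max_size = x$mean_max_size,
                     n_collapsed = x$n_collapsed)
  nut <- as.data.frame(x$nutrient_yield)
  names(nut) <- paste0("yield_", names(nut))
  cbind(base, nut)
}

# 3-point quadratic refinement of a grid argmax, clamped to one grid step;
# returns list(x, y) of the refined maximum location and value
refine_argmax <- function(xg, yg) {
  k <- which.max(yg)
  if (k == 1 || k == length(yg))
    return(list(x = xg[k], y = yg[k], index = k))
  y1 <- yg[k - 1]; y2 <- yg[k]; y3 <- yg[k + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(list(x = xg[k], y = yg[k], index = k))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-1, min(1, delta))
  h <- (xg[k + 1] - xg[k - 1]) / 2
  yref <- y2 + 0.5 * (y3 - y1) * delta + 0.5 * denom * delta^2
  list(x = xg[k] + delta * h, y = yref, index = k)
}

#' Reference points from a yield curve
#'
#' Locates the multispecies maximum sustainable yield (mMSY: maximum total
#' catch) and, per nutrient, the multispecies maximum nutrient yield (mMNY),
#' together with the community fishing levels producing them (F_mMSY and
#' F_mMNY on the effort-multiplier axis, with the corresponding exploitation
#' rates also reported). Grid argmaxes are refined by 3-point quadratic
#' interpolation, clamped to one grid step. A nutrient is classified
#' `"overfished"` when F_mMNY < F_mMSY beyond `tolerance`, `"underfished"`
#' when above, `"neutral"` within it. `yield_at_mMSY_fraction` is the
#' nutrient yield at the catch-maximising grid point as a fraction of the
#' nutrient's own grid maximum.
#'
#' @param curve A `mny_yield_curve`.
#' @param tolerance Relative tolerance on F_mMNY / F_mMSY for the neutral
#'   classification (default 0.05).
#' @return Object of class `mny_curve_summary`: list with `mMSY`, `F_mMSY`,
#'   `exploitation_at_mMSY` and a data.frame `nutrients` with columns
#'   `nutrient`, `mMNY`, `F_mMNY`, `exploitation_at_mMNY`, `ratio`
#'   (F_mMNY / F_mMSY), `classification`, `yield_at_mMSY_fraction`.
#' @export
summarise_curve <- function(curve, tolerance = 0.05) {
  stopifnot(inherits(curve, "mny_yield_curve"))
  if (length(curve$efforts) < 3)
    stop("curve needs at least 3 effort levels")
  total <- rowSums(curve$catch)
  if (all(total == 0)) stop("all-zero catch curve")
  expl_at <- function(e) approx(curve$efforts, curve$exploitation_rate, e,
                                rule = 2)$y
  rt <- refine_argmax(curve$efforts, total)
  nuts <- colnames(curve$nutrient_yield)
  rows <- lapply(nuts, function(nu) {
    y <- curve$nutrient_yield[, nu]
    if (all(y == 0)) {
      return(data.frame(nutrient = nu, mMNY = 0, F_mMNY = NA_real_,
                        exploitation_at_mMNY = NA_real_, ratio = NA_real_,
                        classification = NA_character_,
                        yield_at_mMSY_fraction = NA_real_))
    }
    rn <- refine_argmax(curve$efforts, y)
    ratio <- rn$x / rt$x
    cls <- if (!is.finite(ratio)) NA_character_
    else if (abs(ratio - 1) <= tolerance) "neutral"
    else if (ratio < 1) "overfished" else "underfished"
    data.frame(nutrient = nu, mMNY = rn$y, F_mMNY = rn$x,
               exploitation_at_mMNY = expl_at(rn$x), ratio = ratio,
               classification = cls,
               yield_at_mMSY_fraction = y[rt$index] / y[rn$index])
  })
  structure(list(mMSY = rt$y, F_mMSY = rt$x,
                 exploitation_at_mMSY = expl_at(rt$x),
                 mMSY_index = rt$index,
                 nutrients = do.call(rbind, rows),
                 tolerance = tolerance),
            class = "mny_curve_summary")
}

#' @export
print.mny_curve_summary <- function(x, ...) {
  cat(sprintf("mMSY %.4g t/yr at community fishing level %.3f (exploitation rate %.3f)\n",
              x$mMSY, x$F_mMSY, x$exploitation_at_mMSY))
  print(x$nutrients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rescale yield-curve series as proportions of their maxima
#'
#' @param curve A `mny_yield_curve`.
#' @return Data.frame with `effort`, `exploitation_rate`, and every series
#'   (total catch, each nutrient yield, community and fishable biomass, mean
#'   maximum size) divided by its own maximum, so each has maximum exactly 1.
#'   A series whose maximum is zero is returned as all `NA`.
#' @export
rescale_curves <- function(curve) {
  stopifnot(inherits(curve, "mny_yield_curve"))
  df <- as.data.frame(curve)
  out <- df[c("effort", "exploitation_rate")]
  series <- setdiff(names(df), c("effort", "exploitation_rate", "n_collapsed"))
  for (s in series) {
    mx <- suppressWarnings(max(df[[s]], na.rm = TRUE))
    out[[s]] <- if (is.finite(mx) && mx > 0) df[[s]] / mx else NA_real_
  }
  out$n_collapsed <- df$n_collapsed
  out
}
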