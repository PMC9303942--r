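# community model assembly: precomputes every size-dependent quantity the
# projection kernel needs (intake, metabolism, search rate, maturity
# allocation, predation kernels, per-unit-effort fishing mortality)

#' Build a multispecies size-spectrum community model
#'
#' Assembles a trait-based size-spectrum model from a species parameter table,
#' a gear selectivity table, an interaction matrix and background resource
#' parameters. Individual-level processes follow allometric scaling: maximum
#' intake `h w^n`, standard metabolism `ks w^p`, search volume `gamma w^q`, a
#' lognormal predator-prey size-preference kernel (`beta`, `sigma`), net energy
#' split between somatic growth and reproduction by a maturity ogive, and
#' Beverton-Holt capped recruitment.
#'
#' @param species Species parameter table, see [validate_species_params()].
#' @param gears Gear selectivity table, see [validate_gear_params()].
#' @param interaction Square interaction matrix `theta[i, j]` in `[0, 1]`
#'   giving the availability of prey species `j` to predator species `i`
#'   (rows/cols in species order). Defaults to all ones.
#' @param resource Background resource parameters, see [resource_params()].
#' @param grid Optional [size_grid()]; by default 100 log-spaced bins from the
#'   smallest `w_min` to the largest `w_inf`, with the resource grid extending
#'   3 decades below.
#' @param numerics Optional list overriding any of `dt` (yr), `tol`
#'   (equilibrium tolerance, relative biomass change per year), `t_max` (yr),
#'   `window` (trailing convergence window, yr), `n_bins`, `res_decades`.
#' @param thresholds Optional list overriding `collapse` (fraction of unfished
#'   biomass below which a stock counts as collapsed, default 0.10) and
#'   `neutral` (relative tolerance for calling reference points equal,
#'   default 0.05).
#' @return An object of class `mny_model`.
#' @export
#' @examples
#' com <- make_generic_community(n_species = 3, seed = 1)
#' m <- nym_model(com$species, com$gears)
nym_model <- function(species, gears, interaction = NULL,
                      resource = resource_params(), grid = NULL,
                      numerics = list(), thresholds = list()) {
  species <- as.data.frame(species)
  gears <- as.data.frame(gears)
  validate_species_params(species)
  validate_gear_params(gears, species$name)
  if (!inherits(resource, "mny_resource")) stop("resource must come from resource_params()")

  num <- modifyList(list(dt = 0.1, tol = 1e-5, t_max = 300, window = 10,
                         n_bins = 100, res_decades = 3), numerics)
  thr <- modifyList(list(collapse = 0.10, neutral = 0.05), thresholds)
  if (thr$collapse <= 0 || thr$collapse >= 1)
    stop("collapse threshold must lie in (0, 1)")

  if (is.null(grid)) {
    grid <- size_grid(min(species$w_min), max(species$w_inf),
                      n_bins = num$n_bins, res_decades = num$res_decades)
  }
  if (!inherits(grid, "mny_grid")) stop("grid must come from size_grid()")

  S <- nrow(species)
  nw <- length(grid$w)
  nwf <- length(grid$w_full)

  if (is.null(interaction)) {
    interaction <- matrix(1, S, S, dimnames = list(species$name, species$name))
  }
  interaction <- as.matrix(interaction)
  if (!all(dim(interaction) == c(S, S)))
    stop("interaction matrix must be ", S, " x ", S)
  if (any(interaction < 0 | interaction > 1))
    stop("interaction coefficients must lie in [0, 1]")

  w <- grid$w
  rowfun <- function(f) t(vapply(seq_len(S), f, numeric(nw)))
  intake_max <- rowfun(function(i) species$h[i] * w^species$n[i])
  metab <- rowfun(function(i) species$ks[i] * w^species$p[i])
  search_w <- rowfun(function(i) species$gamma[i] * w^species$q[i])
  # maturity allocation: sigmoid ogive in w/w_mat times (w/w_inf)^(1-n), so
  # that allocation reaches 1 (all net energy to reproduction) at w_inf
  psi <- rowfun(function(i) {
    pmin(1, 1 / (1 + (w / species$w_mat[i])^(-10)) *
           (w / species$w_inf[i])^(1 - species$n[i]))
  })
  gmask <- rowfun(function(i) as.numeric(w <= species$w_inf[i]))
  mu_b <- species$mu_b0 * species$w_inf^(species$n - 1)
  rec_idx <- vapply(species$w_min, function(wm)
    which.min(abs(log(w) - log(wm))), integer(1)) - 1L

  # predation kernels, one slice per unique (beta, sigma) pair
  key <- paste(species$beta, species$sigma)
  groups <- match(key, unique(key))
  K <- array(0, dim = c(nw, nwf, max(groups)))
  for (g in seq_len(max(groups))) {
    i <- which(groups == g)[1]
    K[, , g] <- outer(w, grid$w_full, feeding_kernel,
                      beta = species$beta[i], sigma = species$sigma[i])
  }

  r_res <- resource$r0 * grid$w_full^(resource$n_r - 1)
  cc <- resource$kappa * grid$w_full^(-resource$lambda)
  cc[grid$w_full > resource$w_res_max] <- 0

  # per-unit-effort fishing mortality, by gear and combined per species
  sel_by_gear <- lapply(split(gears, gears$gear), function(gt) {
    Fg <- matrix(0, S, nw)
    for (k in seq_len(nrow(gt))) {
      i <- match(gt$species[k], species$name)
      Fg[i, ] <- Fg[i, ] +
        selectivity_sigmoid(w, gt$w50[k], gt$slope[k]) * gt$Q[k]
    }
    Fg
  })
  Funit <- Reduce(`+`, sel_by_gear, matrix(0, S, nw))
  Smax <- matrix(0, S, nw) # max over gears of raw selectivity, for fishable biomass
  for (k in seq_len(nrow(gears))) {
    i <- match(gears$species[k], species$name)
    Smax[i, ] <- pmax(Smax[i, ], selectivity_sigmoid(w, gears$w50[k], gears$slope[k]))
  }

  cpp <- list(w = w, dw = grid$dw, w_full = grid$w_full, dw_full = grid$dw_full,
              n_res = grid$n_res, intake_max = intake_max, metab = metab,
              search_w = search_w, psi = psi, gmask = gmask, mu_b = mu_b,
              alpha = species$alpha, erepro = species$erepro,
              R_max = species$R_max, w_min = species$w_min,
              rec_idx = rec_idx, kidx = groups - 1L, K = K,
              theta = interaction, theta_res = rep(1, S),
              r_res = r_res, cc = cc)

  structure(list(species = species, gears = gears, interaction = interaction,
                 resource = resource, grid = grid, numerics = num,
                 thresholds = thr, Funit = Funit, Smax = Smax,
                 sel_by_gear = sel_by_gear, cpp = cpp),
            class = "mny_model")
}

#' @export
print.mny_model <- function(x, ...) {
  cat("Multispecies size-spectrum model\n")
  cat("  species:", nrow(x$species), " gears:",
      length(unique(x$gears$gear)), "\n")
  cat("  size grid:", length(x$grid$w), "bins,",
      format(min(x$grid$w), digits = 3), "-",
      format(max(x$grid$w), digits = 3), "g (+",
      x$grid$n_res, "resource bins)\n")
  invisible(x)
}

n_species <- function(model) nrow(model$species)

#' Fishing mortality at size
#'
#' Total fishing mortality `F_i(w) = sum_g S_gi(w) Q_gi E_g`: for each gear the
#' product of its size selectivity, catchability and relative fishing effort,
#' summed over gears.
#'
#' @param model A `mny_model`.
#' @param efforts Named numeric vector of relative efforts `E_g`, one per gear
#'   (gears omitted get effort 0).
#' @param species Optional single species name; if given, returns that
#'   species' mortality-at-size vector instead of the full matrix.
#' @return Species x size matrix of fishing mortality (1/yr), or a vector for
#'   one species.
#' @export
fishing_mortality <- function(model, efforts, species = NULL) {
  stopifnot(inherits(model, "mny_model"))
  if (length(efforts) && is.null(names(efforts)))
    stop("efforts must be named by gear")
  unknown <- setdiff(names(efforts), names(model$sel_by_gear))
  if (length(unknown)) stop("unknown gear(s): ", paste(unknown, collapse = ", "))
  if (any(efforts < 0)) stop("efforts must be non-negative")
  Fm <- matrix(0, n_species(model), length(model$grid$w))
  for (g in names(efforts)) Fm <- Fm + model$sel_by_gear[[g]] * efforts[[g]]
  rownames(Fm) <- model$species$name
  if (!is.null(species)) {
    i <- match(species, model$species$name)
    if (is.na(i)) stop("unknown species: ", species)
    return(Fm[i, ])
  }
  Fm
}

# resolve the F argument accepted throughout: NULL (unfished), a named
# per-species fishing level vector (scales each species' per-unit-effort
# selectivity-at-size), or a full species x size matrix
resolve_F <- function(model, f) {
  S <- n_species(model); nw <- length(model$grid$w)
  if (is.null(f)) return(matrix(0, S, nw))
  if (is.matrix(f)) {
    if (!all(dim(f) == c(S, nw))) stop("F matrix has wrong dimensions")
    return(f)
  }
  if (is.null(names(f))) {
    if (length(f) != S) stop("per-species fishing levels must be named or length ", S)
    names(f) <- model$species$name
  }
  unknown <- setdiff(names(f), model$species$name)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (any(f < 0)) stop("fishing levels must be non-negative")
  lev <- setNames(rep(0, S), model$species$name)
  lev[names(f)] <- f
  model$Funit * lev
}
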