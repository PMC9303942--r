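#' Logarithmic body-size grid
#'
#' Builds the community size grid: `n_bins` logarithmically spaced body masses
#' spanning the community size range, plus an extended grid (`w_full`) that
#' continues the same log spacing downwards to cover the background resource
#' spectrum.
#'
#' @param w_min Smallest fish body mass on the grid (g), typically the smallest
#'   offspring mass in the community.
#' @param w_max Largest body mass (g), typically the largest asymptotic mass.
#' @param n_bins Number of size bins for the fish grid (>= 2).
#' @param res_decades How many decades below `w_min` the resource grid extends.
#' @return An object of class `mny_grid`: list with `w`, `dw` (bin widths from
#'   the log step), `w_full`, `dw_full` and `n_res` (number of resource-only
#'   bins preceding the fish grid inside `w_full`).
#' @export
#' @examples
#' g <- size_grid(1e-3, 1e3, 7)
#' g$w  # successive powers of 10
size_grid <- function(w_min, w_max, n_bins = 100, res_decades = 3) {
  if (!is.numeric(w_min) || !is.numeric(w_max) || w_min <= 0 || w_max <= 0)
    stop("w_min and w_max must be positive masses (g)")
  if (w_max <= w_min)
    stop("w_max must exceed w_min: degenerate size range")
  if (n_bins < 2) stop("n_bins must be at least 2")

  lmin <- log10(w_min); lmax <- log10(w_max)
  dl <- (lmax - lmin) / (n_bins - 1)
  w <- 10^(lmin + dl * (seq_len(n_bins) - 1))
  n_res <- max(1L, as.integer(ceiling(res_decades / dl)))
  w_full <- 10^(lmin + dl * ((-n_res):(n_bins - 1)))
  ratio <- 10^dl
  dw <- w * (ratio - 1)
  dw_full <- w_full * (ratio - 1)

  structure(list(w = w, dw = dw, w_full = w_full, dw_full = dw_full,
                 n_res = n_res, log_step = dl),
            class = "mny_grid")
}

#' Lognormal predator-prey size-preference kernel
#'
#' Preference of a predator of mass `pred_mass` for prey of mass `prey_mass`:
#' `exp(-(log(pred / (beta * prey)))^2 / (2 sigma^2))`. Maximal (= 1) when the
#' predator is exactly `beta` times heavier than the prey, symmetric in log
#' displacement from that preferred ratio.
#'
#' @param pred_mass Predator body mass (g). Recycled against `prey_mass`.
#' @param prey_mass Prey body mass (g).
#' @param beta Preferred predator:prey mass ratio (> 1).
#' @param sigma Diet breadth, standard deviation on the natural-log scale (> 0).
#' @return Preference values in (0, 1].
#' @export
#' @examples
#' feeding_kernel(100, 1, beta = 100, sigma = 1)  # at the mode: 1
feeding_kernel <- function(pred_mass, prey_mass, beta, sigma) {
  if (any(pred_mass <= 0) || any(prey_mass <= 0))
    stop("masses must be positive")
  if (any(beta <= 1)) stop("beta must exceed 1")
  if (any(sigma <= 0)) stop("sigma must be positive")
  exp(-log(pred_mass / (beta * prey_mass))^2 / (2 * sigma^2))
}

#' Sigmoidal trawl selectivity at size
#'
#' Standard trawl selection ogive on the log-mass axis:
#' `S(w) = 1 / (1 + exp(-slope * (log w - log w50)))`.
#'
#' @param w Body mass (g).
#' @param w50 Mass at 50% retention (g).
#' @param slope Steepness of the ogive on the log-mass axis (> 0).
#' @return Selectivity values in (0, 1).
#' @export
selectivity_sigmoid <- function(w, w50, slope) {
  if (any(w50 <= 0) || any(slope <= 0)) stop("w50 and slope must be positive")
  1 / (1 + exp(-slope * (log(w) - log(w50))))
}
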