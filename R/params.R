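# species, gear and resource parameter tables with validation

SPECIES_COLS <- c("name", "w_min", "w_mat", "w_inf", "L_inf", "h", "n",
                  "gamma", "q", "beta", "sigma", "alpha", "ks", "p",
                  "mu_b0", "erepro", "R_max")
GEAR_COLS <- c("gear", "species", "w50", "slope", "Q")

#' Validate a species parameter table
#'
#' Checks the life-history / feeding / mortality / recruitment parameter table
#' used to build a community model. Columns: `name`, offspring mass `w_min`,
#' maturation mass `w_mat`, asymptotic mass `w_inf` (all g), asymptotic length
#' `L_inf` (cm), maximum intake coefficient `h` and exponent `n`, search-volume
#' coefficient `gamma` and exponent `q`, preferred predator:prey mass ratio
#' `beta`, diet breadth `sigma`, assimilation efficiency `alpha`, standard
#' metabolism coefficient `ks` and exponent `p`, background mortality
#' coefficient `mu_b0` (1/yr), reproduction efficiency `erepro`, and maximum
#' recruitment `R_max` (numbers/yr).
#'
#' @param species A data.frame with the columns above.
#' @return The validated data.frame (invisibly unchanged), or an error naming
#'   offending rows.
#' @export
validate_species_params <- function(species) {
  if (!is.data.frame(species)) stop("species must be a data.frame")
  missing_cols <- setdiff(SPECIES_COLS, names(species))
  if (length(missing_cols))
    stop("species table is missing columns: ", paste(missing_cols, collapse = ", "))
  num <- setdiff(SPECIES_COLS, "name")
  for (cl in num) {
    if (!is.numeric(species[[cl]]))
      stop("species column '", cl, "' must be numeric")
  }
  if (anyDuplicated(species$name))
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      stop("species table row(s) ", paste(idx, collapse = ", "), ": ", msg)
  }
  bad(!(species$w_min > 0 & species$w_min < species$w_mat),
      "need 0 < w_min < w_mat")
  bad(!(species$w_mat < species$w_inf), "need w_mat < w_inf")
  bad(!(species$beta > 1), "need beta > 1")
  bad(!(species$sigma > 0), "need sigma > 0")
  bad(!(species$alpha > 0 & species$alpha <= 1), "need 0 < alpha <= 1")
  bad(!(species$R_max > 0), "need R_max > 0")
  bad(!(species$h > 0 & species$gamma >= 0 & species$ks >= 0),
      "need h > 0, gamma >= 0, ks >= 0")
  bad(!(species$erepro > 0 & species$erepro <= 1), "need 0 < erepro <= 1")
  bad(!(species$mu_b0 >= 0), "need mu_b0 >= 0")
  invisible(species)
}

#' Validate a gear selectivity table
#'
#' One row per (gear, species) combination: `gear` and `species` labels, mass
#' at 50% selection `w50` (g), ogive `slope`, and catchability `Q`.
#'
#' @param gears A data.frame with columns `gear`, `species`, `w50`, `slope`, `Q`.
#' @param species_names Optional character vector; every `species` entry must
#'   be among them.
#' @return The validated data.frame, invisibly.
#' @export
validate_gear_params <- function(gears, species_names = NULL) {
  if (!is.data.frame(gears)) stop("gears must be a data.frame")
  missing_cols <- setdiff(GEAR_COLS, names(gears))
  if (length(missing_cols))
    stop("gear table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(gears$w50 <= 0)) stop("gear w50 must be positive")
  if (any(gears$slope <= 0)) stop("gear slope must be positive")
  if (any(gears$Q < 0)) stop("gear Q must be non-negative")
  if (!is.null(species_names)) {
    unknown <- setdiff(gears$species, species_names)
    if (length(unknown))
      stop("gear table refers to unknown species: ",
           paste(unknown, collapse = ", "))
  }
  invisible(gears)
}

#' Background resource parameters
#'
#' Semi-chemostat background resource spectrum: carrying capacity
#' `kappa * w^-lambda` up to `w_res_max`, regenerating at rate
#' `r0 * w^(n_r - 1)` towards capacity.
#'
#' @param kappa Resource spectrum magnitude (numbers g^-1 per unit area scale).
#' @param lambda Resource spectrum exponent (~ 2 for marine communities).
#' @param r0 Regeneration rate coefficient (1/yr).
#' @param w_res_max Largest resource size (g); capacity is zero above it.
#' @param n_r Allometric exponent of the regeneration rate.
#' @return A list of class `mny_resource`.
#' @export
resource_params <- function(kappa = 1e11, lambda = 2.05, r0 = 10,
                            w_res_max = 100, n_r = 0.75) {
  if (kappa <= 0) stop("kappa must be positive")
  if (r0 <= 0) stop("r0 must be positive")
  if (w_res_max <= 0) stop("w_res_max must be positive")
  structure(list(kappa = kappa, lambda = lambda, r0 = r0,
                 w_res_max = w_res_max, n_r = n_r),
            class = "mny_resource")
}

#' Search-volume coefficient from an initial feeding level
#'
#' Chooses `gamma` so that a consumer feeding on an unperturbed power-law
#' resource spectrum `kappa w^-lambda` realises feeding level `f0`,
#' independent of size when `q = n + lambda - 2`.
#'
#' @param f0 Target feeding level in (0, 1).
#' @param h Maximum intake coefficient.
#' @param beta,sigma Kernel parameters.
#' @param kappa,lambda Resource spectrum parameters.
#' @return The coefficient `gamma`.
#' @export
gamma_from_f0 <- function(f0 = 0.6, h = 40, beta = 100, sigma = 1.3,
                          kappa = 1e11, lambda = 2.05) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie in (0, 1)")
  lam2 <- lambda - 2
  alpha_e <- sqrt(2 * pi) * sigma * beta^lam2 * exp(lam2^2 * sigma^2 / 2)
  f0 * h / ((1 - f0) * kappa * alpha_e)
}
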