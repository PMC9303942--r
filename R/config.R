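# run configuration: defaults plus YAML overrides

#' Default run configuration
#'
#' The configuration consumed by the command-line interface and convenient
#' for scripted runs: grid settings, projection numerics, effort-grid and
#' optimiser settings, thresholds, and the seed governing all randomness.
#'
#' @return Nested list with sections `grid` (`n_bins`, `res_decades`),
#'   `numerics` (`dt`, `tol`, `t_max`, `window`), `resource` (`kappa`,
#'   `lambda`, `r0`, `w_res_max`), `effort` (`max`, `step`), `optimiser`
#'   (`lower`, `upper`, `starts`), `thresholds` (`collapse`, `neutral`) and
#'   `seed`.
#' @export
default_config <- function() {
  list(grid = list(n_bins = 100, res_decades = 3),
       numerics = list(dt = 0.1, tol = 1e-5, t_max = 300, window = 10),
       resource = list(kappa = 1e11, lambda = 2.05, r0 = 10, w_res_max = 100),
       effort = list(max = 4, step = 0.05),
       optimiser = list(lower = 0.01, upper = 2, starts = 5),
       thresholds = list(collapse = 0.10, neutral = 0.05),
       seed = 1)
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; sections and keys
#' not present keep their defaults, unknown sections are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  out <- modifyList(cfg, user)
  if (out$thresholds$collapse <= 0 || out$thresholds$collapse >= 1)
    stop("thresholds$collapse must lie in (0, 1)")
  if (out$optimiser$lower >= out$optimiser$upper)
    stop("optimiser bounds must be ordered")
  out
}

# model construction from a config plus parameter tables
model_from_config <- function(species, gears, interaction, cfg) {
  nym_model(species, gears, interaction = interaction,
            resource = resource_params(kappa = cfg$resource$kappa,
                                       lambda = cfg$resource$lambda,
                                       r0 = cfg$resource$r0,
                                       w_res_max = cfg$resource$w_res_max),
            numerics = c(cfg$numerics, cfg$grid),
            thresholds = cfg$thresholds)
}
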