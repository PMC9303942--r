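# synthetic inputs: generic interacting communities, nutrient concentration
# tables, and reconstructed-catch style regional catch tables

# lognormal medians per nutrient, amount per 100 g edible tissue
# (calcium/iron/zinc mg; selenium/vitamin_a/vitamin_d ug; omega3 g)
NUTRIENT_MEDIANS <- c(calcium = 50, iron = 1, zinc = 1, selenium = 40,
                      vitamin_a = 30, vitamin_d = 5, omega3 = 0.5)

#' Generate a generic interacting fish community
#'
#' Builds the parameter tables for a trait-based community of `n_species`
#' interacting species with asymptotic masses log-spaced across
#' `w_inf_range`, one trawl gear per species, and a nutrient concentration
#' profile per species. Life-history allometries follow standard trait-based
#' conventions: `w_mat = 0.25 w_inf`, maximum recruitment
#' `R_max` proportional to `w_inf^-1.5`, gear mass at 50% selection
#' `0.05 w_inf` with catchability 1.
#'
#' Nutrient concentrations are drawn lognormally per nutrient. In
#' `"size-correlated"` mode (the default) log-concentrations load negatively on
#' log `w_inf`, so smaller, more productive species tend to be more nutritious
#' - the pattern that makes nutrient and catch reference points diverge.
#'
#' @param n_species Number of species (>= 1), default 15.
#' @param w_inf_range Range of asymptotic masses (g), default 10 g - 100 kg.
#' @param nutrient_model `"size-correlated"` or `"independent"`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param kappa Resource magnitude used to scale `gamma` and `R_max`.
#' @param size_loading Loading of standardised negative log `w_inf` on
#'   log-concentration in size-correlated mode.
#' @param conc_sd Residual lognormal sd of log-concentrations.
#' @param w_inf Optional explicit vector of asymptotic masses (g) overriding
#'   the log-spaced default; its length sets `n_species`.
#' @return List with `species`, `gears`, `nutrients` (one row per species,
#'   one column per nutrient) and `interaction` (all ones).
#' @export
#' @examples
#' com <- make_generic_community(n_species = 5, seed = 1)
#' com$species$w_inf
make_generic_community <- function(n_species = 15,
                                   w_inf_range = c(10, 1e5),
                                   nutrient_model = c("size-correlated",
                                                      "independent"),
                                   seed = 1, kappa = 1e11,
                                   size_loading = 0.5, conc_sd = 0.4,
                                   w_inf = NULL) {
  nutrient_model <- match.arg(nutrient_model)
  if (!is.null(w_inf)) {
    if (any(w_inf <= 0)) stop("w_inf values must be positive")
    n_species <- length(w_inf)
  }
  if (n_species < 1) stop("n_species must be at least 1")
  if (length(w_inf_range) != 2 || any(w_inf_range <= 0) ||
      diff(w_inf_range) <= 0)
    stop("w_inf_range must be an increasing positive pair")

  with_seed(seed, {
    if (is.null(w_inf))
      w_inf <- if (n_species == 1) w_inf_range[2] else
        10^seq(log10(w_inf_range[1]), log10(w_inf_range[2]),
               length.out = n_species)
    n <- 0.75; p <- 0.75; q <- 0.8; lambda <- 2.05
    h <- 40; alpha <- 0.6; beta <- 100; sigma <- 2.2
    ks <- 0.25 * alpha * h # critical feeding level 0.25
    gamma <- gamma_from_f0(0.6, h = h, beta = beta, sigma = sigma,
                           kappa = kappa, lambda = lambda)
    species <- data.frame(
      name = sprintf("species_%02d", seq_len(n_species)),
      w_min = 1e-3,
      w_mat = 0.25 * w_inf,
      w_inf = w_inf,
      L_inf = (100 * w_inf)^(1 / 3), # length-weight a = 0.01, b = 3
      h = h, n = n, gamma = gamma, q = q, beta = beta, sigma = sigma,
      alpha = alpha, ks = ks, p = p, mu_b0 = 2.0, erepro = 0.002,
      R_max = kappa * 5 * w_inf^(-1.5)
    )
    gears <- data.frame(
      gear = paste0("trawl_", species$name),
      species = species$name,
      w50 = 0.05 * w_inf,
      slope = 3,
      Q = 1
    )
    z <- if (n_species == 1) 0 else
      as.vector(scale(log(w_inf)))
    conc <- sapply(NUTRIENTS, function(nu) {
      load <- if (nutrient_model == "size-correlated") -size_loading * z else 0
      NUTRIENT_MEDIANS[[nu]] * exp(load + rnorm(n_species, 0, conc_sd))
    })
    conc <- matrix(conc, nrow = n_species,
                   dimnames = list(NULL, NUTRIENTS))
    nutrients <- data.frame(species = species$name, conc)
    interaction <- matrix(1, n_species, n_species,
                          dimnames = list(species$name, species$name))
    list(species = species, gears = gears, nutrients = nutrients,
         interaction = interaction)
  })
}

#' Generate a regional catch table with species profiles
#'
#' Emulates a reconstructed-catch database: per region, a set of taxa with
#' strongly skewed (lognormal) catch shares, a fraction of records reported
#' only at genus or family rank, and an intrinsic fishing vulnerability score
#' in `[1, 100]` correlated (via a Gaussian copula) with asymptotic length.
#' A companion species-profile table carries genus/family lineage and
#' nutrient concentrations for the species-level taxa, so taxonomic fallback
#' assignment can be exercised.
#'
#' @param n_regions Number of regions (EEZ-like units).
#' @param taxa_per_region Integer range `c(min, max)` of taxa per region.
#' @param share_skew Lognormal sigma of catch shares (0 = even shares).
#' @param rank_missing_rate Fraction of records demoted to genus/family rank.
#' @param vuln_length_corr Correlation between vulnerability and log length.
#' @param n_pool Size of the underlying species pool.
#' @param seed Integer seed.
#' @return List with `catch` (columns `region`, `taxon`, `rank`,
#'   `catch_tonnes`, `vulnerability`) and `profiles` (columns `species`,
#'   `genus`, `family`, `length`, `vulnerability` and the six catch-mode
#'   nutrients).
#' @export
make_catch_table <- function(n_regions = 20, taxa_per_region = c(8, 25),
                             share_skew = 1.5, rank_missing_rate = 0.2,
                             vuln_length_corr = 0.7, n_pool = 60, seed = 1) {
  if (n_regions < 1 || n_pool < 2) stop("need at least 1 region and 2 species")
  if (rank_missing_rate < 0 || rank_missing_rate > 1)
    stop("rank_missing_rate must lie in [0, 1]")
  if (abs(vuln_length_corr) > 1) stop("vuln_length_corr must lie in [-1, 1]")
  if (share_skew < 0) stop("share_skew must be non-negative")
  taxa_per_region <- as.integer(taxa_per_region)
  if (any(taxa_per_region < 1) || taxa_per_region[2] > n_pool)
    stop("taxa_per_region must lie in [1, n_pool]")

  with_seed(seed, {
    n_family <- max(2L, round(n_pool / 10))
    n_genus <- max(3L, round(n_pool / 4))
    genus_family <- sprintf("Family%02d", sample.int(n_family, n_genus,
                                                     replace = TRUE))
    sp_genus <- sample.int(n_genus, n_pool, replace = TRUE)
    profiles <- data.frame(
      species = sprintf("Genus%02d sp%02d", sp_genus, seq_len(n_pool)),
      genus = sprintf("Genus%02d", sp_genus),
      family = genus_family[sp_genus],
      length = rlnorm(n_pool, log(40), 0.8)
    )
    # vulnerability correlated with log length through a Gaussian copula
    zl <- as.vector(scale(log(profiles$length)))
    zv <- vuln_length_corr * zl +
      sqrt(1 - vuln_length_corr^2) * rnorm(n_pool)
    profiles$vulnerability <- 1 + 99 * stats::pnorm(zv)
    for (nu in NUTRIENTS_CATCH)
      profiles[[nu]] <- rlnorm(n_pool, log(NUTRIENT_MEDIANS[[nu]]), 0.6)

    recs <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      k <- taxa_per_region[1] +
        sample.int(taxa_per_region[2] - taxa_per_region[1] + 1L, 1) - 1L
      idx <- sample.int(n_pool, k)
      shares <- rlnorm(k, 0, share_skew)
      shares <- shares / sum(shares)
      total <- rlnorm(1, log(1e5), 1)
      rank <- rep("species", k)
      taxon <- profiles$species[idx]
      demote <- runif(k) < rank_missing_rate
      to_genus <- demote & runif(k) < 0.5
      taxon[to_genus] <- profiles$genus[idx][to_genus]
      rank[to_genus] <- "genus"
      to_family <- demote & !to_genus
      taxon[to_family] <- profiles$family[idx][to_family]
      rank[to_family] <- "family"
      recs[[r]] <- data.frame(
        region = sprintf("region_%02d", r),
        taxon = taxon, rank = rank,
        catch_tonnes = shares * total,
        vulnerability = profiles$vulnerability[idx]
      )
    }
    catch <- do.call(rbind, recs)
    rownames(catch) <- NULL
    list(catch = catch, profiles = profiles)
  })
}

#' Community fixture with a nutrient loaded onto one species
#'
#' Builds a small forage-plus-predators community (one small, highly
#' productive forage species and four larger predator species that dominate
#' total catch and prey on it) in which one nutrient (`"iron"` by default) is
#' concentrated almost entirely on a single species: the species with the
#' highest fishing mortality at maximum sustainable yield (the forage
#' species) for `target_class = "resilient"`, or the lowest (the largest
#' predator) for `"vulnerable"`. Used for directional cross-checks: a
#' resilient loading should put the nutrient's maximum-yield fishing level
#' above the community's catch-maximising level (nutrient underfishing,
#' driven by predation release of the forage stock), and a vulnerable loading
#' below it.
#'
#' By default the target is picked by asymptotic size (smallest = most
#' resilient); pass estimated per-species `fmsy` values to pick it from the
#' model instead.
#'
#' @param target_class `"resilient"` or `"vulnerable"`.
#' @param fmsy Optional named vector of per-species fishing mortality at MSY;
#'   the loading then targets its argmax (resilient) or argmin (vulnerable).
#' @param seed Integer seed for the base community.
#' @param nutrient Which nutrient carries the loading.
#' @return As [make_generic_community()], plus `resource` (the
#'   [resource_params()] the fixture assumes), `target` (the loaded species)
#'   and `nutrient`.
#' @export
make_nutrient_loading_fixture <- function(target_class = c("resilient",
                                                           "vulnerable"),
                                          fmsy = NULL, seed = 42,
                                          nutrient = "iron") {
  target_class <- match.arg(target_class)
  stopifnot(nutrient %in% NUTRIENTS)
  # one forage species plus four piscivores whose preferred prey size sits on
  # the forage adults; the resource is zooplankton-sized so the piscivores
  # genuinely depend on the forage stock
  w_inf <- c(20, 10^seq(log10(500), log10(2000), length.out = 4))
  com <- make_generic_community(w_inf = w_inf,
                                nutrient_model = "independent", seed = seed)
  n_species <- length(w_inf)
  com$species$sigma <- 1.6
  com$species$erepro <- c(0.002, rep(0.1, n_species - 1))
  com$species$R_max[1] <- com$species$R_max[1] * 0.3
  com$species$R_max[-1] <- com$species$R_max[-1] * 3
  theta <- matrix(0, n_species, n_species,
                  dimnames = dimnames(com$interaction))
  theta[-1, 1] <- 1 # piscivores feed on the forage species only
  com$interaction <- theta
  com$resource <- resource_params(w_res_max = 2)
  if (!is.null(fmsy)) {
    fmsy <- fmsy[com$species$name]
    target <- if (target_class == "resilient")
      which.max(fmsy) else which.min(fmsy)
  } else {
    # the forage species withstands the highest F, the largest predator the
    # lowest
    target <- if (target_class == "resilient")
      which.min(com$species$w_inf) else which.max(com$species$w_inf)
  }
  base <- NUTRIENT_MEDIANS[[nutrient]]
  conc <- rep(0.02 * base, n_species)
  conc[target] <- 20 * base
  com$nutrients[[nutrient]] <- conc
  com$target <- com$species$name[target]
  com$nutrient <- nutrient
  com
}
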