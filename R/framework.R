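# evenness-vulnerability framework: predicting nutrient over-/underfishing
# from the composition of catches

#' Pielou's evenness
#'
#' Shannon diversity of the positive shares divided by the log of the number
#' of positive entries: `J = (-sum p log p) / log(S+)`. With a single
#' contributing taxon the index is defined as 0 (a catch dominated by one
#' stock is maximally uneven); zero-weight taxa do not count towards
#' richness.
#'
#' @param weights Non-negative weights (catches or nutrient yields).
#' @return Evenness in `[0, 1]`.
#' @export
#' @examples
#' pielou_evenness(c(0.5, 0.25, 0.25))  # 0.946
pielou_evenness <- function(weights) {
  if (any(is.na(weights)) || any(weights < 0))
    stop("weights must be non-negative and non-missing")
  w <- weights[weights > 0]
  if (!length(w)) stop("at least one weight must be positive")
  if (length(w) == 1) return(0)
  p <- w / sum(w)
  -sum(p * log(p)) / log(length(w))
}

#' Weighted mean fishing vulnerability
#'
#' Mean vulnerability across taxa weighted by catch or nutrient yield:
#' `V = sum(w v) / sum(w)`. The vulnerability scores can be per-species
#' fishing mortality at maximum sustainable yield (`mode = "fmsy"`, 1/yr,
#' higher = more resilient) or an intrinsic vulnerability index
#' (`mode = "index"`, 1-100, higher = more vulnerable).
#'
#' @param weights Non-negative weights, summing to a positive value.
#' @param vuln Vulnerability score per taxon, aligned with `weights`.
#' @param mode `"index"` or `"fmsy"`; recorded as an attribute.
#' @return Weighted mean vulnerability, with attribute `mode`.
#' @export
#' @examples
#' weighted_vulnerability(c(100, 50), c(30, 60))  # 40
weighted_vulnerability <- function(weights, vuln, mode = c("index", "fmsy")) {
  mode <- match.arg(mode)
  if (length(weights) != length(vuln)) stop("weights and vuln must align")
  if (any(is.na(weights)) || any(weights < 0))
    stop("weights must be non-negative and non-missing")
  if (sum(weights) <= 0) stop("total weight must be positive")
  bad <- weights > 0 & is.na(vuln)
  if (any(bad))
    stop("missing vulnerability for positively-weighted taxa: ",
         paste(which(bad), collapse = ", "))
  keep <- weights > 0
  structure(sum(weights[keep] * vuln[keep]) / sum(weights[keep]), mode = mode)
}

#' Resolve nutrient profiles onto catch records
#'
#' Attaches nutrient concentrations to each catch record. Species-rank
#' records get their own profile; genus- and family-rank records get the
#' unweighted mean concentration across the species of that genus or family
#' in the profile table; records that cannot be resolved are flagged
#' (`resolved = FALSE`) and their count reported in a message.
#'
#' @param records Catch table: data.frame with columns `region`, `taxon`,
#'   `rank` (`"species"`, `"genus"` or `"family"`), `catch_tonnes`,
#'   `vulnerability`.
#' @param species_profiles Data.frame keyed by `species` with `genus` and
#'   `family` columns plus nutrient concentration columns.
#' @param nutrients Which nutrient columns to resolve (default: those present).
#' @param quiet Suppress the exclusion-count message.
#' @return `records` with one concentration column per nutrient and a logical
#'   `resolved` column; attribute `n_excluded` counts unresolved records.
#' @export
resolve_profiles <- function(records, species_profiles,
                             nutrients = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(records), is.data.frame(species_profiles))
  need <- c("region", "taxon", "rank", "catch_tonnes")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$rank %in% c("species", "genus", "family")))
    stop("rank must be species, genus or family")
  if (is.null(nutrients))
    nutrients <- intersect(NUTRIENTS, names(species_profiles))
  if (!length(nutrients)) stop("species_profiles contain no nutrient columns")

  conc <- matrix(NA_real_, nrow(records), length(nutrients),
                 dimnames = list(NULL, nutrients))
  for (r in seq_len(nrow(records))) {
    rk <- records$rank[r]; tx <- records$taxon[r]
    rows <- switch(rk,
                   species = which(species_profiles$species == tx),
                   genus = which(species_profiles$genus == tx),
                   family = which(species_profiles$family == tx))
    if (length(rows))
      conc[r, ] <- colMeans(species_profiles[rows, nutrients, drop = FALSE])
  }
  resolved <- !is.na(conc[, 1])
  out <- cbind(records, as.data.frame(conc))
  out$resolved <- resolved
  n_exc <- sum(!resolved)
  if (n_exc && !quiet)
    message(n_exc, " record(s) could not be resolved to a nutrient profile ",
            "and are flagged resolved = FALSE")
  attr(out, "n_excluded") <- n_exc
  out
}

#' Per-taxon nutrient-yield weights
#'
#' Converts resolved catch records into nutrient-yield weights,
#' `catch x concentration x 1e4` (same unit convention as
#' [nutrient_yield()]).
#'
#' @param records Resolved records (see [resolve_profiles()]); unresolved
#'   records are an error.
#' @param nutrient Nutrient name (a concentration column of `records`).
#' @return Numeric vector of weights aligned with `records` rows.
#' @export
nutrient_weights <- function(records, nutrient) {
  if (!nutrient %in% names(records))
    stop("records lack a '", nutrient, "' concentration column; ",
         "run resolve_profiles() first")
  conc <- records[[nutrient]]
  if (anyNA(conc))
    stop("unresolved nutrient profile for record(s): ",
         paste(head(which(is.na(conc)), 5), collapse = ", "))
  records$catch_tonnes * conc * 1e4
}

#' Classify a nutrient from model reference points
#'
#' A nutrient whose catch-weighted mean single-species F_MSY exceeds the
#' community catch-maximising fishing level is classed resilient (nutrient
#' underfishing at mMSY: its stocks tolerate more fishing than the community
#' optimum applies); one below is vulnerable (nutrient overfishing); a tie is
#' neutral.
#'
#' @param weighted_fmsy Nutrient-catch-weighted mean of per-species F_MSY
#'   (1/yr).
#' @param f_mmsy Community fishing level at maximum total catch (same axis).
#' @return `"resilient"`, `"vulnerable"` or `"neutral"`.
#' @export
classify_nutrient_model <- function(weighted_fmsy, f_mmsy) {
  if (!is.finite(weighted_fmsy) || !is.finite(f_mmsy) ||
      weighted_fmsy <= 0 || f_mmsy <= 0)
    stop("both values must be positive")
  if (weighted_fmsy > f_mmsy) "resilient"
  else if (weighted_fmsy < f_mmsy) "vulnerable"
  else "neutral"
}

#' Regional evenness and vulnerability of nutrient catches
#'
#' For each region: Pielou evenness and catch-weighted mean intrinsic
#' vulnerability of the total catch and of each nutrient catch, the relative
#' vulnerability `dV = V_nutrient - V_total`, a resilient/vulnerable class
#' per nutrient (by the sign of `dV`), and the region mean evenness and
#' vulnerability across nutrients with twice the standard error of that mean
#' (SEM over the nutrient values).
#'
#' Records of the same taxon within a region are pooled; records with missing
#' vulnerability or unresolved profiles are dropped from the affected
#' statistics (counts are attached as attributes).
#'
#' @param records Resolved catch records (see [resolve_profiles()]).
#' @param nutrients Nutrients to analyse (default: the six-nutrient
#'   catch-table set present in `records`).
#' @return Data.frame of class `mny_framework`, one row per region x
#'   nutrient (plus a `total` row per region), with columns `region`,
#'   `nutrient`, `evenness`, `vulnerability`, `delta_vulnerability`, `class`,
#'   `mean_evenness`, `mean_vulnerability`, `sem2_evenness`,
#'   `sem2_vulnerability` (region-level columns repeated within region).
#' @export
regional_summary <- function(records, nutrients = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(nutrients))
    nutrients <- intersect(NUTRIENTS_CATCH, names(records))
  if (!length(nutrients)) stop("no nutrient concentration columns in records")
  if (!"resolved" %in% names(records)) records$resolved <- TRUE

  n_drop_vuln <- sum(is.na(records$vulnerability))
  n_drop_prof <- sum(!records$resolved)
  out <- list()
  for (rg in unique(records$region)) {
    rr <- records[records$region == rg & !is.na(records$vulnerability) &
                    records$resolved, , drop = FALSE]
    if (!nrow(rr) || sum(rr$catch_tonnes) <= 0) {
      message("region ", rg, " has no usable catch records; skipped")
      next
    }
    # pool duplicate taxa (catch-weighted concentrations are identical per
    # taxon, so summing catch preserves every statistic)
    agg <- do.call(rbind, lapply(split(rr, rr$taxon), function(d) {
      d$catch_tonnes[1] <- sum(d$catch_tonnes); d[1, , drop = FALSE]
    }))
    v_tot <- weighted_vulnerability(agg$catch_tonnes, agg$vulnerability)
    rows <- data.frame(region = rg, nutrient = "total",
                       evenness = pielou_evenness(agg$catch_tonnes),
                       vulnerability = as.numeric(v_tot),
                       delta_vulnerability = 0, class = NA_character_)
    for (nu in nutrients) {
      wts <- nutrient_weights(agg, nu)
      if (sum(wts) <= 0) {
        rows <- rbind(rows, data.frame(region = rg, nutrient = nu,
                                       evenness = NA_real_,
                                       vulnerability = NA_real_,
                                       delta_vulnerability = NA_real_,
                                       class = NA_character_))
        next
      }
      v_n <- as.numeric(weighted_vulnerability(wts, agg$vulnerability))
      dv <- v_n - as.numeric(v_tot)
      rows <- rbind(rows, data.frame(
        region = rg, nutrient = nu, evenness = pielou_evenness(wts),
        vulnerability = v_n, delta_vulnerability = dv,
        class = if (dv < 0) "resilient" else if (dv > 0) "vulnerable"
                else "neutral"))
    }
    nut_rows <- rows$nutrient != "total"
    sem <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    rows$mean_evenness <- mean(rows$evenness[nut_rows], na.rm = TRUE)
    rows$mean_vulnerability <- mean(rows$vulnerability[nut_rows], na.rm = TRUE)
    rows$sem2_evenness <- 2 * sem(rows$evenness[nut_rows])
    rows$sem2_vulnerability <- 2 * sem(rows$vulnerability[nut_rows])
    out[[rg]] <- rows
  }
  if (!length(out)) stop("no region had usable catch records")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped_vulnerability") <- n_drop_vuln
  attr(res, "n_dropped_profile") <- n_drop_prof
  class(res) <- c("mny_framework", "data.frame")
  res
}

#' Global summary of relative nutrient-catch vulnerability
#'
#' Across regions, the fraction where each nutrient's catch is less
#' vulnerable to fishing than the total catch (`frac_negative`,
#' `dV < 0`: potential nutrient underfishing), more vulnerable
#' (`frac_positive`, potential overfishing), or exactly tied (`frac_zero`).
#'
#' @param results A `mny_framework` from [regional_summary()].
#' @return Data.frame, one row per nutrient, columns `nutrient`, `n_regions`,
#'   `frac_negative`, `frac_positive`, `frac_zero`.
#' @export
global_deviation_summary <- function(results) {
  stopifnot(is.data.frame(results))
  nut <- results[results$nutrient != "total" &
                   !is.na(results$delta_vulnerability), , drop = FALSE]
  if (!nrow(nut)) stop("no nutrient rows with delta_vulnerability")
  do.call(rbind, lapply(split(nut, nut$nutrient), function(d) {
    data.frame(nutrient = d$nutrient[1], n_regions = nrow(d),
               frac_negative = mean(d$delta_vulnerability < 0),
               frac_positive = mean(d$delta_vulnerability > 0),
               frac_zero = mean(d$delta_vulnerability == 0))
  }))
}
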