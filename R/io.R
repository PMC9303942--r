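# CSV readers/writers for every table the pipeline consumes or emits.
# Numeric output uses 17 significant digits so write -> read round-trips at
# full double precision.

write_csv17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cl in names(df)[num])
    out[[cl]] <- formatC(df[[cl]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write species parameter tables
#'
#' CSV with one header row and the exact column names of
#' [validate_species_params()]. Validation failures are reported with row
#' numbers.
#'
#' @param path File path.
#' @return `read_species_csv`: validated data.frame.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_species_params(df)
  df
}

#' @rdname read_species_csv
#' @param species Species parameter table to write.
#' @export
write_species_csv <- function(species, path) {
  validate_species_params(species)
  write_csv17(species, path)
}

#' Read and write gear selectivity tables
#'
#' CSV with columns `gear`, `species`, `w50`, `slope`, `Q`.
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
read_gear_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_gear_params(df)
  df
}

#' @rdname read_gear_csv
#' @param gears Gear table to write.
#' @export
write_gear_csv <- function(gears, path) {
  validate_gear_params(gears)
  write_csv17(gears, path)
}

#' Read and write interaction matrices
#'
#' Square CSV with species labels as both row and column headers.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_interaction_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("interaction matrix must be square")
  if (!identical(rownames(m), colnames(m)))
    stop("interaction matrix row and column labels must match")
  if (any(m < 0 | m > 1)) stop("interaction coefficients must lie in [0, 1]")
  m
}

#' @rdname read_interaction_csv
#' @param interaction Matrix to write.
#' @export
write_interaction_csv <- function(interaction, path) {
  df <- as.data.frame(interaction)
  out <- cbind(data.frame(species = rownames(interaction)),
               as.data.frame(lapply(df, formatC, digits = 17, format = "g")))
  names(out)[-1] <- colnames(interaction)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write nutrient concentration tables
#'
#' CSV keyed by `species` with one column per nutrient (subset of
#' [nutrient_names()]); concentrations are amounts per 100 g.
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_nutrient_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("nutrient table needs a species column")
  nut <- intersect(NUTRIENTS, names(df))
  if (!length(nut)) stop("nutrient table has no recognised nutrient columns")
  for (cl in nut) {
    if (!is.numeric(df[[cl]]) || any(df[[cl]] < 0, na.rm = TRUE))
      stop("nutrient column '", cl, "' must be non-negative numeric")
  }
  df
}

#' @rdname read_nutrient_csv
#' @param nutrients Table to write.
#' @export
write_nutrient_csv <- function(nutrients, path) {
  write_csv17(nutrients, path)
}

#' Read and write regional catch tables
#'
#' CSV with columns `region`, `taxon`, `rank` (species/genus/family),
#' `catch_tonnes` and `vulnerability` (intrinsic index, 1-100, may be empty
#' for non-species ranks).
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
read_catch_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "taxon", "rank", "catch_tonnes", "vulnerability")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catch table missing columns: ",
                         paste(miss, collapse = ", "))
  badrank <- which(!df$rank %in% c("species", "genus", "family"))
  if (length(badrank))
    stop("catch table row(s) ", paste(badrank, collapse = ", "),
         ": rank must be species, genus or family")
  badc <- which(is.na(df$catch_tonnes) | df$catch_tonnes < 0)
  if (length(badc))
    stop("catch table row(s) ", paste(badc, collapse = ", "),
         ": catch_tonnes must be non-negative")
  badv <- which(!is.na(df$vulnerability) &
                  (df$vulnerability < 1 | df$vulnerability > 100))
  if (length(badv))
    stop("catch table row(s) ", paste(badv, collapse = ", "),
         ": vulnerability must lie in [1, 100]")
  df
}

#' @rdname read_catch_csv
#' @param records Catch table to write.
#' @export
write_catch_csv <- function(records, path) {
  write_csv17(records, path)
}

#' Tidy exports of a yield curve
#'
#' Writes the long-format catch table (one row per effort x species), the
#' nutrient yield table (one row per effort x nutrient) and the indicator
#' table to CSV.
#'
#' @param curve A `mny_yield_curve`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_yield_curve_csv <- function(curve, dir, prefix = "yield_curve") {
  stopifnot(inherits(curve, "mny_yield_curve"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- function(m, value) {
    data.frame(effort = rep(curve$efforts, ncol(m)),
               name = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }
  ct <- long(curve$catch); names(ct)[2:3] <- c("species", "catch_tonnes")
  ny <- long(curve$nutrient_yield); names(ny)[2:3] <- c("nutrient", "yield")
  paths <- file.path(dir, paste0(prefix, c("_catch.csv", "_nutrients.csv",
                                           "_indicators.csv")))
  write_csv17(ct, paths[1])
  write_csv17(ny, paths[2])
  write_csv17(as.data.frame(curve), paths[3])
  invisible(paths)
}
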