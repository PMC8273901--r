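#' Damage-yield tables
#'
#' A damage-yield table records simulated or measured complex-damage
#' yields for one particle species on a grid of kinetic energies and
#' oxygen tensions, the raw material the surface fit consumes.  It is a
#' plain `data.frame` (class `damage_yield_table`) with columns
#' `species`, `energy_MeV`, `oxygen_percent`,
#' `yield_dsb_per_cell_gbp_gy` and optionally `sigma` (per-record
#' measurement noise, used as inverse-variance weights by the fit).
#'
#' @param species Species name (single species per table).
#' @param energy_MeV Kinetic energies, > 0.
#' @param oxygen_percent Oxygen tensions in percent, >= 0.
#' @param yield Yields in DSB per cell per Gbp per Gy, > 0.
#' @param sigma Optional per-record noise standard deviation.
#' @return A `damage_yield_table`.
#' @export
damage_yield_table <- function(species, energy_MeV, oxygen_percent, yield,
                               sigma = NULL) {
  sp <- particle_species(species)
  n <- length(energy_MeV)
  stopifnot(length(oxygen_percent) == n, length(yield) == n)
  if (any(!is.finite(energy_MeV)) || any(energy_MeV <= 0)) {
    stop("energies must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(oxygen_percent)) || any(oxygen_percent < 0)) {
    stop("oxygen tensions must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(yield)) || any(yield <= 0)) {
    stop("yields must be finite and > 0", call. = FALSE)
  }
  tab <- data.frame(
    species = rep(sp$name, n),
    energy_MeV = as.numeric(energy_MeV),
    oxygen_percent = as.numeric(oxygen_percent),
    yield_dsb_per_cell_gbp_gy = as.numeric(yield),
    stringsAsFactors = FALSE
  )
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == n || length(sigma) == 1L)
    tab$sigma <- as.numeric(rep_len(sigma, n))
  }
  class(tab) <- c("damage_yield_table", "data.frame")
  tab
}

.ytab_cols <- c("species", "energy_MeV", "oxygen_percent",
                "yield_dsb_per_cell_gbp_gy")

#' Read or write a damage-yield table CSV
#'
#' The neutral CSV bridge for yield tables (one species per file):
#' header `species,energy_MeV,oxygen_percent,yield_dsb_per_cell_gbp_gy`
#' with an optional `sigma` column.  Oxygen may alternatively be given as
#' `oxygen_torr`, converted to percent on read (7.6 Torr per percent).
#' Numbers are written with 17 significant digits so write-then-read is
#' the identity.
#'
#' @param path CSV file path.
#' @param table A `damage_yield_table` to write.
#' @return The read table, or (for the writer) `path` invisibly.
#' @export
read_yield_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("oxygen_torr" %in% names(df) && !"oxygen_percent" %in% names(df)) {
    df$oxygen_percent <- df$oxygen_torr / TORR_PER_PERCENT
    df$oxygen_torr <- NULL
  }
  miss <- setdiff(.ytab_cols, names(df))
  if (length(miss)) {
    stop("yield-table CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$yield_dsb_per_cell_gbp_gy) |
                 df$yield_dsb_per_cell_gbp_gy <= 0)
  if (length(bad)) {
    stop("non-positive yield at row ", bad[1], call. = FALSE)
  }
  if (length(unique(df$species)) != 1L) {
    stop("a yield table must contain a single species", call. = FALSE)
  }
  damage_yield_table(df$species[1], df$energy_MeV, df$oxygen_percent,
                     df$yield_dsb_per_cell_gbp_gy,
                     sigma = if ("sigma" %in% names(df)) df$sigma else NULL)
}

#' @rdname read_yield_table
#' @export
write_yield_table <- function(table, path) {
  stopifnot(inherits(table, "damage_yield_table"))
  df <- as.data.frame(table)
  for (nm in setdiff(names(df), "species")) {
    df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
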