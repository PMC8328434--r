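# Biovolume-to-carbon conversion via allometric laws of the form
# C[pg] = m * a * V[um^3]^b, with V the average cell volume. The multiplier m
# exists for laws stated on another currency first (e.g. dry weight, with
# carbon = 0.5 * DW for bacteria).

#' Construct an allometric volume-to-carbon law
#'
#' Represents `C[pg] = m * a * V^b` with `V` in cubic micrometres.
#'
#' @param a Coefficient, pg per um^3^b; must be > 0.
#' @param b Exponent, dimensionless; must be > 0. `b = 1` gives a linear law
#'   with volume-independent carbon density `m * a`.
#' @param m Extra multiplier, dimensionless, default 1. Used e.g. for the
#'   dry-weight-to-carbon step of the bacterial law (`m = 0.5`).
#' @return An object of class `allometric_law`.
#' @examples
#' cry_law <- allometric_law(0.216, 0.939)
#' carbon_per_cell(664, cry_law)
#' @export
allometric_law <- function(a, b, m = 1) {
  check_positive(a, "a")
  check_positive(b, "b")
  check_positive(m, "m")
  structure(list(a = a, b = b, m = m), class = "allometric_law")
}

#' @export
print.allometric_law <- function(x, ...) {
  cat(sprintf("<allometric_law> C[pg] = %s%g * V^%g\n",
              if (x$m != 1) paste0(x$m, " * ") else "", x$a, x$b))
  invisible(x)
}

#' Carbon content of a single cell
#'
#' Evaluates the allometric law `m * a * V^b` at cell volume `V`.
#'
#' @param volume Cell volume in um^3; must be > 0. Vectorised.
#' @param law An [allometric_law()].
#' @return Carbon per cell in pg.
#' @export
carbon_per_cell <- function(volume, law) {
  stopifnot(inherits(law, "allometric_law"))
  check_positive(volume, "volume")
  law$m * law$a * volume^law$b
}

#' Carbon density of a cell
#'
#' Carbon per unit biovolume, `carbon_per_cell(V, law) / V`, in pg C per um^3.
#' Stored at full precision; round only when formatting for comparison with
#' published conversion factors.
#'
#' @inheritParams carbon_per_cell
#' @return Carbon density in pg C per um^3.
#' @examples
#' carbon_density(664, allometric_law(0.216, 0.939)) # ~0.145
#' @export
carbon_density <- function(volume, law) {
  carbon_per_cell(volume, law) / volume
}

#' Construct a taxon profile
#'
#' Bundles a taxon's morphometry (mean cell volume), its volume-to-carbon law,
#' the derived carbon density, and optionally a detection limit for counts.
#'
#' @param name Taxon identifier.
#' @param mean_cell_volume Mean cell volume in um^3; > 0.
#' @param law An [allometric_law()].
#' @param detection_limit_abundance Optional detection limit, cells per ml.
#' @return An object of class `taxon_profile` with fields `name`,
#'   `mean_cell_volume`, `law`, `carbon_density` (pg C per um^3, derived) and
#'   `detection_limit_abundance`.
#' @export
taxon_profile <- function(name, mean_cell_volume, law,
                          detection_limit_abundance = NA_real_) {
  check_positive(mean_cell_volume, "mean_cell_volume")
  stopifnot(inherits(law, "allometric_law"))
  structure(
    list(
      name = as.character(name),
      mean_cell_volume = mean_cell_volume,
      law = law,
      carbon_density = carbon_density(mean_cell_volume, law),
      detection_limit_abundance = detection_limit_abundance
    ),
    class = "taxon_profile"
  )
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile> %s: V = %g um^3, %g pg C/cell (%.3g pg C/um^3)\n",
              x$name, x$mean_cell_volume,
              carbon_per_cell(x$mean_cell_volume, x$law), x$carbon_density))
  invisible(x)
}

#' Carbon content of one cell of a taxon
#'
#' @param profile A [taxon_profile()].
#' @return pg C per cell at the taxon's mean cell volume.
#' @export
cell_carbon <- function(profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  profile$mean_cell_volume * profile$carbon_density
}

#' Convert an abundance to carbon biomass
#'
#' `abundance * mean_cell_volume * carbon_density`, mapping cells per ml to
#' pg C per ml. Zero maps to zero.
#'
#' @param abundance Cells per ml; >= 0. Vectorised.
#' @param profile A [taxon_profile()].
#' @return Biomass in pg C per ml.
#' @examples
#' eup <- taxon_profile("Eup", 26890, allometric_law(0.14, 1))
#' log10(abundance_to_carbon(0.5, eup)) # ~3.3, the detection limit in carbon
#' @export
abundance_to_carbon <- function(abundance, profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  check_non_negative(abundance, "abundance")
  abundance * cell_carbon(profile)
}

#' Convert carbon biomass back to abundance
#'
#' Inverse of [abundance_to_carbon()].
#'
#' @param biomass pg C per ml; >= 0. Vectorised.
#' @param profile A [taxon_profile()].
#' @return Abundance in cells per ml.
#' @export
carbon_to_abundance <- function(biomass, profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  check_non_negative(biomass, "biomass")
  biomass / cell_carbon(profile)
}

#' Convert a cell-based maximum ingestion rate to carbon units
#'
#' `imax_cells * mean_cell_volume * carbon_density` of the prey: prey cells
#' per grazer per day become pg C per grazer per day.
#'
#' @param imax_cells Prey cells per ciliate per day; >= 0. Vectorised.
#' @param prey The prey [taxon_profile()].
#' @return Maximum ingestion rate in pg C per ciliate per day.
#' @export
imax_to_carbon <- function(imax_cells, prey) {
  stopifnot(inherits(prey, "taxon_profile"))
  check_non_negative(imax_cells, "imax_cells")
  imax_cells * cell_carbon(prey)
}

#' Diet composition from per-prey maximum ingestion rates
#'
#' Given carbon-based maximum ingestion rates per prey, returns the fractional
#' contribution of each prey to the total ingested carbon when feeding at
#' maximum rate on all prey simultaneously.
#'
#' @param imax_by_prey Named numeric vector of pg C per ciliate per day, one
#'   entry per prey; at least one entry must be positive.
#' @return A tibble with columns `prey`, `imax_carbon` and `share` (fractions
#'   summing to 1).
#' @examples
#' diet_share(c(Cry = 1.79e3, Nav = 0.15e3)) # Nav share rounds to 8%
#' @export
diet_share <- function(imax_by_prey) {
  check_non_negative(imax_by_prey, "imax_by_prey")
  if (length(imax_by_prey) == 0 || is.null(names(imax_by_prey))) {
    abort("`imax_by_prey` must be a named numeric vector.", class = "chemocomp_domain_error")
  }
  if (sum(imax_by_prey) <= 0) {
    abort("All ingestion rates are zero; diet shares are undefined.",
          class = "chemocomp_undefined_share_error")
  }
  tibble(
    prey = names(imax_by_prey),
    imax_carbon = unname(imax_by_prey),
    share = unname(imax_by_prey) / sum(imax_by_prey)
  )
}

#' Round to a number of significant figures
#'
#' Formatting convenience for comparing computed conversion factors and
#' carbon-based ingestion rates with published tables, which state 2 or 3
#' significant figures.
#'
#' @param x Numeric vector.
#' @param digits Significant figures.
#' @return `signif(x, digits)`.
#' @export
round_sig <- function(x, digits = 3) signif(x, digits)

# trait tables ----------------------------------------------------------------

#' Read a taxon trait table
#'
#' Reads a CSV of taxon traits: columns `taxon`, `volume_um3`, `law_a`,
#' `law_b`, `law_m`, `detection_limit_per_ml`, `imax_cells_cry`,
#' `imax_cells_nav`. Missing ingestion columns are allowed for non-grazers.
#'
#' @param path Path to a CSV file; the default reads the bundled trait table
#'   for the two-ciliate / two-alga / bacteria community (cell volumes,
#'   allometric laws and maximum ingestion rates of the study system).
#' @return A tibble, one row per taxon.
#' @export
read_traits <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "community_traits.csv", package = "chemocomp",
                        mustWork = TRUE)
  }
  traits <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("taxon", "volume_um3", "law_a", "law_b", "law_m")
  missing <- setdiff(required, names(traits))
  if (length(missing) > 0) {
    abort(sprintf("Trait table is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "chemocomp_schema_error")
  }
  check_positive(traits$volume_um3, "volume_um3")
  as_tibble(traits)
}

#' Default trait table of the study community
#'
#' @return The bundled trait tibble (see [read_traits()]).
#' @export
default_traits <- function() read_traits(NULL)

#' Build taxon profiles from a trait table
#'
#' @param traits A trait tibble as returned by [read_traits()].
#' @return A named list of [taxon_profile()] objects keyed by taxon.
#' @export
taxon_profiles <- function(traits = default_traits()) {
  dl <- traits$detection_limit_per_ml %||% rep(NA_real_, nrow(traits))
  profs <- purrr::pmap(
    list(traits$taxon, traits$volume_um3, traits$law_a, traits$law_b,
         traits$law_m, dl),
    function(taxon, v, a, b, m, dl) {
      taxon_profile(taxon, v, allometric_law(a, b, m), dl)
    }
  )
  stats::setNames(profs, traits$taxon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a tidy series from biovolume/abundance to carbon units
#'
#' Adds a `biomass_pgC_per_ml` column computed from `abundance_per_ml` via the
#' taxon profiles; rows whose taxon is missing from the trait table raise a
#' schema error.
#'
#' @param series A tidy series tibble with at least `taxon` and
#'   `abundance_per_ml` columns.
#' @param traits Trait table (see [read_traits()]).
#' @return The series tibble with `biomass_pgC_per_ml` added (overwritten if
#'   present).
#' @export
series_to_carbon <- function(series, traits = default_traits()) {
  profs <- taxon_profiles(traits)
  unknown <- setdiff(unique(series$taxon), names(profs))
  if (length(unknown) > 0) {
    abort(sprintf("Taxa absent from trait table: %s.", paste(unknown, collapse = ", ")),
          class = "chemocomp_schema_error")
  }
  per_cell <- purrr::map_dbl(profs, cell_carbon)
  series %>%
    mutate(biomass_pgC_per_ml = unname(.data$abundance_per_ml *
                                         per_cell[.data$taxon]))
}
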