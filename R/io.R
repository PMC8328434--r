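# Readers/writers for the tidy interchange formats and the end-to-end
# pipeline: convert -> censor -> rates -> log-ratios -> budget.

series_required_cols <- c("day", "treatment", "replicate", "taxon")

#' Read a tidy abundance/biomass series CSV
#'
#' Expects columns `day`, `treatment`, `replicate`, `taxon` and at least one
#' of `abundance_per_ml` / `biovolume_um3_per_ml` (the latter is converted to
#' abundance through the trait table's cell volumes). Validates the schema,
#' rejects negative abundances and non-monotone days per series, and (when a
#' trait table is given) rejects unknown taxa.
#'
#' @param path CSV path.
#' @param traits Optional trait table for taxon validation and biovolume
#'   conversion.
#' @return A tidy series tibble with an `abundance_per_ml` column.
#' @export
read_series <- function(path, traits = NULL) {
  series <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(series_required_cols, names(series))
  if (length(missing) > 0) {
    abort(sprintf("Series file %s is missing column(s): %s.",
                  path, paste(missing, collapse = ", ")),
          class = "chemocomp_schema_error")
  }
  has_ab <- "abundance_per_ml" %in% names(series)
  has_bv <- "biovolume_um3_per_ml" %in% names(series)
  if (!has_ab && !has_bv) {
    abort("Series needs `abundance_per_ml` and/or `biovolume_um3_per_ml`.",
          class = "chemocomp_schema_error")
  }
  if (!is.null(traits)) {
    unknown <- setdiff(unique(series$taxon), traits$taxon)
    if (length(unknown) > 0) {
      abort(sprintf("Series contains taxa absent from the trait table: %s.",
                    paste(unknown, collapse = ", ")),
            class = "chemocomp_schema_error")
    }
    if (!has_ab) {
      vol <- stats::setNames(traits$volume_um3, traits$taxon)
      series$abundance_per_ml <- unname(series$biovolume_um3_per_ml / vol[series$taxon])
    }
  }
  if (has_ab || !is.null(traits)) {
    neg <- which(series$abundance_per_ml < 0)
    if (length(neg) > 0) {
      abort(sprintf("Negative abundance at row(s) %s.",
                    paste(utils::head(neg, 5), collapse = ", ")),
            class = "chemocomp_schema_error")
    }
  }
  bad <- series %>%
    group_by(.data$treatment, .data$replicate, .data$taxon) %>%
    summarise(ok = !is.unsorted(.data$day, strictly = FALSE), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-monotone days in series %s/%s/%s.",
                  bad$treatment[1], bad$replicate[1], bad$taxon[1]),
          class = "chemocomp_schema_error")
  }
  as_tibble(series)
}

#' Write a tidy series CSV
#'
#' @param series Series tibble.
#' @param path Output path; refuses to overwrite unless `force = TRUE`.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, force = FALSE) {
  if (file.exists(path) && !force) {
    abort(sprintf("%s exists; pass force = TRUE to overwrite.", path),
          class = "chemocomp_io_error")
  }
  readr::write_csv(series, path)
  invisible(path)
}

#' Read a bottle-experiment CSV
#'
#' One row per bottle with the [bottle_experiment()] columns.
#'
#' @param path CSV path.
#' @return A validated `bottle_experiment` tibble.
#' @export
read_bottles <- function(path) {
  b <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("prey_control_start", "prey_control_end", "prey_grazed_start",
                "prey_grazed_end", "grazer_start", "grazer_end", "duration")
  missing <- setdiff(required, names(b))
  if (length(missing) > 0) {
    abort(sprintf("Bottle file %s is missing column(s): %s.",
                  path, paste(missing, collapse = ", ")),
          class = "chemocomp_schema_error")
  }
  do.call(bottle_experiment, as.list(b[required]))
}

#' Run the full analysis pipeline on a tidy series
#'
#' Executes the chain convert (abundance to carbon) -> censor (detection
#' policy) -> rates (growth/filtration table) -> log-ratio response table ->
#' carbon budget (from final-day mean stocks), and returns all intermediate
#' tables plus a run manifest. Deterministic for fixed inputs; pass `out_dir`
#' to also write every table as CSV.
#'
#' @param series Tidy series tibble (e.g. from [read_series()] or
#'   [observe()]).
#' @param traits Trait table.
#' @param window Growth-phase window in days for [rate_table()].
#' @param numerator_taxon,denominator_taxon Taxa for the log biomass ratio;
#'   defaults: every Coleps clone present versus `"Eup"`.
#' @param budget Optional [budget_params()] (defaults used otherwise).
#' @param seed Seed recorded in the manifest (the pipeline itself draws no
#'   random numbers).
#' @param out_dir Optional output directory for CSVs.
#' @param force Overwrite existing outputs.
#' @return A list of class `chemocomp_pipeline`: `series` (carbon-converted,
#'   censored), `rates`, `log_ratios`, `budget` (a [budget_sweep()] from the
#'   final sampling day's mean stocks, `NULL` when the needed taxa are
#'   absent), and `manifest` (seed, timestamps omitted for reproducibility,
#'   content hash).
#' @export
run_pipeline <- function(series, traits = default_traits(), window = c(0, 5),
                         numerator_taxon = NULL, denominator_taxon = "Eup",
                         budget = budget_params(), seed = 1L,
                         out_dir = NULL, force = FALSE) {
  taxa <- unique(series$taxon)
  numerator_taxon <- numerator_taxon %||%
    intersect(c("Col1", "Col2", "Col3"), taxa)

  prepared <- series
  if (!"censored" %in% names(prepared)) {
    prepared <- apply_detection_policy(prepared, detection_policies(traits))
  }
  prepared <- series_to_carbon(prepared, traits)

  rates <- rate_table(prepared, traits, window)
  ratios <- if (length(numerator_taxon) > 0 && denominator_taxon %in% taxa) {
    log_ratio_table(prepared, numerator_taxon, denominator_taxon)
  } else NULL

  budget_tbl <- NULL
  final_day <- max(prepared$day)
  finals <- prepared %>%
    filter(.data$day == final_day) %>%
    group_by(.data$taxon) %>%
    summarise(bm = mean(.data$biomass_pgC_per_ml), .groups = "drop")
  get_bm <- function(tx) {
    v <- finals$bm[finals$taxon %in% tx]
    if (length(v) == 0) NA_real_ else sum(v)
  }
  if (all(c("Nav", "Bacteria") %in% finals$taxon)) {
    state <- community_state(get_bm("Nav"), get_bm("Bacteria"),
                             ifelse(is.na(get_bm("Eup")), 0, get_bm("Eup")))
    budget_tbl <- budget_sweep(state, budget)
  }

  bundle <- list(series = prepared, rates = rates, log_ratios = ratios,
                 budget = budget_tbl)
  manifest <- tibble(
    package_version = as.character(utils::packageVersion("chemocomp")),
    seed = as.integer(seed),
    n_rows = nrow(prepared),
    content_hash = rlang::hash(bundle)
  )
  bundle$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("series", "rates", "log_ratios", "budget", "manifest")) {
      if (!is.null(bundle[[nm]])) {
        write_series(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     force = force)
      }
    }
  }
  structure(bundle, class = "chemocomp_pipeline")
}

#' @export
print.chemocomp_pipeline <- function(x, ...) {
  cat(sprintf("<chemocomp_pipeline> %d series rows, %d rate rows, hash %s\n",
              nrow(x$series), nrow(x$rates),
              substr(x$manifest$content_hash, 1, 8)))
  invisible(x)
}
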