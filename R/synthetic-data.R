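# Ground-truth simulators for both table types. The bone generator draws MATs
# uniformly and puts Gaussian noise on log10 persistence, the structure the
# regression assumes; the series generator drops fossil sightings as a Poisson
# process that stops at a known extinction date, lets eDNA continue through a
# known persistence window (dead-tissue DNA input), and blurs every age with
# Gaussian dating noise. Defaults mimic the scales of real high-latitude
# megafauna records: semi-continuous fossil series from 50 down to 11 cal kyr
# BP at ~10 dated finds per kyr, calibrated 2-sigma errors of ~400 yr, and
# bone persistence of a few kyr at sub-zero MAT.

#' Configuration for the synthetic bone-table generator
#'
#' @param slope True slope, log10-years per deg C (negative: colder = longer
#'   persistence). Default -0.06.
#' @param intercept True intercept, log10-years at 0 deg C. Default 2.6
#'   (~400 yr).
#' @param sigma_resid Residual SD of log10 persistence. Default 0.15.
#' @param mat_range MAT range (deg C) sampled uniformly. Default c(-25, 20).
#' @param n Number of bones, >= 3. Default 30.
#' @param seed Integer seed.
#' @param age_2sigma Reported dating error (2-sigma, yr) attached to every
#'   record. Default 50.
#' @return A list of class `bone_gen_config`.
#' @export
bone_gen_config <- function(slope = -0.06, intercept = 2.6, sigma_resid = 0.15,
                            mat_range = c(-25, 20), n = 30, seed = 1L,
                            age_2sigma = 50) {
  stopifnot(length(mat_range) == 2, mat_range[1] < mat_range[2],
            sigma_resid >= 0, n >= 3, age_2sigma >= 0)
  structure(list(slope = slope, intercept = intercept, sigma_resid = sigma_resid,
                 mat_range = mat_range, n = as.integer(n), seed = as.integer(seed),
                 age_2sigma = age_2sigma),
            class = "bone_gen_config")
}

#' Generate a synthetic bone-persistence table
#'
#' MATs are uniform on `mat_range` and
#' `log10(age) = intercept + slope * MAT + Normal(0, sigma_resid)`. Records
#' alternate between the two burial classes so both are always represented;
#' each record gets its own region, so the table is unchanged by
#' [consolidate_oldest_per_region()]. Deterministic under `seed`.
#'
#' @param config A [bone_gen_config()].
#' @return A validated bone tibble of `config$n` rows.
#' @export
#' @examples
#' gen_bone_table(bone_gen_config(n = 5, seed = 1))
gen_bone_table <- function(config = bone_gen_config()) {
  stopifnot(inherits(config, "bone_gen_config"))
  withr::with_seed(config$seed, {
    mat <- runif(config$n, config$mat_range[1], config$mat_range[2])
    log_age <- config$intercept + config$slope * mat +
      rnorm(config$n, 0, config$sigma_resid)
    bones <- tibble(
      record_id = sprintf("bone_%03d", seq_len(config$n)),
      region = sprintf("locality_%03d", seq_len(config$n)),
      taxon = "synthetic_taxon",
      age = 10^log_age,
      age_2sigma = config$age_2sigma,
      mat = mat,
      burial_class = rep_len(BURIAL_CLASSES, config$n)
    )
    validate_bone_table(bones)
    bones
  })
}

#' Configuration for the synthetic occurrence-series generator
#'
#' @param true_extinction True extinction date, cal yr BP. Default 11000.
#' @param record_start Oldest end of the record, cal yr BP; must be older than
#'   `true_extinction`. Default 50000.
#' @param sighting_rate Dated finds per kyr for the Poisson sighting process.
#'   Default 10.
#' @param dating_2sigma Reported 2-sigma dating error (yr) applied to every
#'   age as Gaussian noise with SD `dating_2sigma / 2`. Default 400.
#' @param n_edna_postmortem Number of eDNA detections deposited after
#'   extinction, uniform over the persistence window. Default 5.
#' @param persistence_true True bone-persistence duration (yr): dead-tissue
#'   DNA input continues this long past extinction. Default 4000.
#' @param seed Integer seed.
#' @param region Region label for all records.
#' @param uniform_n If not `NULL`, draw exactly this many fossil sightings
#'   uniformly over the record span instead of the Poisson process.
#' @return A list of class `series_gen_config`.
#' @export
series_gen_config <- function(true_extinction = 11000, record_start = 50000,
                              sighting_rate = 10, dating_2sigma = 400,
                              n_edna_postmortem = 5, persistence_true = 4000,
                              seed = 1L, region = "synthetic_region",
                              uniform_n = NULL) {
  stopifnot(record_start > true_extinction, sighting_rate > 0,
            dating_2sigma >= 0, n_edna_postmortem >= 0, persistence_true >= 0)
  structure(list(true_extinction = true_extinction, record_start = record_start,
                 sighting_rate = sighting_rate, dating_2sigma = dating_2sigma,
                 n_edna_postmortem = as.integer(n_edna_postmortem),
                 persistence_true = persistence_true, seed = as.integer(seed),
                 region = region, uniform_n = uniform_n),
            class = "series_gen_config")
}

#' Generate a synthetic fossil + eDNA occurrence series
#'
#' Fossil true ages are a Poisson process at `sighting_rate` per kyr on
#' `[true_extinction, record_start]` (living animals only). eDNA true ages are
#' the same process plus exactly `n_edna_postmortem` detections uniform on
#' `[true_extinction - persistence_true, true_extinction]`, emulating DNA shed
#' by remains decaying after extinction. Observed ages add
#' `Normal(0, dating_2sigma / 2)` noise and are floored at 0 BP. If the
#' Poisson draw yields fewer than 3 fossils the series is regenerated from the
#' next seed (with a message). Deterministic under `seed`.
#'
#' @param config A [series_gen_config()].
#' @return A validated occurrence tibble with `source` `"fossil"` and
#'   `"edna"` rows.
#' @export
#' @examples
#' occ <- gen_occurrence_series(series_gen_config(seed = 7))
#' dplyr::count(occ, source)
gen_occurrence_series <- function(config = series_gen_config()) {
  stopifnot(inherits(config, "series_gen_config"))
  for (attempt in 0:100) {
    out <- withr::with_seed(config$seed + attempt, gen_series_once(config))
    if (!is.null(out)) {
      if (attempt > 0) {
        message(sprintf("fewer than 3 fossils realized; regenerated with seed %d",
                        config$seed + attempt))
      }
      return(out)
    }
  }
  abort("could not realize >= 3 fossil sightings in 100 attempts; increase sighting_rate or span",
        class = "bonechron_input_error")
}

gen_series_once <- function(config) {
  span <- config$record_start - config$true_extinction
  rate_yr <- config$sighting_rate / 1000
  n_fossil <- if (is.null(config$uniform_n)) rpois(1, rate_yr * span) else config$uniform_n
  if (n_fossil < 3) return(NULL)
  fossil_true <- runif(n_fossil, config$true_extinction, config$record_start)
  n_edna_live <- rpois(1, rate_yr * span)
  edna_true <- c(
    runif(n_edna_live, config$true_extinction, config$record_start),
    runif(config$n_edna_postmortem,
          config$true_extinction - config$persistence_true, config$true_extinction)
  )
  sigma <- config$dating_2sigma / 2
  fossil_obs <- pmax(fossil_true + rnorm(n_fossil, 0, sigma), 0)
  edna_obs <- pmax(edna_true + rnorm(length(edna_true), 0, sigma), 0)
  occ <- tibble(
    record_id = c(sprintf("fossil_%04d", seq_len(n_fossil)),
                  sprintf("edna_%04d", seq_along(edna_obs))),
    region = config$region,
    source = rep(c("fossil", "edna"), c(n_fossil, length(edna_obs))),
    age = c(fossil_obs, edna_obs),
    age_2sigma = config$dating_2sigma
  )
  validate_occurrence_table(occ)
  occ
}

#' Generate a complete multi-region synthetic study
#'
#' Convenience wrapper producing everything [run_pipeline()] needs: one bone
#' table, an occurrence table across `n_regions` regions (each with its own
#' derived seed), and a site table assigning each region a MAT.
#'
#' @param n_regions Number of regions. Default 3.
#' @param bone_config A [bone_gen_config()].
#' @param series_config A [series_gen_config()] used as template per region.
#' @param site_mats MATs (deg C) recycled across regions. Default -13.3.
#' @param seed Integer root seed; region seeds are derived from it.
#' @return A list with `bones`, `occurrences`, `sites`, and `truth` (the
#'   per-region generating parameters).
#' @export
gen_mixing_study <- function(n_regions = 3,
                             bone_config = bone_gen_config(),
                             series_config = series_gen_config(),
                             site_mats = -13.3,
                             seed = 1L) {
  bone_config$seed <- derive_seed(seed, 0L, 17L)
  bones <- gen_bone_table(bone_config)
  occ <- purrr::map_dfr(seq_len(n_regions), function(ri) {
    cfg <- series_config
    cfg$seed <- derive_seed(seed, ri, 23L)
    cfg$region <- sprintf("region_%02d", ri)
    gen_occurrence_series(cfg)
  })
  sites <- tibble(region = sprintf("region_%02d", seq_len(n_regions)),
                  mat = rep_len(site_mats, n_regions))
  list(bones = bones, occurrences = occ, sites = sites,
       truth = list(bone_config = bone_config, series_config = series_config))
}
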