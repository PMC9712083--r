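fake_estimate <- function(median_bp, region = "reg_A", source = "fossil") {
  structure(list(region = region, source = source, median = median_bp,
                 mean = median_bp, ci_lower = median_bp + 200,
                 ci_upper = median_bp - 200, n_occurrences = 10,
                 config = estimator_config(n_resamples = 10), draws = median_bp),
            class = "extinction_estimate")
}

test_that("window arithmetic: subtraction, collapse, and sign convention", {
  est <- fake_estimate(11000)
  w <- build_window(est, 4190)
  expect_equal(w$window_old, 11000)
  expect_equal(w$window_young, 6810)
  expect_equal(build_window(est, 0)$window_young, 11000)   # collapses to a point
  expect_lt(build_window(est, 12000)$window_young, 0)      # extends past present

  pred <- tibble::tibble(mean_persistence = 2260, upper_ci = 4190)
  expect_equal(build_window(est, pred, "mean")$window_young, 11000 - 2260)
  expect_equal(build_window(est, pred, "upper")$window_young, 6810)
})

test_that("classification picks the tightest window, with inclusive bounds", {
  windows <- c(window_old = 11000, window_young_mean = 9000,
               window_young_upper = 7000, window_young_upper_potential = 3000)
  edna <- make_occurrences(
    c(12000, 11000, 9000, 8999.999, 7000, 5000, 3000, 2999.999),
    source = "edna")
  cls <- classify_edna(edna, windows)
  expect_equal(as.character(cls$status),
               c("within_mean",             # older than window_old
                 "within_mean",             # at window_old
                 "within_mean",             # at the mean bound (inclusive)
                 "within_upper",
                 "within_upper",            # exactly at the upper bound
                 "within_upper_potential",
                 "within_upper_potential",  # at the potential bound
                 "outside"))
  # exhaustive and mutually exclusive
  expect_equal(sum(table(cls$status)), nrow(edna))
  expect_false(any(is.na(cls$status)))
})

test_that("non-nested windows and non-eDNA input are rejected", {
  windows <- c(window_old = 11000, window_young_mean = 7000,
               window_young_upper = 9000, window_young_upper_potential = 3000)
  edna <- make_occurrences(c(5000, 4000), source = "edna")
  expect_error(classify_edna(edna, windows), "nested",
               class = "bonechron_input_error")
  ok <- c(window_old = 11000, window_young_mean = 9000,
          window_young_upper = 7000, window_young_upper_potential = 3000)
  expect_error(classify_edna(make_occurrences(c(5000, 4000)), ok),
               class = "bonechron_input_error")
  expect_error(classify_edna(edna, ok[-2]), class = "bonechron_input_error")
})

test_that("constructed topologies reproduce expected counts (all-inside and two-outside)", {
  windows <- c(window_old = 11000, window_young_mean = 8740,
               window_young_upper = 6810, window_young_upper_potential = 3000)
  inside <- make_occurrences(seq(10900, 8800, length.out = 7), source = "edna")
  cls <- classify_edna(inside, windows)
  expect_equal(sum(cls$status == "outside"), 0)
  expect_true(all(cls$status == "within_mean"))

  # two detections younger than even the broadest persistence window
  mixed <- make_occurrences(c(10000, 7500, 5000, 2500, 900), source = "edna")
  cls <- classify_edna(mixed, windows)
  expect_equal(sum(cls$status == "outside"), 2)
  expect_equal(as.character(cls$status),
               c("within_mean", "within_upper", "within_upper_potential",
                 "outside", "outside"))
})

test_that("the pipeline yields one report per region and is seed-reproducible to the byte", {
  st <- gen_mixing_study(
    n_regions = 3, seed = 3,
    series_config = series_gen_config(record_start = 16000, sighting_rate = 6))
  cfg <- estimator_config(n_resamples = 150, seed = 42)
  reports <- run_pipeline(st$bones, st$occurrences, st$sites, config = cfg)
  expect_s3_class(reports, "mixing_report_set")
  expect_length(reports, 3)
  expect_equal(purrr::map_chr(unclass(reports), "region"),
               sort(unique(st$occurrences$region)))

  g <- glance(reports)
  expect_equal(nrow(g), 3)
  # windows nested on the BP axis in every region
  expect_true(all(g$window_old >= g$window_young_mean))
  expect_true(all(g$window_young_mean >= g$window_young_upper))
  expect_true(all(g$window_young_upper >= g$window_young_upper_potential))
  # classification counts sum to the number of eDNA records per region
  n_edna <- dplyr::count(dplyr::filter(st$occurrences, source == "edna"),
                         region, name = "n_edna")
  totals <- g$n_within_mean + g$n_within_upper + g$n_within_upper_potential +
    g$n_outside
  expect_equal(totals, n_edna$n_edna[match(g$region, n_edna$region)])

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_mixing_report(run_pipeline(st$bones, st$occurrences, st$sites, config = cfg), p1)
  write_mixing_report(run_pipeline(st$bones, st$occurrences, st$sites, config = cfg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the pipeline report is invariant to input row order", {
  st <- gen_mixing_study(
    n_regions = 2, seed = 8,
    series_config = series_gen_config(record_start = 15000, sighting_rate = 5))
  cfg <- estimator_config(n_resamples = 100, seed = 7)
  r1 <- run_pipeline(st$bones, st$occurrences, st$sites, config = cfg)
  set.seed(1)
  shuffled <- st$occurrences[sample(nrow(st$occurrences)), ]
  r2 <- run_pipeline(st$bones, shuffled, st$sites, config = cfg)
  expect_equal(glance(r1), glance(r2))
  expect_equal(tidy(r1), tidy(r2))
})

test_that("pipeline errors are annotated with the failing region", {
  st <- gen_mixing_study(
    n_regions = 2, seed = 8,
    series_config = series_gen_config(record_start = 15000, sighting_rate = 5))
  # drop region_02's fossils below the minimum record length
  occ <- st$occurrences
  drop <- which(occ$region == "region_02" & occ$source == "fossil")[-(1:2)]
  occ <- occ[setdiff(seq_len(nrow(occ)), drop), ]
  expect_error(
    run_pipeline(st$bones, occ, st$sites,
                 config = estimator_config(n_resamples = 50, seed = 1)),
    "region_02", class = "bonechron_pipeline_error")
})

test_that("with true windows, the outside fraction matches the dating-noise expectation", {
  # post-mortem eDNA ages are uniform on [ext - P, ext]; observed ages add
  # Normal(0, sigma) noise; classified against the *true* windows, the chance
  # of falling below ext - P is E[ Phi((u - P)/sigma) ], u ~ U(0, P) measured
  # from the extinction date. Independent oracle: numeric integration.
  ext <- 11000; P <- 3000; sigma2 <- 800; sigma <- sigma2 / 2
  cfg <- series_gen_config(true_extinction = ext, record_start = 13000,
                           sighting_rate = 2, dating_2sigma = sigma2,
                           n_edna_postmortem = 400, persistence_true = P,
                           seed = 60)
  occ <- gen_occurrence_series(cfg)
  edna <- dplyr::filter(occ, source == "edna")
  post <- dplyr::filter(edna,
                        as.integer(sub("edna_", "", record_id)) > nrow(edna) - 400)
  windows <- c(window_old = ext, window_young_mean = ext - P,
               window_young_upper = ext - P, window_young_upper_potential = ext - P)
  cls <- classify_edna(post, windows)
  frac_outside <- mean(cls$status == "outside")
  expected <- stats::integrate(function(u) stats::pnorm((u - P) / sigma) / P,
                               0, P)$value
  mc_err <- 3 * sqrt(expected * (1 - expected) / 400)
  expect_lt(abs(frac_outside - expected), mc_err + 0.01)
})
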