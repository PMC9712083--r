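# Log-linear taphonomic model: the duration a surface bone persists on a
# landscape falls off exponentially with local mean annual temperature, so
# log10(persistence) is modelled as a straight line in MAT. The fit stores the
# OLS sufficient statistics alongside the lm object so a serialized model can
# still produce exact confidence / prediction intervals at new temperatures.

#' Fit the bone-persistence ~ temperature regression
#'
#' Ordinary least squares of `log10(age)` on mean annual temperature (MAT),
#' fitted separately per burial-history class. The `"never_buried"` fit uses
#' only bones confidently exposed for their entire post-mortem history; the
#' `"potentially_never_buried"` fit uses the union of both classes, since the
#' broader class is "never buried OR possibly exhumed" (set
#' `strict_classes = TRUE` to fit on the disjoint subset instead).
#'
#' Dating error is ignored in the fit by default (2-sigma errors on these dates
#' are small relative to the residual scatter); `weighted = TRUE` weights each
#' point by the inverse variance of its log10 age, obtained from the reported
#' 2-sigma by the delta method.
#'
#' @param bones A validated bone table; typically already consolidated to the
#'   oldest bone per region with [consolidate_oldest_per_region()].
#' @param burial_class `"never_buried"` or `"potentially_never_buried"`.
#' @param strict_classes If `TRUE`, the potentially-never-buried fit uses only
#'   records labelled with that class rather than the union. Default `FALSE`.
#' @param weighted If `TRUE`, inverse-variance weights from `age_2sigma`.
#' @return An object of class `persistence_fit` with elements `slope`,
#'   `intercept` (log10-years per deg C, log10-years), `n`, `r_squared`,
#'   `p_value` (two-sided, slope), `residual_variance` (mean squared residual,
#'   `n - 2` df), `design_info` (MAT mean and centred sum of squares),
#'   `mat_range`, and the underlying `lm` fit.
#' @export
#' @examples
#' bones <- gen_bone_table(bone_gen_config(n = 20, seed = 42))
#' fit <- fit_persistence(bones, "never_buried")
#' glance(fit)
fit_persistence <- function(bones,
                            burial_class = c("never_buried", "potentially_never_buried"),
                            strict_classes = FALSE,
                            weighted = FALSE) {
  burial_class <- match.arg(burial_class)
  validate_bone_table(bones)
  keep <- if (burial_class == "never_buried" || strict_classes) {
    bones$burial_class == burial_class
  } else {
    rep(TRUE, nrow(bones))  # union: never-buried bones also qualify as potentially so
  }
  sub <- bones[keep, , drop = FALSE]
  if (nrow(sub) < 3) {
    abort(sprintf("need at least 3 records to fit (%d after filtering to '%s')",
                  nrow(sub), burial_class),
          class = "bonechron_insufficient_data")
  }
  if (stats::var(sub$mat) == 0) {
    abort("all records share one MAT; the design is degenerate",
          class = "bonechron_degenerate_design")
  }
  dat <- data.frame(log_age = log10(sub$age), mat = sub$mat)
  if (weighted) {
    sigma_log <- (sub$age_2sigma / 2) / (sub$age * log(10))
    if (any(sigma_log <= 0)) {
      abort("weighted fit requires strictly positive age_2sigma for every record",
            class = "bonechron_input_error")
    }
    fit <- lm(log_age ~ mat, data = dat, weights = 1 / sigma_log^2)
  } else {
    fit <- lm(log_age ~ mat, data = dat)
  }
  # summary.lm warns on exact fits; zero residual variance is legitimate here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(
    list(
      burial_class = burial_class,
      slope = unname(coef(fit)[["mat"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      n = nrow(sub),
      r_squared = sm$r.squared,
      p_value = sm$coefficients["mat", "Pr(>|t|)"],
      residual_variance = sm$sigma^2,
      design_info = list(mat_mean = mean(dat$mat),
                         ss_mat = sum((dat$mat - mean(dat$mat))^2),
                         n = nrow(sub)),
      mat_range = range(dat$mat),
      weighted = weighted,
      fit = fit
    ),
    class = "persistence_fit"
  )
}

#' Predict bone persistence at a temperature
#'
#' Back-transformed point prediction and upper interval bound for bone
#' persistence at a new MAT. The mean persistence is
#' `10^(intercept + slope * mat)`; the upper bound is the back-transformed
#' upper limit of a two-sided interval on the log10 scale, either the
#' confidence interval of the mean regression line (default) or the prediction
#' interval for a single new bone (`interval_kind = "new_observation"`).
#' Intervals are computed from the stored sufficient statistics, so they work
#' identically on a model read back from JSON.
#'
#' @param model A `persistence_fit` (from [fit_persistence()] or
#'   [read_persistence_model()]).
#' @param mat Mean annual temperature(s), deg C. Vectorized.
#' @param ci_level Two-sided interval level, default 0.95.
#' @param interval_kind `"mean_confidence"` (interval on the regression line)
#'   or `"new_observation"` (prediction interval for a new bone).
#' @return A tibble with one row per `mat`: `mat`, `mean_persistence` (yr),
#'   `upper_ci` (yr), `ci_level`, `interval_kind`, and `extrapolated`
#'   (`TRUE` when `mat` lies outside the fitted MAT range).
#' @export
#' @examples
#' bones <- gen_bone_table(bone_gen_config(n = 20, seed = 42))
#' fit <- fit_persistence(bones, "never_buried")
#' predict_persistence(fit, mat = -13.3)
predict_persistence <- function(model, mat, ci_level = 0.95,
                                interval_kind = c("mean_confidence", "new_observation")) {
  interval_kind <- match.arg(interval_kind)
  stopifnot(inherits(model, "persistence_fit"))
  if (any(!is.finite(mat))) {
    abort("mat must be finite", class = "bonechron_input_error")
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("ci_level must be in (0, 1)", class = "bonechron_input_error")
  }
  di <- model$design_info
  mu <- model$intercept + model$slope * mat
  leverage <- 1 / di$n + (mat - di$mat_mean)^2 / di$ss_mat
  if (interval_kind == "new_observation") leverage <- leverage + 1
  se <- sqrt(model$residual_variance * leverage)
  tq <- qt(1 - (1 - ci_level) / 2, df = di$n - 2)
  tibble(
    mat = mat,
    mean_persistence = 10^mu,
    upper_ci = 10^(mu + tq * se),
    ci_level = ci_level,
    interval_kind = interval_kind,
    extrapolated = mat < model$mat_range[1] | mat > model$mat_range[2]
  )
}

#' Predict persistence at a set of sites
#'
#' Vectorized [predict_persistence()] over a site table, keeping the site
#' identifiers alongside the predictions in input order.
#'
#' @param model A `persistence_fit`.
#' @param sites A data frame with a `mat` column and any identifier columns
#'   (e.g. `site_id`, `region`).
#' @inheritParams predict_persistence
#' @return `sites` with the prediction columns appended, one row per site.
#' @export
predict_at_sites <- function(model, sites, ci_level = 0.95,
                             interval_kind = c("mean_confidence", "new_observation")) {
  stopifnot(is.data.frame(sites))
  require_columns(sites, "mat", "site table")
  if (nrow(sites) == 0) {
    pred <- predict_persistence(model, numeric(0), ci_level, interval_kind)
    return(dplyr::bind_cols(as_tibble(sites), pred[, setdiff(names(pred), "mat")]))
  }
  pred <- predict_persistence(model, sites$mat, ci_level, interval_kind)
  dplyr::bind_cols(as_tibble(sites), pred[, setdiff(names(pred), "mat")])
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("Bone persistence regression (%s)\n", x$burial_class))
  cat(sprintf("  log10(persistence yr) = %.4f %+.4f * MAT   (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.3f, slope p = %.3g, residual variance = %.4f\n",
              x$r_squared, x$p_value, x$residual_variance))
  invisible(x)
}

#' Tidy a persistence fit
#'
#' @param x A `persistence_fit`.
#' @param ... Unused.
#' @return A tibble of coefficient estimates with standard errors and
#'   two-sided p-values, one row per term, as for `lm`.
#' @export
tidy.persistence_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "mat"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' One-row model summary of a persistence fit
#'
#' @param x A `persistence_fit`.
#' @param ... Unused.
#' @return A one-row tibble: burial class, slope, intercept, `r.squared`,
#'   slope `p.value`, residual variance and n.
#' @export
glance.persistence_fit <- function(x, ...) {
  tibble(
    burial_class = x$burial_class,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    p.value = x$p_value,
    residual_variance = x$residual_variance,
    n = x$n
  )
}

#' Plot a persistence fit
#'
#' Scatter of log10 persistence against MAT with the fitted line and the
#' two-sided interval band of the requested kind.
#'
#' @param object A `persistence_fit`.
#' @param ci_level,interval_kind Passed to [predict_persistence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot persistence_fit
#' @export
autoplot.persistence_fit <- function(object, ci_level = 0.95,
                                     interval_kind = "mean_confidence", ...) {
  dat <- object$fit$model
  grid <- seq(object$mat_range[1], object$mat_range[2], length.out = 100)
  pred <- predict_persistence(object, grid, ci_level, interval_kind)
  di <- object$design_info
  leverage <- 1 / di$n + (grid - di$mat_mean)^2 / di$ss_mat
  if (interval_kind == "new_observation") leverage <- leverage + 1
  tq <- qt(1 - (1 - ci_level) / 2, df = di$n - 2)
  band <- tibble(
    mat = grid,
    fit = log10(pred$mean_persistence),
    lwr = log10(pred$mean_persistence) - tq * sqrt(object$residual_variance * leverage),
    upr = log10(pred$upper_ci)
  )
  ggplot2::ggplot(band, ggplot2::aes(x = .data$mat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(data = dat, ggplot2::aes(x = .data$mat, y = .data$log_age)) +
    ggplot2::labs(x = "Mean annual temperature (°C)",
                  y = "log10 bone persistence (yr)",
                  title = sprintf("Bone persistence vs temperature (%s)",
                                  object$burial_class)) +
    ggplot2::theme_minimal()
}

#' Serialize a persistence model to JSON
#'
#' Writes every scalar field plus the design sufficient statistics, enough to
#' reconstruct predictions and intervals exactly; the raw `lm` object is not
#' stored.
#'
#' @param model A `persistence_fit`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_persistence_model <- function(model, path) {
  stopifnot(inherits(model, "persistence_fit"))
  payload <- model[c("burial_class", "slope", "intercept", "n", "r_squared",
                     "p_value", "residual_variance", "design_info", "mat_range",
                     "weighted")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized persistence model
#'
#' @param path Path to a JSON file written by [write_persistence_model()].
#' @return A `persistence_fit` whose predictions and intervals are identical to
#'   the original's; the `fit` element is `NULL`.
#' @export
read_persistence_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$mat_range <- as.numeric(payload$mat_range)
  payload$fit <- NULL
  structure(payload, class = "persistence_fit")
}
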