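# Seasonal contrasts in trip-level metrics: random-intercept linear mixed
# models on log-transformed responses, REML with Satterthwaite degrees of
# freedom (lmerTest).

#' Fit the seasonal mixed model for one trip-level response
#'
#' Fits `log(response) ~ season + (1 | bird)` by REML and reports the
#' spring-vs-autumn contrast with a Satterthwaite-based p-value and Wald
#' 95% confidence interval. Singular fits (zero between-bird variance) are
#' flagged, not treated as errors: they indicate negligible
#' between-individual variation.
#'
#' @param data Data frame with columns `bird`, `season` (values `autumn` /
#'   `spring`), and the response.
#' @param response Name of the response column (positive values; the model
#'   is fitted on the log scale).
#' @param conf_level Confidence level for the Wald interval.
#' @return Object of class `season_effect`.
#' @export
fit_season_model <- function(data, response = "value", conf_level = 0.95) {
  stopifnot(all(c("bird", "season", response) %in% names(data)))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  seasons <- unique(data$season)
  if (!all(c("autumn", "spring") %in% seasons)) {
    stop("both seasons must be present to estimate a seasonal contrast")
  }
  if (length(unique(data$bird)) < 2) stop("need at least 2 birds")
  bad <- which(data[[response]] <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive response in row %d: log-transform undefined", bad[1]))
  }
  df <- data.frame(y = log(data[[response]]),
                   season = factor(data$season, levels = c("autumn", "spring")),
                   bird = factor(data$bird))
  if (nlevels(df$bird) < nrow(df)) {
    fit <- suppressMessages(lmerTest::lmer(y ~ season + (1 | bird),
                                           data = df, REML = TRUE))
    co <- stats::coef(summary(fit))["seasonspring", ]
    est <- unname(co["Estimate"]); se <- unname(co["Std. Error"])
    dfree <- unname(co["df"]); p <- unname(co["Pr(>|t|)"])
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_bird <- vc$sdcor[vc$grp == "bird"]
    sd_resid <- vc$sdcor[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit)
  } else {
    # one observation per bird: the random intercept is unidentifiable, so
    # the model degrades to the fixed-effect fit with a singular flag
    fit <- stats::lm(y ~ season, data = df)
    co <- stats::coef(summary(fit))["seasonspring", ]
    est <- unname(co["Estimate"]); se <- unname(co["Std. Error"])
    dfree <- fit$df.residual; p <- unname(co["Pr(>|t|)"])
    sd_bird <- 0
    sd_resid <- stats::sigma(fit)
    singular <- TRUE
  }
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfree)
  med <- tapply(data[[response]], data$season, stats::median)
  rng <- tapply(data[[response]], data$season, range)
  structure(list(
    response = response, model = fit,
    estimate = est, se = se, df = dfree, p.value = p,
    conf.low = est - tcrit * se, conf.high = est + tcrit * se,
    conf_level = conf_level,
    sd_bird = sd_bird,
    sd_resid = sd_resid,
    singular = singular,
    n_obs = nrow(df), n_birds = nlevels(df$bird),
    median_autumn = unname(med["autumn"]), median_spring = unname(med["spring"]),
    range_autumn = rng[["autumn"]], range_spring = rng[["spring"]]),
    class = "season_effect")
}

#' @export
print.season_effect <- function(x, ...) {
  cat(sprintf("<season_effect> %s: spring vs autumn (log scale)\n", x$response))
  cat(sprintf("  estimate %+.3f [%.3f, %.3f], p = %.3f%s\n",
              x$estimate, x$conf.low, x$conf.high, x$p.value,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.season_effect <- function(x, ...) {
  tibble::tibble(response = x$response, term = "seasonspring",
                 estimate = x$estimate, std.error = x$se, df = x$df,
                 p.value = x$p.value,
                 conf.low = x$conf.low, conf.high = x$conf.high,
                 singular = x$singular)
}

#' @export
glance.season_effect <- function(x, ...) {
  tibble::tibble(response = x$response, n_obs = x$n_obs, n_birds = x$n_birds,
                 sd_bird = x$sd_bird, sd_resid = x$sd_resid,
                 REMLcrit = stats::deviance(x$model, REML = TRUE),
                 singular = x$singular)
}

#' Seasonal contrasts for a set of trip metrics
#'
#' Fits [fit_season_model()] for each response column and returns a
#' report table: medians and ranges on the original scale (per trip, or
#' per bird means first when `summary_level = "bird"`), the log-scale
#' contrast with confidence interval and p-value, and the singular-fit
#' flag.
#'
#' @param trips Trip table with `bird`, `season`, and the response columns.
#' @param responses Character vector of response column names.
#' @param summary_level `"trip"` or `"bird"`: aggregation level for the
#'   reported medians/ranges (the model itself is always fitted per trip).
#' @return Tibble, one row per response.
#' @export
season_effects <- function(trips,
                           responses = c("duration_h", "total_dist_km",
                                         "home_range_km2", "mean_depth_m",
                                         "max_depth_m"),
                           summary_level = c("trip", "bird")) {
  summary_level <- match.arg(summary_level)
  rows <- lapply(responses, function(resp) {
    if (!resp %in% names(trips)) return(NULL)
    fitted <- fit_season_model(trips, resp)
    summ <- trips[!is.na(trips[[resp]]), c("bird", "season", resp)]
    if (summary_level == "bird") {
      summ <- dplyr::summarise(dplyr::group_by(summ, .data$bird, .data$season),
                               !!resp := mean(.data[[resp]]), .groups = "drop")
    }
    med <- tapply(summ[[resp]], summ$season, stats::median)
    lo <- tapply(summ[[resp]], summ$season, min)
    hi <- tapply(summ[[resp]], summ$season, max)
    dplyr::bind_cols(
      tibble::tibble(
        median_autumn = unname(med["autumn"]), min_autumn = unname(lo["autumn"]),
        max_autumn = unname(hi["autumn"]),
        median_spring = unname(med["spring"]), min_spring = unname(lo["spring"]),
        max_spring = unname(hi["spring"])),
      tidy(fitted))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "response")
}
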