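#' Validate a daily weather table
#'
#' Checks the invariants a daily weather series must satisfy before thermal
#' time or environmental covariates are computed: one row per day with
#' strictly increasing consecutive dates within each environment,
#' `tmin <= tavg <= tmax` where all three are present, and non-negative
#' precipitation and global radiation.
#'
#' @param weather A data frame with columns `env_id` (optional when the table
#'   holds a single environment), `date` (`Date`), and any of `tmin`, `tavg`,
#'   `tmax` (deg C), `precip` (mm), `evap` (mm, potential evaporation),
#'   `glorad` (MJ/m2), `vpd` (kPa).
#' @return The input, invisibly, after validation.
#' @export
check_weather <- function(weather) {
  weather <- as_weather(weather)
  split(weather, weather$env_id) |>
    purrr::iwalk(function(w, env) {
      d <- diff(as.numeric(w$date))
      if (length(d) && any(d != 1)) {
        abort(sprintf("weather for '%s' is not daily: gap after %s",
                      env, w$date[which(d != 1)[1]]))
      }
      if (all(c("tmin", "tavg", "tmax") %in% names(w))) {
        ok <- stats::complete.cases(w[c("tmin", "tavg", "tmax")])
        bad <- ok & !(w$tmin <= w$tavg & w$tavg <= w$tmax)
        if (any(bad)) {
          abort(sprintf("weather for '%s': tmin <= tavg <= tmax violated on %s",
                        env, w$date[which(bad)[1]]))
        }
      }
      for (v in c("precip", "glorad")) {
        if (v %in% names(w) && any(w[[v]] < 0, na.rm = TRUE)) {
          abort(sprintf("weather for '%s': negative %s", env, v))
        }
      }
    })
  invisible(weather)
}

as_weather <- function(weather) {
  weather <- tibble::as_tibble(weather)
  if (!"date" %in% names(weather)) abort("weather must have a 'date' column")
  if (!"env_id" %in% names(weather)) weather$env_id <- "env"
  weather$date <- as.Date(weather$date)
  dplyr::arrange(weather, .data$env_id, .data$date)
}

#' Cumulative growing degree-days from daily average temperature
#'
#' Thermal time is accumulated as the daily sum of average temperature
#' truncated at 0 deg C, from the sowing date to the end of the season.
#' Days with `tavg < 0` contribute zero; they never subtract.
#'
#' @param weather Daily weather table (see [check_weather()]); `tavg` must be
#'   present and non-missing for every day of the season window.
#' @param sowing_date,season_end Either single `Date`s applied to every
#'   environment, or a data frame with columns `env_id`, `sowing_date`,
#'   `season_end`. `season_end` defaults to August 15 of the calendar year in
#'   which the series ends when omitted.
#' @return A tibble with one row per in-season day: `env_id`, `date`, `tavg`,
#'   `gdd_daily` (the truncated increment) and `gdd` (cumulative,
#'   non-decreasing).
#' @export
compute_gdd <- function(weather, sowing_date = NULL, season_end = NULL) {
  weather <- as_weather(weather)
  if (!"tavg" %in% names(weather)) abort("weather must have a 'tavg' column")

  windows <- season_windows(weather, sowing_date, season_end)
  out <- dplyr::inner_join(weather, windows, by = "env_id") |>
    dplyr::filter(.data$date >= .data$sowing_date, .data$date <= .data$season_end)
  if (nrow(out) == 0) abort("no weather days fall inside the season window")

  miss <- out[is.na(out$tavg), ]
  if (nrow(miss) > 0) {
    abort(sprintf("missing tavg inside the season window: %s (%s)",
                  miss$date[1], miss$env_id[1]))
  }
  out |>
    dplyr::group_by(.data$env_id) |>
    dplyr::mutate(gdd_daily = pmax(.data$tavg, 0), gdd = cumsum(.data$gdd_daily)) |>
    dplyr::ungroup() |>
    dplyr::select("env_id", "date", "tavg", "gdd_daily", "gdd")
}

season_windows <- function(weather, sowing_date, season_end) {
  envs <- unique(weather$env_id)
  if (is.data.frame(sowing_date)) {
    win <- tibble::as_tibble(sowing_date)
    if (is.null(season_end) && !"season_end" %in% names(win)) {
      win$season_end <- default_season_end(win$sowing_date)
    }
    win$sowing_date <- as.Date(win$sowing_date)
    win$season_end <- as.Date(win$season_end)
  } else {
    first <- tapply(weather$date, weather$env_id, min)
    last <- tapply(weather$date, weather$env_id, max)
    sow <- if (is.null(sowing_date)) as.Date(first[envs], origin = "1970-01-01")
           else rep(as.Date(sowing_date), length(envs))
    end <- if (is.null(season_end)) pmin(as.Date(last[envs], origin = "1970-01-01"),
                                         default_season_end(sow))
           else rep(as.Date(season_end), length(envs))
    win <- tibble::tibble(env_id = envs, sowing_date = sow, season_end = end)
  }
  bad <- win$sowing_date >= win$season_end
  if (any(bad)) abort(sprintf("sowing_date is not before season_end for '%s'",
                              win$env_id[which(bad)[1]]))
  win
}

# fixed end of the harvest season (Aug 15): the growing season of a
# winter-sown crop ends in the calendar year after sowing
default_season_end <- function(sowing_date) {
  y <- as.integer(format(as.Date(sowing_date), "%Y"))
  m <- as.integer(format(as.Date(sowing_date), "%m"))
  as.Date(sprintf("%d-08-15", ifelse(m > 8, y + 1L, y)))
}

#' Partition a season into fixed-size growing-degree-day stages
#'
#' Days are assigned to stages greedily: a stage accumulates daily
#' degree-days and closes on the day its running total reaches `stage_size`;
#' the next day opens the next stage. The boundary-crossing day is therefore
#' counted with the stage it started in, so every complete stage accumulates
#' at least `stage_size` (and less than `stage_size` plus the largest daily
#' increment). A trailing stage that has not reached `stage_size` by season
#' end is flagged incomplete.
#'
#' @param gdd Output of [compute_gdd()].
#' @param stage_size Stage width in degree-days (default 100).
#' @return A tibble with one row per (`env_id`, `stage`): `start_date`,
#'   `end_date`, `gdd_start`, `gdd_end`, `n_days`, `complete`. The per-day
#'   stage assignment is attached as attribute `"days"`.
#' @export
assign_stages <- function(gdd, stage_size = 100) {
  if (!is.data.frame(gdd) || nrow(gdd) == 0) abort("empty GDD series")
  if (stage_size <= 0) abort("stage_size must be positive")

  days <- gdd |>
    dplyr::group_by(.data$env_id) |>
    dplyr::mutate(
      gdd_before = .data$gdd - .data$gdd_daily,
      stage = greedy_stages(.data$gdd_daily, stage_size)
    ) |>
    dplyr::ungroup()

  stages <- days |>
    dplyr::group_by(.data$env_id, .data$stage) |>
    dplyr::summarise(
      start_date = min(.data$date),
      end_date = max(.data$date),
      gdd_start = min(.data$gdd_before),
      gdd_end = max(.data$gdd),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(complete = .data$gdd_end - .data$gdd_start >= stage_size) |>
    dplyr::arrange(.data$env_id, .data$stage)

  attr(stages, "days") <- days[c("env_id", "date", "stage")]
  attr(stages, "stage_size") <- stage_size
  stages
}

greedy_stages <- function(inc, stage_size) {
  stage <- integer(length(inc))
  k <- 1L
  acc <- 0
  for (i in seq_along(inc)) {
    stage[i] <- k
    acc <- acc + inc[i]
    if (acc >= stage_size) {
      k <- k + 1L
      acc <- 0
    }
  }
  stage
}
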