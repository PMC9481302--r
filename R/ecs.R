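#' @section Climatic covariate codes:
#' The 17 per-stage climatic covariates follow the field's standard set:
#' `ave.glorad`, `ave.temp`, `ave.vpd` (stage means of radiation, temperature
#' and vapour-pressure deficit), `cumglorad`, `cumprec`, `cumvpd`
#' (accumulations), `ratrdtmp` (accumulated radiation over accumulated
#' truncated-at-0 temperature), `cumpospetp` / `cumnegpetp` / `cumpetp`
#' (accumulated positive / negative / total daily precipitation minus
#' potential evaporation), `cumntdryd` (days with precipitation <=
#' evaporation; ties are dry), `cumnsti4` / `cumsti0` (accumulated minimum
#' temperature on days below -4 / 0 deg C), `cumndt0` (days with minimum
#' temperature below 0), `GDD` (stage thermal sum), and `ndi10m` / `sri10m`
#' (count of, and radiation summed over, days below 10.45 MJ/m2, i.e. 1,045
#' J/cm2 converted to the radiation unit).
#' @name climatic-ecs
#' @keywords internal
NULL

climatic_ec_codes <- c(
  "ave.glorad", "ave.temp", "ave.vpd", "cumglorad", "ratrdtmp",
  "cumpospetp", "cumnegpetp", "cumpetp", "cumntdryd", "cumnsti4",
  "cumndt0", "cumsti0", "cumprec", "cumvpd", "GDD", "ndi10m", "sri10m"
)

# low-radiation threshold, MJ/m2 (1,045 J/cm2)
low_radiation_mjm2 <- 10.45

# sum of x over days where cond holds; NA if any day value is missing
# (missing days are never silently treated as zero)
csum <- function(x, cond = TRUE) {
  if (length(x) == 0 || anyNA(x) || anyNA(cond)) return(NA_real_)
  sum(x[cond])
}
cmean <- function(x) {
  if (length(x) == 0 || anyNA(x)) return(NA_real_)
  mean(x)
}

#' Per-stage climatic environmental covariates
#'
#' Computes the 17 climatic covariates (see the codes listed under Details)
#' for every growth stage of every environment, over each stage's day window.
#' A covariate whose input field is absent (e.g. no `vpd` column) or has a
#' missing day inside the stage is emitted as `NA` for that stage, never as
#' zero; downstream quality control ([qc_ecs()]) decides whether the column
#' survives. Temperature sums and counts below 0 / -4 deg C use `tmin`,
#' falling back to `tavg` when `tmin` is not provided.
#'
#' @param weather Daily weather table (see [check_weather()]).
#' @param stages Stage table from [assign_stages()].
#' @return A tibble with one row per (`env_id`, `stage`): `complete` flag plus
#'   the 17 covariate columns.
#' @export
compute_stage_ecs <- function(weather, stages) {
  weather <- as_weather(weather)
  days <- attr(stages, "days")
  if (is.null(days)) abort("stages must come from assign_stages()")

  w <- dplyr::inner_join(weather, days, by = c("env_id", "date"))
  counts <- dplyr::count(w, .data$env_id, .data$stage)
  missing_stage <- dplyr::anti_join(stages, counts, by = c("env_id", "stage"))
  if (nrow(missing_stage) > 0) {
    abort(sprintf("stage %d of '%s' has zero weather days",
                  missing_stage$stage[1], missing_stage$env_id[1]))
  }

  col <- function(v) if (v %in% names(w)) w[[v]] else rep(NA_real_, nrow(w))
  w$.tavg <- col("tavg")
  w$.tmin <- if ("tmin" %in% names(w)) w$tmin else w$.tavg
  w$.prec <- col("precip")
  w$.evap <- col("evap")
  w$.glorad <- col("glorad")
  w$.vpd <- col("vpd")

  ecs <- w |>
    dplyr::group_by(.data$env_id, .data$stage) |>
    dplyr::summarise(
      ave.glorad = cmean(.data$.glorad),
      ave.temp = cmean(.data$.tavg),
      ave.vpd = cmean(.data$.vpd),
      cumglorad = csum(.data$.glorad),
      ratrdtmp = csum(.data$.glorad) / csum(pmax(.data$.tavg, 0)),
      cumpospetp = csum(pmax(.data$.prec - .data$.evap, 0)),
      cumnegpetp = csum(pmin(.data$.prec - .data$.evap, 0)),
      cumpetp = csum(.data$.prec - .data$.evap),
      cumntdryd = csum(as.numeric(.data$.prec <= .data$.evap)),
      cumnsti4 = csum(.data$.tmin, .data$.tmin < -4),
      cumndt0 = csum(as.numeric(.data$.tmin < 0)),
      cumsti0 = csum(.data$.tmin, .data$.tmin < 0),
      cumprec = csum(.data$.prec),
      cumvpd = csum(.data$.vpd),
      GDD = csum(pmax(.data$.tavg, 0)),
      ndi10m = csum(as.numeric(.data$.glorad < low_radiation_mjm2)),
      sri10m = csum(.data$.glorad, .data$.glorad < low_radiation_mjm2),
      .groups = "drop"
    )

  dplyr::left_join(stages[c("env_id", "stage", "complete")], ecs,
                   by = c("env_id", "stage"))
}

#' Per-depth soil environmental covariates
#'
#' Soil profiles are location-level descriptors measured on four standard
#' depth layers (0-30, 30-60, 60-100 and 100-200 cm); each soil variable at
#' each depth becomes one covariate column, constant across the years of a
#' location.
#'
#' @param soil Data frame with columns `location`, `depth_top_cm`,
#'   `depth_bottom_cm` and one column per soil variable (percentages or mm).
#' @param depths Matrix-like definition of the required layers; default the
#'   four standard intervals.
#' @return A tibble with one row per location and columns named
#'   `<variable>_d<k>` for depth layer `k`.
#' @export
compute_soil_ecs <- function(soil,
                             depths = cbind(top = c(0, 30, 60, 100),
                                            bottom = c(30, 60, 100, 200))) {
  soil <- tibble::as_tibble(soil)
  need <- c("location", "depth_top_cm", "depth_bottom_cm")
  if (!all(need %in% names(soil))) {
    abort("soil must have columns location, depth_top_cm, depth_bottom_cm")
  }
  vars <- setdiff(names(soil), need)
  if (length(vars) == 0) abort("soil has no variable columns")

  for (loc in unique(soil$location)) {
    here <- soil[soil$location == loc, ]
    for (k in seq_len(nrow(depths))) {
      hit <- here$depth_top_cm == depths[k, "top"] &
        here$depth_bottom_cm == depths[k, "bottom"]
      if (sum(hit) != 1) {
        abort(sprintf("location '%s' lacks soil layer %g-%g cm",
                      loc, depths[k, "top"], depths[k, "bottom"]))
      }
    }
  }

  soil |>
    dplyr::inner_join(
      tibble::tibble(depth_top_cm = depths[, "top"],
                     depth_bottom_cm = depths[, "bottom"],
                     depth = seq_len(nrow(depths))),
      by = c("depth_top_cm", "depth_bottom_cm")
    ) |>
    dplyr::select("location", "depth", dplyr::all_of(vars)) |>
    tidyr::pivot_wider(names_from = "depth", values_from = dplyr::all_of(vars),
                       names_glue = "{.value}_d{depth}") |>
    dplyr::arrange(.data$location)
}

#' Assemble the environment-level covariate table
#'
#' Binds per-stage climatic covariates (complete stages only, by default)
#' with location-level soil covariates broadcast to every environment of the
#' location. Climatic columns are named `<code>_s<stage>`.
#'
#' @param climatic Output of [compute_stage_ecs()].
#' @param soil Output of [compute_soil_ecs()], or `NULL` to omit soil.
#' @param env_info Data frame mapping `env_id` to `location`; required when
#'   `soil` is given.
#' @param complete_only Drop incomplete trailing stages (default `TRUE`).
#' @return A tibble with one row per environment: `env_id` plus covariate
#'   columns.
#' @export
ec_table <- function(climatic, soil = NULL, env_info = NULL,
                     complete_only = TRUE) {
  cl <- climatic
  if (complete_only) cl <- dplyr::filter(cl, .data$complete)
  wide <- cl |>
    dplyr::select(-"complete") |>
    tidyr::pivot_wider(
      names_from = "stage",
      values_from = dplyr::all_of(climatic_ec_codes),
      names_glue = "{.value}_s{stage}"
    )
  if (!is.null(soil)) {
    if (is.null(env_info)) abort("env_info (env_id -> location) needed to join soil")
    wide <- env_info |>
      tibble::as_tibble() |>
      dplyr::distinct(.data$env_id, .data$location) |>
      dplyr::inner_join(soil, by = "location") |>
      dplyr::select(-"location") |>
      dplyr::right_join(wide, by = "env_id")
  }
  dplyr::arrange(wide, .data$env_id)
}

#' Quality control of environmental covariates
#'
#' Drops every covariate column whose missing fraction exceeds `na_frac` or
#' whose fraction of repeated values (values occurring more than once)
#' exceeds `repeat_frac` (strict inequalities: a column at exactly the
#' threshold is kept; a constant column is 100% repeated). The operation is
#' idempotent. Dropped columns and the reason are recorded in the
#' `"qc_dropped"` attribute.
#'
#' @param ec Environment-level covariate table ([ec_table()] output or any
#'   data frame whose non-numeric columns are identifiers).
#' @param na_frac,repeat_frac Proportion thresholds (defaults 0.10 and 0.30).
#' @return The table with offending columns removed.
#' @export
qc_ecs <- function(ec, na_frac = 0.10, repeat_frac = 0.30) {
  ec <- tibble::as_tibble(ec)
  if (nrow(ec) < 2) abort("qc_ecs needs at least 2 rows")
  num <- names(ec)[vapply(ec, is.numeric, logical(1))]
  n <- nrow(ec)

  drops <- purrr::map_dfr(num, function(cn) {
    x <- ec[[cn]]
    fna <- mean(is.na(x))
    if (fna > na_frac) {
      return(tibble::tibble(column = cn, reason = "missing", fraction = fna))
    }
    xx <- x[!is.na(x)]
    counts <- tabulate(match(xx, unique(xx)))
    frep <- if (length(xx)) sum(counts[counts > 1]) / n else 1
    if (frep > repeat_frac) {
      return(tibble::tibble(column = cn, reason = "repeated", fraction = frep))
    }
    tibble::tibble()
  })
  if (!"column" %in% names(drops)) {
    drops <- tibble::tibble(column = character(), reason = character(),
                            fraction = double())
  }

  keep <- setdiff(num, drops$column)
  if (length(keep) == 0) {
    abort("all covariate columns failed QC; review na_frac/repeat_frac thresholds")
  }
  out <- ec[, !(names(ec) %in% drops$column), drop = FALSE]
  attr(out, "qc_dropped") <- drops
  out
}

#' Centered and scaled observation-level covariate matrix
#'
#' Expands the environment-level covariate table to phenotypic observations
#' and standardizes every column to mean zero and unit sample standard
#' deviation. By default standardization happens at the environment level
#' (each environment weighted once, so the derived covariance kernel is
#' constant within environment) before row expansion; `scale =
#' "observation"` standardizes the expanded matrix instead. Residual missing
#' values are imputed to 0 after centering; columns without variance are
#' dropped with a warning.
#'
#' @param ec Environment-level covariate table that passed [qc_ecs()].
#' @param obs_index Data frame with columns `obs_id` and `env_id` mapping
#'   every phenotypic observation to its environment.
#' @param scale `"environment"` (default) or `"observation"`.
#' @return A tibble with one row per observation: `obs_id`, `env_id` and the
#'   standardized covariate columns; attributes `q` (number of covariates)
#'   and `centered_scaled = TRUE`.
#' @export
build_w <- function(ec, obs_index, scale = c("environment", "observation")) {
  scale <- match.arg(scale)
  ec <- tibble::as_tibble(ec)
  obs_index <- tibble::as_tibble(obs_index)[c("obs_id", "env_id")]
  missing_env <- setdiff(obs_index$env_id, ec$env_id)
  if (length(missing_env) > 0) {
    abort(sprintf("observations map to environments absent from ec: %s",
                  paste(missing_env[seq_len(min(5, length(missing_env)))],
                        collapse = ", ")))
  }
  num <- names(ec)[vapply(ec, is.numeric, logical(1))]

  standardize <- function(df) {
    kept <- character()
    for (cn in num) {
      x <- df[[cn]]
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s) || s == 0) next
      z <- (x - mean(x, na.rm = TRUE)) / s
      z[is.na(z)] <- 0
      df[[cn]] <- z
      kept <- c(kept, cn)
    }
    if (length(kept) < length(num)) {
      warn(sprintf("dropped %d zero-variance covariate column(s)",
                   length(num) - length(kept)))
    }
    df[c(setdiff(names(df), num), kept)]
  }

  if (scale == "environment") {
    ec_std <- standardize(ec)
    out <- dplyr::inner_join(obs_index, ec_std, by = "env_id")
  } else {
    expanded <- dplyr::inner_join(obs_index, ec, by = "env_id")
    out <- standardize(expanded)
  }
  out <- dplyr::arrange(out, match(.data$obs_id, obs_index$obs_id))
  q <- sum(vapply(out, is.numeric, logical(1)))
  attr(out, "q") <- q
  attr(out, "centered_scaled") <- TRUE
  attr(out, "scale_level") <- scale
  out
}

#' Environmental covariance kernel
#'
#' The observation-level environmental kernel is the cross-product of the
#' standardized covariate matrix divided by the number of covariates,
#' `Omega = W W' / q`. It is symmetric positive semidefinite and identical
#' over observations sharing an environment.
#'
#' @param W Output of [build_w()].
#' @return A symmetric matrix with `obs_id` dimnames; attribute `q`.
#' @export
build_omega <- function(W) {
  num <- vapply(W, is.numeric, logical(1))
  q <- sum(num)
  if (q == 0) abort("W has no covariate columns (q = 0)")
  M <- as.matrix(W[num])
  omega <- tcrossprod(M) / q
  dimnames(omega) <- list(W$obs_id, W$obs_id)
  attr(omega, "q") <- q
  omega
}
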