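# shared fixture builders; everything is generated in code at test time

const_weather <- function(days, tavg = 10, tmin = tavg, tmax = tavg,
                          precip = 0, evap = 0, glorad = 0, vpd = 0,
                          env_id = "env", start = as.Date("2014-03-01")) {
  n <- days
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  tibble::tibble(
    env_id = env_id, date = start + seq_len(n) - 1,
    tmin = rep_n(tmin), tavg = rep_n(tavg), tmax = rep_n(tmax),
    precip = rep_n(precip), evap = rep_n(evap),
    glorad = rep_n(glorad), vpd = rep_n(vpd)
  )
}

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cycles = 2, lines_per_cycle = 24, n_locations = 2, years = 2,
         snp_count = 240, block_lines = 8),
    list(...)
  )
  do.call(sim_config, args)
}

# memoised small dataset shared across test files
.fixture_env <- new.env(parent = emptyenv())
tiny_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_dataset(tiny_cfg(), seed = seed)
  }
  .fixture_env[[key]]
}

# independent naive per-day oracle for the 17 climatic covariates
naive_stage_ecs <- function(w) {
  tm <- if (all(is.na(w$tmin))) w$tavg else w$tmin
  dry <- w$precip <= w$evap
  low <- w$glorad < 10.45
  c(
    ave.glorad = mean(w$glorad), ave.temp = mean(w$tavg), ave.vpd = mean(w$vpd),
    cumglorad = sum(w$glorad),
    ratrdtmp = sum(w$glorad) / sum(ifelse(w$tavg > 0, w$tavg, 0)),
    cumpospetp = sum(ifelse(w$precip - w$evap > 0, w$precip - w$evap, 0)),
    cumnegpetp = sum(ifelse(w$precip - w$evap < 0, w$precip - w$evap, 0)),
    cumpetp = sum(w$precip - w$evap),
    cumntdryd = sum(dry),
    cumnsti4 = sum(tm[tm < -4]),
    cumndt0 = sum(tm < 0),
    cumsti0 = sum(tm[tm < 0]),
    cumprec = sum(w$precip), cumvpd = sum(w$vpd),
    GDD = sum(ifelse(w$tavg > 0, w$tavg, 0)),
    ndi10m = sum(low), sri10m = sum(w$glorad[low])
  )
}
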