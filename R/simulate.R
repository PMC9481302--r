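#' Configuration of the synthetic breeding-programme generator
#'
#' Describes a winter-wheat-like multi-environment trial system: breeding
#' cycles of inbred lines genotyped at biallelic SNPs, tested with two
#' replicates in blocks on X-Y field grids across year-location
#' environments, with daily weather, location soil profiles, and two
#' negatively correlated traits generated from the full reaction-norm model
#' (fixed trials plus line, line-by-environment, spatial, genomic and
#' genomic-by-environmental effects).
#'
#' Default variance components and between-trait correlations emulate the
#' magnitudes typical of grain yield and protein content in commercial
#' winter-wheat trials (genomic correlation -0.5); trait means default to
#' 8.85 kg/plot and 9.84%.
#'
#' @param n_cycles,lines_per_cycle Breeding cycles and lines per cycle
#'   (default 3 x 100 = 300 lines).
#' @param n_locations,years Locations and years; every location-year pair is
#'   one environment (default 3 x 2 = 6).
#' @param snp_count Number of SNPs (default 1,000).
#' @param maf_range Founder allele-frequency range (uniform draw).
#' @param inbreeding Probability a genotype call is drawn fully homozygous,
#'   emulating the elevated homozygosity of advanced selfing generations so
#'   that the mean GRM diagonal exceeds 1 (default 0.95).
#' @param drift Between-cycle drift of allele frequencies on the logit scale;
#'   0 removes cycle structure (default 0.3).
#' @param missing_rate Fraction of genotype calls set missing (default 0).
#' @param reps Replicate plots per line and environment (default 2).
#' @param block_lines Distinct lines per block (default 21).
#' @param checks Number of check lines replicated in every block (default 2).
#' @param grid_cols Field-grid width in plots (default 23).
#' @param traits Trait names (two).
#' @param trait_means Intercepts per trait.
#' @param fixed_sd SD of the fixed trial effects (deliberately large so fixed
#'   effects absorb substantial variation, default 0.6).
#' @param vc Named list of per-effect variance parameters: each element
#'   `list(var = c(<trait1>, <trait2>), cor = <between-trait correlation>)`
#'   for effects `l`, `f`, `s`, `g`, `gw`, `e`.
#' @param year_anomaly_sd SD of the regional year anomalies shared by all
#'   locations (deg C for temperature; radiation scales with it). Larger
#'   values give more climatically contrasting seasons and hence more
#'   transferable environmental covariates (default 0.8).
#' @param sowing_month_day,season_end_month_day Season window (winter sowing
#'   to the fixed mid-August season end).
#' @param first_year First harvest year label.
#' @return A validated `gddrn_sim_config` list.
#' @export
sim_config <- function(n_cycles = 3, lines_per_cycle = 100,
                       n_locations = 3, years = 2, snp_count = 1000,
                       maf_range = c(0.1, 0.5), inbreeding = 0.95,
                       drift = 0.3, missing_rate = 0,
                       reps = 2, block_lines = 21, checks = 2, grid_cols = 23,
                       traits = c("yield", "protein"),
                       trait_means = c(8.85, 9.84), fixed_sd = 0.6,
                       vc = default_vc(),
                       year_anomaly_sd = 0.8,
                       sowing_month_day = "09-25",
                       season_end_month_day = "08-15",
                       first_year = 2014) {
  cfg <- as.list(environment())
  for (ef in names(cfg$vc)) {
    v <- cfg$vc[[ef]]
    if (any(v$var < 0)) abort(sprintf("negative variance for effect '%s'", ef))
    if (abs(v$cor) > 1) abort(sprintf("|correlation| > 1 for effect '%s'", ef))
  }
  if (length(traits) != 2 || length(trait_means) != 2) {
    abort("the generator is bivariate: give two traits and two means")
  }
  if (n_cycles < 1 || lines_per_cycle < 1 || snp_count < 1) {
    abort("n_cycles, lines_per_cycle and snp_count must be positive")
  }
  if (diff(maf_range) <= 0 || maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("degenerate maf_range: need 0 < lower < upper <= 0.5")
  }
  structure(cfg, class = "gddrn_sim_config")
}

# per-effect variances emulating the magnitudes reported for grain yield
# (trait 1) and protein content (trait 2) in commercial winter-wheat trials
default_vc <- function() {
  list(
    l  = list(var = c(0.051, 0.032), cor = -0.54),
    f  = list(var = c(0.048, 0.020), cor = -0.60),
    s  = list(var = c(0.065, 0.050), cor = -0.25),
    g  = list(var = c(0.049, 0.058), cor = -0.50),
    gw = list(var = c(0.112, 0.039), cor = -0.65),
    e  = list(var = c(0.056, 0.047), cor = 0)
  )
}

#' Simulate cycle-structured inbred-line genotypes
#'
#' Founder allele frequencies are drawn uniformly on `maf_range`; each
#' breeding cycle perturbs them on the logit scale (drift), making lines
#' within a cycle more related than lines across cycles. Calls are drawn
#' fully homozygous with probability `inbreeding` (emulating advanced
#' selfing) and in Hardy-Weinberg proportions otherwise, coded -1/0/1.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return A list: `geno` (matrix, lines x SNPs, `NA` for missing) and
#'   `lines` (tibble `line_id`, `cycle`, `is_check`). Founder frequencies
#'   are attached to `geno` as attribute `"founder_p"`.
#' @export
simulate_genotypes <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p0 <- runif(cfg$snp_count, cfg$maf_range[1], cfg$maf_range[2])
  n_lines <- cfg$n_cycles * cfg$lines_per_cycle
  geno <- matrix(0, n_lines, cfg$snp_count)
  lines <- tibble::tibble(
    line_id = sprintf("L%04d", seq_len(n_lines)),
    cycle = rep(seq_len(cfg$n_cycles), each = cfg$lines_per_cycle),
    is_check = FALSE
  )
  lines$is_check[seq_len(min(cfg$checks, n_lines))] <- TRUE
  rownames(geno) <- lines$line_id
  colnames(geno) <- sprintf("snp%04d", seq_len(cfg$snp_count))

  for (cyc in seq_len(cfg$n_cycles)) {
    lg <- stats::qlogis(p0) + rnorm(cfg$snp_count, 0, cfg$drift)
    pc <- stats::plogis(lg)
    rows <- which(lines$cycle == cyc)
    for (i in rows) {
      hom <- rbinom(cfg$snp_count, 1, cfg$inbreeding) == 1
      calls <- rbinom(cfg$snp_count, 2, pc) - 1
      calls[hom] <- 2 * rbinom(sum(hom), 1, pc[hom]) - 1
      geno[i, ] <- calls
    }
  }
  if (cfg$missing_rate > 0) {
    drop <- runif(length(geno)) < cfg$missing_rate
    geno[drop] <- NA
  }
  attr(geno, "founder_p") <- p0
  list(geno = geno, lines = lines)
}

#' Simulate daily weather for every year-location environment
#'
#' Seasonal sinusoidal temperature and radiation with daily noise, wet-day
#' exponential precipitation, seasonal potential evaporation and a
#' temperature-linked vapour-pressure deficit. Parameters are set so every
#' environment comfortably accumulates the full set of 100-GDD stages
#' between autumn sowing and the fixed mid-August season end.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return A list: `weather` (daily tibble with `env_id`, `date`, `tmin`,
#'   `tavg`, `tmax`, `precip`, `evap`, `glorad`, `vpd`) and `env_info`
#'   (tibble `env_id`, `location`, `year`, `sowing_date`, `season_end`).
#' @export
simulate_weather <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  locs <- sprintf("L%d", seq_len(cfg$n_locations))
  yrs <- cfg$first_year + seq_len(cfg$years) - 1
  # regional year anomalies shared by all locations: sites in one region
  # experience the same warm/cold and dull/bright seasons, which is what
  # makes environmental covariates transferable across locations
  year_temp <- stats::setNames(rnorm(length(yrs), 0, cfg$year_anomaly_sd), yrs)
  year_rad <- stats::setNames(rnorm(length(yrs), 0, 2.5 * cfg$year_anomaly_sd), yrs)
  combos <- expand.grid(location = locs, year = yrs,
                        stringsAsFactors = FALSE)
  out <- purrr::pmap(combos, function(location, year) {
    sowing <- as.Date(sprintf("%d-%s", year - 1, cfg$sowing_month_day))
    season_end <- as.Date(sprintf("%d-%s", year, cfg$season_end_month_day))
    dates <- seq(sowing, season_end, by = "day")
    doy <- as.integer(format(dates, "%j"))
    s <- cos(2 * pi * (doy - 197) / 365)
    # baseline high enough that even a cold year anomaly leaves the season
    # with at least 27 complete 100-GDD stages
    base <- 10.7 + 0.5 * match(location, locs) + year_temp[as.character(year)] +
      rnorm(1, 0, 0.25)
    tavg <- base + 7.5 * s + rnorm(length(dates), 0, 2)
    spread_lo <- 1.5 + abs(rnorm(length(dates), 0, 1.5))
    spread_hi <- 1.5 + abs(rnorm(length(dates), 0, 1.5))
    glorad <- pmax(0.3, 10 + year_rad[as.character(year)] + 8 * s +
                     rnorm(length(dates), 0, 3))
    env_id <- sprintf("%s_%d", location, year)
    list(
      weather = tibble::tibble(
        env_id = env_id, date = dates,
        tmin = tavg - spread_lo, tavg = tavg, tmax = tavg + spread_hi,
        precip = rbinom(length(dates), 1, 0.55) * rexp(length(dates), 1 / 3.5),
        evap = pmax(0, 0.6 + 2.2 * s + rnorm(length(dates), 0, 0.4)),
        glorad = glorad,
        vpd = pmax(0.02, 0.1 + 0.04 * pmax(tavg, 0) + rnorm(length(dates), 0, 0.05))
      ),
      env_info = tibble::tibble(env_id = env_id, location = location,
                                year = year, sowing_date = sowing,
                                season_end = season_end)
    )
  })
  list(weather = purrr::map_dfr(out, "weather"),
       env_info = purrr::map_dfr(out, "env_info"))
}

#' Simulate location soil profiles
#'
#' Seven soil variables on the four standard depth layers per location, with
#' mild depth trends; constant across years within a location.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return A tibble in the [compute_soil_ecs()] input layout.
#' @export
simulate_soil <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  locs <- sprintf("L%d", seq_len(cfg$n_locations))
  depths <- tibble::tibble(depth_top_cm = c(0, 30, 60, 100),
                           depth_bottom_cm = c(30, 60, 100, 200))
  purrr::map_dfr(locs, function(loc) {
    base <- list(pvt = runif(1, 10, 22), wscmm = runif(1, 40, 140),
                 claynor = runif(1, 5, 20), fsandno = runif(1, 10, 35),
                 gsandno = runif(1, 10, 45), kulstof = runif(1, 0.5, 3),
                 siltnor = runif(1, 5, 25))
    purrr::imap_dfc(base, function(b, nm) {
      trend <- if (nm == "kulstof") -0.2 else runif(1, -1, 1)
      stats::setNames(tibble::tibble(pmax(0.1, b + trend * (1:4) +
                                            rnorm(4, 0, 0.5))), nm)
    }) |>
      dplyr::bind_cols(location = loc, depths) |>
      dplyr::select("location", "depth_top_cm", "depth_bottom_cm",
                    dplyr::everything())
  })
}

#' Simulate replicated field layouts
#'
#' Every environment tests every line in `reps` replicate plots, organized
#' in blocks of `block_lines` distinct lines plus `checks` check lines (all
#' replicated), laid out row-major on an X-Y grid of width `grid_cols`.
#'
#' @param cfg A [sim_config()].
#' @param lines Line table from [simulate_genotypes()].
#' @param env_ids Environment labels.
#' @param seed Optional seed.
#' @return A tibble of real plots: `obs_id`, `env_id`, `trial`, `block`,
#'   `x`, `y`, `line_id`.
#' @export
simulate_layout <- function(cfg, lines, env_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$block_lines < 1) abort("block_lines must be positive")
  check_ids <- lines$line_id[lines$is_check]
  entry_ids <- setdiff(lines$line_id, check_ids)
  purrr::map_dfr(env_ids, function(env) {
    ord <- sample(entry_ids)
    groups <- split(ord, ceiling(seq_along(ord) / cfg$block_lines))
    plots <- purrr::imap_dfr(groups, function(ids, b) {
      tibble::tibble(block = as.integer(b),
                     line_id = sample(rep(c(ids, check_ids), cfg$reps)))
    })
    n <- nrow(plots)
    plots |>
      dplyr::mutate(
        env_id = env, trial = "t1",
        x = (dplyr::row_number() - 1L) %/% cfg$grid_cols + 1L,
        y = (dplyr::row_number() - 1L) %% cfg$grid_cols + 1L,
        obs_id = sprintf("%s_p%04d", env, dplyr::row_number())
      ) |>
      dplyr::select("obs_id", "env_id", "trial", "block", "x", "y", "line_id")
  })
}

# matrix-normal draw with row covariance K (given as a factor L with
# L L' = K) and 2x2 column covariance Sigma (possibly singular)
draw_effect <- function(L, Sigma) {
  z <- matrix(rnorm(ncol(L) * nrow(Sigma)), ncol(L))
  eg <- eigen(Sigma, symmetric = TRUE)
  sq <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(Sigma)) %*% t(eg$vectors)
  L %*% z %*% sq
}

psd_factor <- function(K, tol = 1e-10) {
  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]), sum(keep))
}

effect_sigma <- function(v) {
  sds <- sqrt(v$var)
  diag(sds, 2) %*% matrix(c(1, v$cor, v$cor, 1), 2) %*% diag(sds, 2)
}

#' Simulate phenotypes from the full bivariate reaction-norm model
#'
#' Draws fixed trial effects and the line, line-by-environment, spatial,
#' genomic and genomic-by-environmental random effects from the configured
#' (co)variances against the kernels implied by the simulated genotypes,
#' layout and environmental covariates, and sums them with residuals into
#' two trait phenotypes per plot.
#'
#' @param cfg A [sim_config()].
#' @param geno,lines Output of [simulate_genotypes()].
#' @param layout Output of [simulate_layout()].
#' @param omega Observation-level environmental kernel over the layout's
#'   `obs_id`s ([build_omega()]).
#' @param seed Optional seed.
#' @return A list: `phenos` (plot table with both traits), `truth` (true
#'   effect vectors, variance parameters, and the kernels' provenance) and
#'   `G` (the realized genomic relationship matrix).
#' @export
simulate_phenotypes <- function(cfg, geno, lines, layout, omega, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layout <- tibble::as_tibble(layout)
  n <- nrow(layout)
  G <- build_grm(geno)

  completed <- add_virtual_plots(layout)
  Xs <- spatial_incidence(completed)[layout$obs_id, ]

  pair_ids <- sort(unique(paste(layout$line_id, layout$env_id, sep = "@")))
  obs_pair <- match(paste(layout$line_id, layout$env_id, sep = "@"), pair_ids)
  obs_line <- match(layout$line_id, rownames(G))
  trial_ids <- sort(unique(paste(layout$env_id, layout$trial, sep = "/")))
  obs_trial <- match(paste(layout$env_id, layout$trial, sep = "/"), trial_ids)

  GW <- build_gw_kernel(G, omega[layout$obs_id, layout$obs_id],
                        layout[c("obs_id", "line_id")])

  vc <- cfg$vc
  u_l <- draw_effect(diag(nrow(G)), effect_sigma(vc$l))
  u_f <- draw_effect(diag(length(pair_ids)), effect_sigma(vc$f))
  u_sq <- draw_effect(diag(ncol(Xs)), effect_sigma(vc$s))
  u_s <- as.matrix(Xs %*% u_sq) / 3 # cov = (X X'/9) Sigma_s = S Sigma_s
  u_g <- draw_effect(psd_factor(G), effect_sigma(vc$g))
  u_gw <- draw_effect(psd_factor(GW), effect_sigma(vc$gw))
  e <- draw_effect(diag(n), effect_sigma(vc$e))
  b <- matrix(rnorm(length(trial_ids) * 2, 0, cfg$fixed_sd),
              length(trial_ids), 2)

  Y <- matrix(rep(cfg$trait_means, each = n), n, 2) +
    b[obs_trial, , drop = FALSE] + u_l[obs_line, ] + u_f[obs_pair, ] +
    u_s + u_g[obs_line, ] + u_gw + e
  colnames(Y) <- cfg$traits

  phenos <- layout |>
    dplyr::left_join(lines[c("line_id", "cycle", "is_check")], by = "line_id") |>
    dplyr::bind_cols(tibble::as_tibble(Y))

  rownames(u_l) <- rownames(G)
  rownames(u_g) <- rownames(G)
  rownames(u_f) <- pair_ids
  rownames(u_gw) <- layout$obs_id
  rownames(u_s) <- layout$obs_id
  rownames(b) <- trial_ids

  list(
    phenos = phenos,
    truth = list(vc = vc, fixed = b, trait_means = cfg$trait_means,
                 l = u_l, f = u_f, s = u_s, g = u_g, gw = u_gw,
                 mean_diag_G = mean(diag(G))),
    G = G
  )
}

#' Simulate a complete reaction-norm study
#'
#' End-to-end generator: genotypes, weather, soil, layouts, then the full
#' environmental-covariate pipeline (thermal time, 100-GDD stages, climatic
#' and soil covariates, quality control, standardization) and finally
#' phenotypes from the bivariate reaction-norm model. A single seed makes
#' the whole dataset reproducible.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default 1).
#' @return A list with every intermediate product: `weather`, `env_info`,
#'   `soil`, `geno`, `lines`, `layout`, `ec`, `W`, `omega`, `G`, `phenos`,
#'   `truth`, plus the `config` and `seed`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  gen <- simulate_genotypes(cfg)
  wx <- simulate_weather(cfg)
  soil <- simulate_soil(cfg)
  layout <- simulate_layout(cfg, gen$lines, wx$env_info$env_id)

  gdd <- compute_gdd(wx$weather, wx$env_info[c("env_id", "sowing_date", "season_end")])
  stages <- assign_stages(gdd)
  climatic <- compute_stage_ecs(wx$weather, stages)
  soil_ec <- compute_soil_ecs(soil)
  ec <- ec_table(climatic, soil_ec, wx$env_info) |> qc_ecs()
  W <- build_w(ec, layout[c("obs_id", "env_id")])
  omega <- build_omega(W)

  sim <- simulate_phenotypes(cfg, gen$geno, gen$lines, layout, omega)
  list(config = cfg, seed = seed,
       weather = wx$weather, env_info = wx$env_info, soil = soil,
       geno = gen$geno, lines = gen$lines, layout = layout,
       stages = stages, ec = ec, W = W, omega = omega,
       G = sim$G, S = build_spatial_matrix(layout),
       phenos = sim$phenos, truth = sim$truth)
}
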