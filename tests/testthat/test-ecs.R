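stage_of <- function(w) {
  g <- compute_gdd(w)
  assign_stages(g)
}

test_that("water-balance covariates match hand sums on a 10-day stage", {
  w <- const_weather(10, tavg = 10, precip = 2, evap = 1)
  ec <- compute_stage_ecs(w, stage_of(w))
  expect_equal(ec$cumprec[1], 20)
  expect_equal(ec$cumpetp[1], 10)
  expect_equal(ec$cumpospetp[1], 10)
  expect_equal(ec$cumnegpetp[1], 0)
  expect_equal(ec$cumntdryd[1], 0)
})

test_that("radiation and temperature covariates match hand computation", {
  w <- const_weather(10, tavg = 10, glorad = 5)
  ec <- compute_stage_ecs(w, stage_of(w))
  expect_equal(ec$ave.temp[1], 10)
  expect_equal(ec$cumglorad[1], 50)
  expect_equal(ec$ratrdtmp[1], 0.5)
  expect_equal(ec$GDD[1], 100)
  expect_equal(ec$cumndt0[1], 0)
  # 5 MJ/m2 is below the 10.45 MJ/m2 low-radiation threshold
  expect_equal(ec$ndi10m[1], 10)
  expect_equal(ec$sri10m[1], 50)
})

test_that("every complete stage emits exactly the 17 climatic covariates", {
  codes <- c("ave.glorad", "ave.temp", "ave.vpd", "cumglorad", "ratrdtmp",
             "cumpospetp", "cumnegpetp", "cumpetp", "cumntdryd", "cumnsti4",
             "cumndt0", "cumsti0", "cumprec", "cumvpd", "GDD", "ndi10m",
             "sri10m")
  w <- const_weather(60, tavg = 15, precip = 1, evap = 1, glorad = 12, vpd = 0.3)
  ec <- compute_stage_ecs(w, stage_of(w))
  expect_setequal(setdiff(names(ec), c("env_id", "stage", "complete")), codes)
  expect_true(all(!is.na(ec[ec$complete, codes])))
})

test_that("absent or missing inputs yield NA covariates, never silent zeros", {
  w <- const_weather(30, tavg = 12)[, c("env_id", "date", "tavg")]
  ec <- compute_stage_ecs(w, stage_of(const_weather(30, tavg = 12)))
  expect_true(all(is.na(ec$cumvpd)))
  expect_true(all(is.na(ec$cumprec)))
  expect_false(anyNA(ec$GDD[ec$complete]))

  w2 <- const_weather(30, tavg = 12, precip = 1, evap = 0.5)
  w2$precip[3] <- NA
  ec2 <- compute_stage_ecs(w2, stage_of(w2))
  expect_true(is.na(ec2$cumprec[1]))
  expect_false(is.na(ec2$cumprec[2]))
})

test_that("every covariate matches an independent per-day oracle on random stages", {
  set.seed(7)
  for (rep in 1:5) {
    w <- const_weather(
      20, tavg = runif(20, -6, 25), tmin = NULL, precip = rexp(20, 1),
      evap = runif(20, 0, 3), glorad = runif(20, 0, 25), vpd = runif(20, 0, 1)
    )
    w$tmin <- w$tavg - runif(20, 0, 4)
    w$tmax <- w$tavg + runif(20, 0, 4)
    st <- assign_stages(compute_gdd(w), stage_size = 1e6) # one big stage
    ec <- compute_stage_ecs(w, st)
    oracle <- naive_stage_ecs(w)
    for (nm in names(oracle)) {
      expect_equal(ec[[nm]][1], unname(oracle[nm]), tolerance = 1e-12,
                   label = nm)
    }
  }
})

test_that("soil covariates: 7 variables x 4 depths per location", {
  soil <- simulate_soil(sim_config(), seed = 3)
  sec <- compute_soil_ecs(soil)
  expect_equal(nrow(sec), 3)
  expect_equal(ncol(sec) - 1, 28)
  # three distinct row-value patterns
  expect_equal(nrow(dplyr::distinct(sec[-1])), 3)
  # missing layer is an error naming the location and depth
  expect_error(compute_soil_ecs(soil[-2, ]), "lacks soil layer")
})

test_that("soil covariates broadcast identically across years of a location", {
  cfg <- tiny_cfg()
  wx <- simulate_weather(cfg, seed = 9)
  soil <- simulate_soil(cfg, seed = 9)
  gdd <- compute_gdd(wx$weather, wx$env_info[c("env_id", "sowing_date", "season_end")])
  climatic <- compute_stage_ecs(wx$weather, assign_stages(gdd))
  ec <- ec_table(climatic, compute_soil_ecs(soil), wx$env_info)
  soil_cols <- grep("_d[1-4]$", names(ec), value = TRUE)
  expect_equal(length(soil_cols), 28)
  byloc <- dplyr::inner_join(ec[c("env_id", soil_cols)],
                             wx$env_info[c("env_id", "location")], by = "env_id")
  for (loc in unique(byloc$location)) {
    rows <- unique(byloc[byloc$location == loc, soil_cols])
    expect_equal(nrow(rows), 1)
  }
})

test_that("EC quality control drops by strict missingness and repetition thresholds", {
  set.seed(5)
  n <- 100
  ec <- tibble::tibble(
    env_id = sprintf("e%03d", 1:n),
    ok = rnorm(n),
    miss11 = replace(rnorm(n), 1:11, NA),
    rep31 = c(rep(1.5, 31), rnorm(69)),
    rep30 = c(rep(2.5, 30), rnorm(70)),
    const = rep(3, n)
  )
  out <- qc_ecs(ec)
  expect_setequal(setdiff(names(out), "env_id"), c("ok", "rep30"))
  dropped <- attr(out, "qc_dropped")
  expect_setequal(dropped$column, c("miss11", "rep31", "const"))
  expect_equal(dropped$reason[dropped$column == "miss11"], "missing")
  # idempotent
  out2 <- qc_ecs(out)
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)
  expect_equal(nrow(attr(out2, "qc_dropped")), 0)
  # everything dropped is an error
  expect_error(qc_ecs(ec[c("env_id", "const")]), "failed QC")
})

test_that("W is centered and scaled, and expands environments to observations", {
  ec <- tibble::tibble(env_id = c("A", "B"), x1 = c(3, 7))
  obs <- tibble::tibble(obs_id = c("o1", "o2", "o3"),
                        env_id = c("A", "A", "B"))
  W <- build_w(ec, obs)
  # environment-level scaling with sample sd: values +/- 0.7071
  expect_equal(W$x1, c(-1, -1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(nrow(W), 3)
  expect_equal(attr(W, "q"), 1)

  # observation-level scaling: mean 0, sd 1 over the expanded rows
  W2 <- build_w(ec, obs, scale = "observation")
  expect_equal(mean(W2$x1), 0, tolerance = 1e-10)
  expect_equal(sd(W2$x1), 1, tolerance = 1e-10)
})

test_that("omega equals W W'/q, is PSD and constant within environment", {
  ec <- tibble::tibble(env_id = c("A", "B"), x1 = c(3, 7))
  obs <- tibble::tibble(obs_id = c("o1", "o2"), env_id = c("A", "B"))
  om <- build_omega(build_w(ec, obs))
  expect_equal(unname(om), matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # duplicated identical columns leave omega unchanged (q cancels)
  ec5 <- tibble::tibble(env_id = c("A", "B"), x1 = c(3, 7), x2 = c(3, 7),
                        x3 = c(3, 7))
  om5 <- build_omega(build_w(ec5, obs))
  expect_equal(unname(om5), unname(om), tolerance = 1e-10, ignore_attr = TRUE)

  # random W: omega matches the brute-force double loop
  set.seed(11)
  ecr <- tibble::as_tibble(cbind(env_id = sprintf("e%d", 1:10),
                                 as.data.frame(matrix(rnorm(50), 10, 5))))
  ecr[-1] <- lapply(ecr[-1], as.numeric)
  obsr <- tibble::tibble(obs_id = sprintf("o%d", 1:10), env_id = ecr$env_id)
  Wr <- build_w(ecr, obsr)
  M <- as.matrix(Wr[vapply(Wr, is.numeric, logical(1))])
  omr <- build_omega(Wr)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) brute[i, j] <- sum(M[i, ] * M[j, ]) / ncol(M)
  expect_equal(unname(omr), brute, tolerance = 1e-12, ignore_attr = TRUE)
  ev <- eigen(omr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  # same-environment observations share omega rows
  sim <- tiny_sim()
  o <- sim$omega
  env <- sim$layout$env_id[match(rownames(o), sim$layout$obs_id)]
  same <- which(env == env[1])[1:2]
  expect_equal(o[same[1], ], o[same[2], ], tolerance = 1e-10)
})
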