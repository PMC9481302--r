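# minimal hand-built design: one iid random effect, intercept only
iid_design <- function(y, group, iters = 2000, burn_in = 400, thin = 4) {
  n <- length(y)
  ids <- sprintf("o%04d", seq_len(n))
  lv <- sort(unique(group))
  structure(list(
    Y = matrix(y, ncol = 1, dimnames = list(ids, "y")),
    X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
    effects = list(l = list(name = "l", type = "iid",
                            Z = gddrn:::incidence(group, lv))),
    spec = model_spec("M1", "y", iters = iters, burn_in = burn_in, thin = thin),
    obs = tibble::tibble(obs_id = ids, line_id = group, env_id = "E",
                         trial = "t1"),
    mean_diag_G = NA_real_
  ), class = "gddrn_design")
}

test_that("model specifications mirror the M1-M5 effect ladder", {
  expect_equal(model_spec("M1", "y")$effects, c("l", "f", "s"))
  expect_equal(model_spec("M3", "y")$effects, c("l", "f", "s", "g", "gw"))
  expect_equal(model_spec("M5", c("y", "p"))$effects, c("l", "f", "s", "g", "gw"))
  expect_error(model_spec("M4", "y"), "bivariate")
  expect_error(model_spec("M2", c("y", "p")), "single-trait")
})

test_that("the fixed design holds one column per trial (intercept + trials - 1)", {
  sim <- tiny_sim()
  spec <- model_spec("M1", "yield")
  des <- build_design(sim$phenos, sim$layout, spec)
  n_trials <- length(unique(paste(sim$phenos$env_id, sim$phenos$trial)))
  expect_equal(ncol(des$X), n_trials)
  expect_equal(colnames(des$X)[1], "(Intercept)")

  spec5 <- model_spec("M5", c("yield", "protein"))
  des5 <- build_design(sim$phenos, sim$layout, spec5, sim$G, sim$omega)
  expect_equal(ncol(des5$Y), 2)
  expect_setequal(names(des5$effects), c("l", "f", "s", "g", "gw"))

  bad <- sim$phenos
  bad$line_id[1] <- "NOPE"
  expect_error(build_design(bad, sim$layout, spec5, sim$G, sim$omega), "NOPE")
})

test_that("posterior variance of an iid effect agrees with a REML oracle", {
  skip_if_not_installed("lme4")
  set.seed(21)
  n_group <- 40
  reps <- 5
  group <- rep(sprintf("g%02d", 1:n_group), each = reps)
  u <- rnorm(n_group, 0, sqrt(0.5))
  y <- 2 + u[match(group, sort(unique(group)))] + rnorm(n_group * reps, 0, 1)
  fit <- fit_gibbs(iid_design(y, group), seed = 5)

  reml <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = group))
  vc_reml <- as.data.frame(lme4::VarCorr(reml))$vcov
  post <- setNames(fit$vc$estimate, fit$vc$component)
  psd <- setNames(fit$vc$psd, fit$vc$component)
  expect_lt(abs(post["l"] - vc_reml[1]), 3 * psd["l"])
  expect_lt(abs(post["e"] - vc_reml[2]), 3 * psd["e"])
})

test_that("a truly zero variance component shrinks toward zero", {
  set.seed(22)
  group <- rep(sprintf("g%02d", 1:40), each = 5)
  y <- rnorm(200) # no group signal at all
  fit <- fit_gibbs(iid_design(y, group), seed = 6)
  post <- setNames(fit$vc$estimate, fit$vc$component)
  expect_lt(post["l"], 0.3 * post["e"])
})

test_that("missing phenotypes are augmented and predictions stay finite", {
  sim <- tiny_sim()
  ph <- sim$phenos
  ph$yield[1:40] <- NA
  spec <- model_spec("M2", "yield", iters = 400, burn_in = 100, thin = 2)
  fit <- fit_gibbs(build_design(ph, sim$layout, spec, sim$G), seed = 3)
  expect_equal(fit$n_missing, 40)
  expect_true(all(is.finite(fit$effects$g)))
  expect_true(all(is.finite(fit$vc$estimate)))
})

test_that("heritability follows the plot-level formulas", {
  fake_fit <- function(vcs, d_g) {
    draws <- matrix(rep(vcs, each = 2), 2, length(vcs),
                    dimnames = list(NULL, names(vcs)))
    structure(list(traits = "y", vc_draws = draws, mean_diag_G = d_g,
                   vc = tibble::tibble(component = names(vcs),
                                       estimate = unname(vcs),
                                       psd = 0)),
              class = "gddrn_fit")
  }
  # sigma2_l = 0, d(G) = 1, sigma2_g = 1, residual 1: h2 = H2 = 0.5
  h <- heritability(fake_fit(c(l = 0, f = 0, s = 0, g = 1, e = 1), 1))
  expect_equal(h$estimate[h$statistic == "h2"], 0.5)
  expect_equal(h$estimate[h$statistic == "H2"], 0.5)

  # plug-in from published protein variance components and d(G) = 1.869
  h2 <- heritability(fake_fit(c(l = 0.032, f = 0.044, s = 0.050,
                                g = 0.069, e = 0.049), 1.869))
  expect_equal(h2$estimate[h2$statistic == "h2"], 0.4243, tolerance = 1e-4)
  expect_equal(h2$estimate[h2$statistic == "H2"], 0.5295, tolerance = 1e-4)

  # all non-genomic variance vanishing: h2 -> 1
  h3 <- heritability(fake_fit(c(l = 0, f = 0, s = 0, g = 1, e = 1e-12), 1))
  expect_equal(h3$estimate[h3$statistic == "h2"], 1, tolerance = 1e-9)

  expect_error(heritability(fake_fit(c(l = 1, f = 1, s = 1, e = 1), 1)), "no 'g'")
})

test_that("between-trait correlations are computed per draw", {
  draws <- cbind(g.v11 = c(1, 1), g.v12 = c(-0.5, -0.5), g.v22 = c(1, 1),
                 e.v11 = c(1, 1), e.v12 = c(0, 0), e.v22 = c(1, 1))
  fake <- structure(list(traits = c("a", "b"), vc_draws = draws),
                    class = "gddrn_fit")
  tc <- trait_correlations(fake)
  expect_equal(tc$estimate[tc$effect == "g"], -0.5)
  expect_equal(tc$estimate[tc$effect == "e"], 0)
  expect_equal(tc$skipped, c(0, 0))
})

test_that("effective sample size matches closed forms", {
  set.seed(23)
  x <- rnorm(2000)
  expect_equal(gddrn:::ess_ipse(x), 2000, tolerance = 0.2)

  rho <- 0.9
  ar <- as.numeric(stats::filter(rnorm(8000), rho, method = "recursive"))
  target <- 8000 * (1 - rho) / (1 + rho)
  expect_equal(gddrn:::ess_ipse(ar), target, tolerance = 0.5)

  if (requireNamespace("coda", quietly = TRUE)) {
    # independent oracle for the autocorrelation adjustment
    expect_equal(gddrn:::ess_ipse(ar),
                 unname(coda::effectiveSize(ar)), tolerance = 0.5)
  }

  draws <- cbind(ok = rnorm(100), flat = rep(1, 100))
  d <- mcmc_diagnostics(draws)
  expect_true(d$flag[d$parameter == "flat"])
  expect_true(is.na(d$ess[d$parameter == "flat"]))
  expect_false(d$flag[d$parameter == "ok"])
  expect_error(mcmc_diagnostics(draws[1:10, ]), "at least 50")
})

test_that("posterior summaries are invariant to observation order (within MC error)", {
  sim <- tiny_sim()
  ph <- sim$phenos[sim$phenos$env_id %in% unique(sim$phenos$env_id)[1:2], ]
  spec <- model_spec("M2", "yield", iters = 1200, burn_in = 300, thin = 3)
  f1 <- fit_gibbs(build_design(ph, sim$layout, spec, sim$G), seed = 11)
  set.seed(99)
  perm <- sample(nrow(ph))
  f2 <- fit_gibbs(build_design(ph[perm, ], sim$layout, spec, sim$G), seed = 12)
  d1 <- mcmc_diagnostics(f1)
  d2 <- mcmc_diagnostics(f2)
  for (cmp in d1$parameter) {
    tol <- 5 * sqrt(d1$mcse[d1$parameter == cmp]^2 + d2$mcse[d2$parameter == cmp]^2)
    expect_lt(abs(d1$mean[d1$parameter == cmp] - d2$mean[d2$parameter == cmp]),
              max(tol, 0.02))
  }
})

test_that("a bivariate fit with uncorrelated traits reproduces the single-trait fit", {
  cfg <- tiny_cfg(vc = purrr::map(gddrn:::default_vc(),
                                  ~ list(var = .x$var, cor = 0)))
  sim0 <- simulate_dataset(cfg, seed = 77)
  ph <- sim0$phenos[sim0$phenos$env_id %in% unique(sim0$phenos$env_id)[1:2], ]
  st <- model_spec("M2", "yield", iters = 2400, burn_in = 600, thin = 3)
  mt <- model_spec("M4", c("yield", "protein"), iters = 2400, burn_in = 600,
                   thin = 3)
  f_st <- fit_gibbs(build_design(ph, sim0$layout, st, sim0$G), seed = 31)
  f_mt <- fit_gibbs(build_design(ph, sim0$layout, mt, sim0$G), seed = 32)
  d_st <- mcmc_diagnostics(f_st)
  d_mt <- mcmc_diagnostics(f_mt)
  for (ef in c("l", "f", "s", "g", "e")) {
    a <- d_st[d_st$parameter == ef, ]
    b <- d_mt[d_mt$parameter == paste0(ef, ".v11"), ]
    tol <- 3 * sqrt(a$mcse^2 + b$mcse^2)
    expect_lt(abs(a$mean - b$mean), max(tol, 0.03))
  }
})

test_that("modeling the reaction-norm term increases genomic explained variance", {
  sim <- tiny_sim()
  s2 <- model_spec("M2", "yield", iters = 800, burn_in = 200, thin = 2)
  s3 <- model_spec("M3", "yield", iters = 800, burn_in = 200, thin = 2)
  f2 <- fit_gibbs(build_design(sim$phenos, sim$layout, s2, sim$G), seed = 41)
  f3 <- fit_gibbs(build_design(sim$phenos, sim$layout, s3, sim$G, sim$omega),
                  seed = 42)
  pve <- function(f, comps) {
    v <- setNames(f$vc$estimate, f$vc$component)
    sum(v[comps]) / sum(v)
  }
  expect_gt(pve(f3, c("g", "gw")), pve(f2, "g"))
  expect_gt(setNames(f3$vc$estimate, f3$vc$component)["gw"], 0.02)
})

test_that("whole-information predictions regressed on themselves have slope one", {
  sim <- tiny_sim()
  spec <- model_spec("M2", "yield", iters = 300, burn_in = 100, thin = 2)
  fit <- fit_gibbs(build_design(sim$phenos, sim$layout, spec, sim$G), seed = 51)
  g <- genetic_predictions(fit, "g")
  expect_equal(inflation_slope(g$pred, g$pred), 1, tolerance = 1e-9)
})

test_that("a non-PSD kernel is rejected before sampling", {
  K <- diag(4); K[1, 1] <- -1
  dimnames(K) <- list(paste0("o", 1:4), paste0("o", 1:4))
  des <- structure(list(
    Y = matrix(rnorm(4), ncol = 1, dimnames = list(rownames(K), "y")),
    X = matrix(1, 4, 1),
    effects = list(gw = list(name = "gw", type = "obs_kernel", K = K)),
    spec = model_spec("M1", "y", iters = 50, burn_in = 10, thin = 1),
    obs = tibble::tibble(obs_id = rownames(K), line_id = "L", env_id = "E",
                         trial = "t"),
    mean_diag_G = NA_real_
  ), class = "gddrn_design")
  expect_error(fit_gibbs(des, seed = 1), "not positive semidefinite")
})
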