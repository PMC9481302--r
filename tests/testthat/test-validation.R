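test_that("folds leave one year-location or one breeding cycle out", {
  sim <- tiny_sim()
  ph <- sim$phenos
  p1 <- make_folds(ph, "cv1")
  expect_equal(nrow(p1), length(unique(ph$env_id)))
  expect_setequal(unlist(p1$obs_ids), ph$obs_id) # every obs masked exactly once
  expect_equal(sum(lengths(p1$obs_ids)), nrow(ph))

  p2 <- make_folds(ph, "cv2")
  expect_equal(nrow(p2), length(unique(ph$cycle)))
  expect_setequal(unlist(p2$obs_ids), ph$obs_id)

  # under cv1 a line's records in other environments stay unmasked
  line1 <- ph$line_id[1]
  fold1_ids <- p1$obs_ids[[1]]
  other <- ph$obs_id[ph$line_id == line1 & !(ph$obs_id %in% fold1_ids)]
  expect_gt(length(other), 0)

  expect_error(make_folds(ph[ph$env_id == ph$env_id[1], ], "cv1"), "fewer than 2")
  expect_error(make_folds(dplyr::select(ph, -"cycle"), "cv2"), "cycle")
})

test_that("corrected line means subtract fixed effects and average replicates", {
  ph <- tibble::tibble(obs_id = c("o1", "o2"), line_id = "L1", env_id = "E1",
                       y = c(8, 9))
  fx0 <- matrix(0, 2, 1, dimnames = list(ph$obs_id, "y"))
  m0 <- corrected_line_means(ph, fx0, traits = "y")
  expect_equal(m0$y_bar, 8.5)
  expect_equal(m0$n_reps, 2)

  fx1 <- matrix(1, 2, 1, dimnames = list(ph$obs_id, "y"))
  expect_equal(corrected_line_means(ph, fx1, traits = "y")$y_bar, 7.5)

  expect_error(corrected_line_means(ph, fx1[1, , drop = FALSE], traits = "y"),
               "no fixed-effect estimate")

  # random set against a brute-force group-by oracle
  set.seed(31)
  phr <- tibble::tibble(
    obs_id = sprintf("o%02d", 1:30),
    line_id = sample(c("A", "B", "C"), 30, TRUE),
    env_id = sample(c("E1", "E2"), 30, TRUE),
    y = rnorm(30)
  )
  fx <- matrix(rnorm(30), 30, 1, dimnames = list(phr$obs_id, "y"))
  got <- corrected_line_means(phr, fx, traits = "y")
  corr <- phr$y - fx[phr$obs_id, 1]
  brute <- tapply(corr, paste(phr$line_id, phr$env_id), mean)
  expect_equal(got$y_bar, as.numeric(brute[paste(got$line_id, got$env_id)]),
               tolerance = 1e-12)
})

test_that("predictive ability is the pooled Pearson correlation", {
  cells <- tibble::tibble(line_id = sprintf("L%d", 1:10), env_id = "E1",
                          trait = "y", y_bar = rnorm(10), n_reps = 2)
  preds <- tibble::tibble(line_id = cells$line_id, env_id = NA_character_,
                          trait = "y", pred = cells$y_bar)
  expect_equal(predictive_ability(cells, preds)$pa, 1)
  preds$pred <- -cells$y_bar
  expect_equal(predictive_ability(cells, preds)$pa, -1)
  expect_error(predictive_ability(cells[1:2, ], preds[1:2, ]), "fewer than 3")
})

test_that("bootstrap standard errors track the delta-method closed form", {
  set.seed(32)
  n <- 500
  r <- 0.5
  x <- rnorm(n)
  y <- r * x + sqrt(1 - r^2) * rnorm(n)
  bs <- bootstrap_se(x, y, reps = 2000, seed = 1)
  delta <- (1 - cor(x, y)^2) / sqrt(n)
  expect_lt(abs(bs$se - delta) / delta, 0.25)

  # perfectly correlated pairs: SE collapses
  bp <- bootstrap_se(x, 2 * x + 1, reps = 200, seed = 2)
  expect_lt(bp$se, 1e-12)

  # SE shrinks roughly as 1/sqrt(n)
  idx <- 1:125
  bs_small <- bootstrap_se(x[idx], y[idx], reps = 2000, seed = 3)
  expect_gt(bs_small$se / bs$se, 1.3)
  expect_error(bootstrap_se(x, y, reps = 50), "at least 100")
})

test_that("the paired model test behaves under identity, shift and the null", {
  e <- rnorm(100)^2
  same <- paired_model_test(e, e)
  expect_equal(same$p_value, 1)
  expect_true(same$flag)

  shifted <- paired_model_test(e + 1, e + rnorm(100, 0, 0.01))
  expect_lt(shifted$p_value, 1e-6)

  # type-I error at the 1% critical value under equal models
  set.seed(33)
  rej <- sum(vapply(1:400, function(i) {
    a <- rnorm(50)^2
    b <- rnorm(50)^2
    paired_model_test(a, b)$p_value < 0.01
  }, logical(1)))
  # binomial(400, 0.01) central range
  expect_lte(rej, qbinom(0.999, 400, 0.01))
})

test_that("the maximum-PA bound follows the replicate-heritability formula", {
  expect_equal(max_pa(5, 1), 1)
  expect_equal(max_pa(1, 0.37), 0.37)
  expect_equal(max_pa(2, 0.5), 2 / 3, tolerance = 1e-12)
  expect_true(all(diff(max_pa(1:10, 0.3)) > 0))
  expect_error(max_pa(2, 1.2), "h2f")
})

test_that("the inflation slope matches closed-form attenuation cases", {
  set.seed(34)
  u <- rnorm(5000)
  expect_equal(inflation_slope(u, u), 1)
  expect_equal(inflation_slope(u, 2 * u), 0.5, tolerance = 1e-12)
  noisy <- u + rnorm(5000)
  expect_equal(inflation_slope(u, noisy), 0.5, tolerance = 0.1)
  expect_error(inflation_slope(u, rep(1, 5000)), "zero")
  expect_error(inflation_slope(u[1:2], u[1:2]), "length >= 3")
})

test_that("run_cv executes the full protocol end to end", {
  sim <- tiny_sim()
  spec <- model_spec("M3", "yield", iters = 500, burn_in = 150, thin = 3)
  cv <- run_cv(sim$phenos, sim$layout, sim$G, sim$omega, spec,
               scheme = "cv1", folds = 1:2, boot_reps = 200, seed = 9)
  expect_s3_class(cv, "gddrn_cv")
  expect_setequal(unique(cv$cells$fold), 1:2)
  expect_true(all(cv$pa$pa >= -1 & cv$pa$pa <= 1))
  expect_setequal(cv$pa$type, c("g", "g+gw"))
  expect_true(all(is.finite(cv$bwp$slope)))
  expect_true(all(cv$max_pa$max_pa >= 0 & cv$max_pa$max_pa <= 1))
  # each masked cell appears once per fold
  expect_false(any(duplicated(cv$cells[c("line_id", "env_id", "trait")])))
  # tidy/glance/autoplot accessors
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$n_folds, 2)
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  expect_s3_class(ggplot2::autoplot(cv$whole_fit), "ggplot")
})

test_that("trait-assisted masking only masks the target trait", {
  sim <- tiny_sim()
  spec <- model_spec("M4", c("yield", "protein"), iters = 300, burn_in = 100,
                     thin = 2)
  cv <- run_cv(sim$phenos, sim$layout, sim$G, NULL, spec, scheme = "cv1",
               ta_trait = "yield", folds = 1, boot_reps = 150, seed = 10)
  expect_setequal(unique(cv$cells$trait), "yield")
  expect_error(run_cv(sim$phenos, sim$layout, sim$G, NULL,
                      model_spec("M2", "yield"), ta_trait = "yield"),
               "bivariate")
})
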