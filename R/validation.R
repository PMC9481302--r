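#' Cross-validation fold construction
#'
#' CV1 (leave-one-year-location-out) builds one fold per environment and
#' masks every observation recorded there; CV2 (leave-one-breeding-cycle-out)
#' builds one fold per breeding cycle and masks every observation of that
#' cycle's lines, wherever tested. Every observation is masked exactly once.
#'
#' @param phenos Phenotype table with `obs_id`, `env_id`, `line_id` and (for
#'   CV2) `cycle`.
#' @param scheme `"cv1"` or `"cv2"`.
#' @return A tibble with columns `fold`, `unit` and a list-column `obs_ids`.
#' @export
make_folds <- function(phenos, scheme = c("cv1", "cv2")) {
  scheme <- match.arg(scheme)
  phenos <- tibble::as_tibble(phenos)
  if (scheme == "cv2" && !"cycle" %in% names(phenos)) {
    abort("cv2 folds need a 'cycle' column (breeding cycle labels)")
  }
  obs_unit <- as.character(if (scheme == "cv1") phenos$env_id else phenos$cycle)
  units <- sort(unique(obs_unit))
  if (length(units) < 2) abort(sprintf("fewer than 2 %s units: cannot cross-validate",
                                       scheme))
  masked <- purrr::map(units, function(u) phenos$obs_id[obs_unit == u])
  tibble::tibble(fold = seq_along(units), unit = units, obs_ids = masked)
}

#' Fixed-effect-corrected line means per environment
#'
#' Subtracts the estimated fixed effects (posterior mean of the trial
#' effects, estimated on the full dataset) from each plot observation and
#' averages within line and year-location, per trait.
#'
#' @param phenos Phenotype table with `obs_id`, `line_id`, `env_id` and the
#'   trait columns.
#' @param fixed A whole-data `gddrn_fit` (its posterior-mean fixed fitted
#'   values are used) or a numeric matrix/vector of per-observation fixed
#'   values with rownames `obs_id`.
#' @param traits Trait columns; default those of the fit.
#' @return A tibble: `line_id`, `env_id`, `trait`, `y_bar`, `n_reps`.
#' @export
corrected_line_means <- function(phenos, fixed, traits = NULL) {
  phenos <- tibble::as_tibble(phenos)
  if (inherits(fixed, "gddrn_fit")) {
    traits <- traits %||% fixed$traits
    fx <- fixed$fixed_fitted
    rownames(fx) <- fixed$obs$obs_id
  } else {
    fx <- as.matrix(fixed)
    if (is.null(traits)) abort("supply trait names when fixed is a matrix")
    if (ncol(fx) == 1 && length(traits) > 1) fx <- fx[, rep(1, length(traits))]
    colnames(fx) <- traits
  }
  idx <- match(phenos$obs_id, rownames(fx))
  if (anyNA(idx)) {
    abort(sprintf("no fixed-effect estimate for observation(s): %s",
                  paste(phenos$obs_id[is.na(idx)][1:min(5, sum(is.na(idx)))],
                        collapse = ", ")))
  }
  purrr::map_dfr(traits, function(trt) {
    tibble::tibble(line_id = phenos$line_id, env_id = phenos$env_id,
                   trait = trt, y_c = phenos[[trt]] - fx[idx, trt]) |>
      dplyr::filter(!is.na(.data$y_c)) |>
      dplyr::group_by(.data$line_id, .data$env_id, .data$trait) |>
      dplyr::summarise(y_bar = mean(.data$y_c), n_reps = dplyr::n(),
                       .groups = "drop")
  })
}

#' Predictive ability
#'
#' Pearson correlation between fixed-effect-corrected line means per
#' year-location and genetic predictions, pooled over all supplied cells
#' (typically the masked cells of all folds of a cross-validation).
#'
#' @param corrected Output of [corrected_line_means()] (possibly filtered to
#'   masked cells).
#' @param predictions Output of [genetic_predictions()]; when its `env_id` is
#'   `NA` (additive-only predictions) cells join on line and trait.
#' @return A tibble with one row per trait: `pa`, `n_cells`.
#' @export
predictive_ability <- function(corrected, predictions) {
  cells <- if (all(is.na(predictions$env_id))) {
    dplyr::inner_join(corrected,
                      dplyr::select(predictions, "line_id", "trait", "pred"),
                      by = c("line_id", "trait"))
  } else {
    dplyr::inner_join(corrected,
                      dplyr::select(predictions, "line_id", "env_id", "trait", "pred"),
                      by = c("line_id", "env_id", "trait"))
  }
  cells |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, ...) {
      if (nrow(d) < 3) abort("fewer than 3 aligned cells: cannot correlate")
      tibble::tibble(pa = stats::cor(d$y_bar, d$pred), n_cells = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Bootstrap standard error of a correlation
#'
#' Ordinary non-parametric bootstrap with replacement over paired cells;
#' degenerate resamples (zero variance in either member) are redrawn and
#' counted.
#'
#' @param x,y Paired numeric vectors.
#' @param reps Bootstrap replicates (default 10,000).
#' @param seed Optional seed.
#' @return A tibble: `estimate`, `se`, `conf.low`, `conf.high` (percentile
#'   95%), `redrawn`.
#' @export
bootstrap_se <- function(x, y, reps = 10000, seed = NULL) {
  if (reps < 100) abort("use at least 100 bootstrap replicates")
  if (length(x) != length(y)) abort("x and y must be paired")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  redrawn <- 0L
  rs <- vapply(seq_len(reps), function(i) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) {
        return(stats::cor(x[idx], y[idx]))
      }
      redrawn <<- redrawn + 1L
      if (redrawn > 100 * reps) abort("bootstrap cannot find non-degenerate resamples")
    }
  }, numeric(1))
  tibble::tibble(estimate = stats::cor(x, y), se = stats::sd(rs),
                 conf.low = unname(stats::quantile(rs, 0.025)),
                 conf.high = unname(stats::quantile(rs, 0.975)),
                 redrawn = redrawn)
}

#' Paired comparison of two models' per-cell errors
#'
#' Two-tailed paired t-test on a per-cell comparison metric of two models
#' evaluated on the same masked cells; the default metric is the squared
#' prediction error. Zero-variance differences yield `p = 1` with a flag.
#'
#' @param err_a,err_b Per-cell errors (same cells, same order).
#' @return A tibble: `statistic`, `df`, `p_value`, `flag`.
#' @export
paired_model_test <- function(err_a, err_b) {
  if (length(err_a) != length(err_b)) abort("error vectors must be paired")
  d <- err_a - err_b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(statistic = NA_real_, df = length(d) - 1,
                          p_value = 1, flag = TRUE))
  }
  tt <- stats::t.test(err_a, err_b, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, flag = FALSE)
}

#' Upper bound on predictive ability
#'
#' The theoretical maximum correlation between line means over `n` replicates
#' and genetic predictions, `sqrt`-free as used in the field's reporting:
#' `n * h2f / (1 + (n - 1) * h2f)`, with `h2f` the family-mean heritability
#' (for reaction-norm predictions, the proportion of variance explained by
#' the genomic additive plus interaction effects).
#'
#' @param n_reps Average number of line repetitions within year-location.
#' @param h2f Family heritability in `[0, 1]`.
#' @return The bound, monotone increasing in both arguments.
#' @export
max_pa <- function(n_reps, h2f) {
  if (any(h2f < 0 | h2f > 1)) abort("h2f must lie in [0, 1]")
  if (any(n_reps < 1)) abort("n_reps must be >= 1")
  n_reps * h2f / (1 + (n_reps - 1) * h2f)
}

#' Variance-inflation slope of predictions
#'
#' Regression slope of whole-information predictions on partial-information
#' predictions, `b_wp = cov(u_w, u_p) / var(u_p)`. A slope of 1 indicates no
#' inflation; below 1, the partial-information predictions are
#' over-dispersed.
#'
#' @param u_w,u_p Aligned prediction vectors (length >= 3).
#' @return The slope.
#' @export
inflation_slope <- function(u_w, u_p) {
  if (length(u_w) != length(u_p) || length(u_w) < 3) {
    abort("need aligned vectors of length >= 3")
  }
  v <- stats::var(u_p)
  if (v == 0) abort("var(u_p) is zero: slope undefined")
  stats::cov(u_w, u_p) / v
}

#' Run a full cross-validation of a reaction-norm model
#'
#' Implements the evaluation protocol: a whole-data fit provides the fixed
#' effects for line-mean correction and the whole-information predictions;
#' each fold is then refit with its phenotypes masked (both traits, or only
#' the target trait under trait-assisted prediction) and the masked cells
#' are predicted from the partial fit. Predictive abilities are pooled over
#' all masked cells, with bootstrap standard errors; per-effect
#' variance-inflation slopes compare whole- and partial-information
#' predictions.
#'
#' @param phenos,layout,G,omega As in [build_design()]; `phenos` needs
#'   `cycle` for `scheme = "cv2"`.
#' @param spec A [model_spec()] with a genomic effect (M2-M5).
#' @param scheme `"cv1"` or `"cv2"`.
#' @param ta_trait For bivariate models: the target trait to mask while the
#'   secondary trait stays observed (trait-assisted prediction); `NULL`
#'   masks all traits.
#' @param folds Optional integer vector restricting which folds to run.
#' @param boot_reps Bootstrap replicates for PA standard errors (default
#'   1,000; use 10,000 for production).
#' @param seed Seed driving every fit and the bootstrap.
#' @param whole_fit Optionally, a precomputed whole-data fit to reuse.
#' @return A `gddrn_cv` object: `cells` (masked cells with observed means and
#'   predictions), `pa`, `bwp`, `max_pa`, fold table and settings.
#' @export
run_cv <- function(phenos, layout, G = NULL, omega = NULL, spec,
                   scheme = c("cv1", "cv2"), ta_trait = NULL, folds = NULL,
                   boot_reps = 1000, seed = 1, whole_fit = NULL) {
  scheme <- match.arg(scheme)
  phenos <- tibble::as_tibble(phenos)
  if (!"g" %in% spec$effects) abort("cross-validation needs a genomic model (M2-M5)")
  if (!is.null(ta_trait)) {
    if (length(spec$traits) != 2) abort("trait-assisted masking needs a bivariate model")
    if (!ta_trait %in% spec$traits) abort("ta_trait must be one of the model traits")
  }
  has_gw <- "gw" %in% spec$effects
  plan <- make_folds(phenos, scheme)
  if (!is.null(folds)) plan <- plan[plan$fold %in% folds, ]

  design <- build_design(phenos, layout, spec, G, omega)
  blocks <- precompute_blocks(design)
  if (is.null(whole_fit)) {
    whole_fit <- fit_gibbs(design, seed = seed, blocks = blocks)
  }
  corrected <- corrected_line_means(phenos, whole_fit)

  masked_traits <- if (is.null(ta_trait)) spec$traits else ta_trait
  cells <- purrr::map2_dfr(plan$fold, plan$obs_ids, function(fd, ids) {
    des <- design
    des$Y[rownames(des$Y) %in% ids, masked_traits] <- NA
    fit_p <- fit_gibbs(des, seed = seed + fd, blocks = blocks)
    pred_g <- genetic_predictions(fit_p, "g")
    pred_ggw <- if (has_gw) genetic_predictions(fit_p, "g+gw") else NULL

    fold_cells <- phenos |>
      dplyr::filter(.data$obs_id %in% ids) |>
      dplyr::distinct(.data$line_id, .data$env_id) |>
      tidyr::expand_grid(trait = masked_traits)

    out <- fold_cells |>
      dplyr::inner_join(corrected, by = c("line_id", "env_id", "trait")) |>
      dplyr::inner_join(dplyr::select(pred_g, "line_id", "trait",
                                      pred_g = "pred"),
                        by = c("line_id", "trait"))
    if (has_gw) {
      out <- dplyr::left_join(out,
        dplyr::select(pred_ggw, "line_id", "env_id", "trait",
                      pred_ggw = "pred"),
        by = c("line_id", "env_id", "trait"))
    }
    out$fold <- fd
    out
  })

  # whole-information predictions aligned to the same cells
  uw_g <- genetic_predictions(whole_fit, "g")
  cells <- dplyr::inner_join(
    cells, dplyr::select(uw_g, "line_id", "trait", whole_g = "pred"),
    by = c("line_id", "trait"))
  if (has_gw) {
    uw_ggw <- genetic_predictions(whole_fit, "g+gw")
    cells <- dplyr::left_join(
      cells, dplyr::select(uw_ggw, "line_id", "env_id", "trait",
                           whole_ggw = "pred"),
      by = c("line_id", "env_id", "trait"))
  }

  types <- c("g", if (has_gw) "g+gw")
  pa <- purrr::map_dfr(types, function(ty) {
    pcol <- if (ty == "g") "pred_g" else "pred_ggw"
    cells |>
      dplyr::group_by(.data$trait) |>
      dplyr::group_modify(function(d, ...) {
        bs <- bootstrap_se(d$y_bar, d[[pcol]], reps = boot_reps,
                           seed = seed)
        dplyr::mutate(bs, n_cells = nrow(d))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(type = ty, .after = "trait") |>
      dplyr::rename(pa = "estimate")
  })

  bwp <- purrr::map_dfr(masked_traits, function(trt) {
    d <- cells[cells$trait == trt, ]
    out <- tibble::tibble(trait = trt, effect = "g",
                          slope = inflation_slope(d$whole_g, d$pred_g))
    if (has_gw) {
      ok <- !is.na(d$pred_ggw) & !is.na(d$whole_ggw)
      out <- dplyr::bind_rows(out, tibble::tibble(
        trait = trt, effect = "gw",
        slope = inflation_slope(d$whole_ggw[ok] - d$whole_g[ok],
                                d$pred_ggw[ok] - d$pred_g[ok])))
    }
    out
  })

  nbar <- mean(corrected$n_reps)
  mpa <- purrr::map_dfr(types, function(ty) {
    h2f <- family_h2(whole_fit, nbar, ty)
    dplyr::mutate(h2f, type = ty, n_reps = nbar,
                  max_pa = max_pa(nbar, .data$h2f))
  })

  structure(list(
    scheme = scheme, spec = spec, ta_trait = ta_trait,
    cells = cells, pa = pa, bwp = bwp, max_pa = mpa,
    folds = plan[c("fold", "unit")], seed = seed,
    whole_fit = whole_fit
  ), class = "gddrn_cv")
}

# family-mean heritability feeding the maximum-PA bound: genomic signal
# (additive, plus reaction-norm interaction for g+gw predictions) over the
# variance of a line's corrected mean given n replicates per year-location
family_h2 <- function(fit, n_reps, type) {
  tr <- length(fit$traits)
  v <- function(ef, j) {
    nm <- if (tr == 1) ef else paste0(ef, ".v", j, j)
    if (nm %in% fit$vc$component) fit$vc$estimate[fit$vc$component == nm] else 0
  }
  purrr::map_dfr(seq_len(tr), function(j) {
    gen <- fit$mean_diag_G * v("g", j)
    if (type == "g+gw") gen <- gen + v("gw", j)
    noise <- v("l", j) + v("f", j) + (v("s", j) + v("e", j)) / n_reps
    tibble::tibble(trait = fit$traits[j], h2f = gen / (gen + noise))
  })
}

#' @export
tidy.gddrn_cv <- function(x, ...) x$pa

#' @export
glance.gddrn_cv <- function(x, ...) {
  tibble::tibble(model = x$spec$model, scheme = x$scheme,
                 ta_trait = x$ta_trait %||% NA_character_,
                 n_folds = nrow(x$folds), n_cells = nrow(x$cells),
                 seed = x$seed)
}

#' @export
print.gddrn_cv <- function(x, ...) {
  cat(sprintf("%s %s cross-validation (%d folds%s)\n", x$spec$model,
              toupper(x$scheme), nrow(x$folds),
              if (!is.null(x$ta_trait)) paste0(", trait-assisted for ", x$ta_trait)
              else ""))
  print(x$pa)
  invisible(x)
}
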