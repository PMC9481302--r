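#' Plot-level heritabilities from a fitted model
#'
#' Narrow-sense heritability is `h2 = d(G) * sigma2_g / sigma2_P` and
#' broad-sense `H2 = (sigma2_l + d(G) * sigma2_g) / sigma2_P`, where `d(G)`
#' is the mean diagonal of the genomic relationship matrix (one plus the
#' average genomic inbreeding) and the plot-level phenotypic variance is
#' `sigma2_P = sigma2_l + d(G) * sigma2_g + sigma2_f + sigma2_s + sigma2_e`.
#' Both are computed per retained draw and then summarized, so the posterior
#' standard deviations are exact functions of the chain.
#'
#' @param fit A `gddrn_fit` from a model containing both `l` and `g`.
#' @param d_g Mean diagonal of `G`; defaults to the value recorded at design
#'   time.
#' @return A tibble with one row per trait and statistic (`h2`, `H2`,
#'   `sigma2_P`): posterior mean and posterior SD.
#' @export
heritability <- function(fit, d_g = NULL) {
  stopifnot(inherits(fit, "gddrn_fit"))
  d_g <- d_g %||% fit$mean_diag_G
  if (is.null(fit$vc_draws)) abort("fit was run with keep_draws = FALSE")
  draws <- fit$vc_draws
  tr <- length(fit$traits)

  get <- function(effect, trait_idx) {
    nm <- if (tr == 1) effect else paste0(effect, ".v", trait_idx, trait_idx)
    if (!nm %in% colnames(draws)) {
      abort(sprintf("model has no '%s' effect: heritability needs l and g", effect))
    }
    draws[, nm]
  }

  purrr::map_dfr(seq_len(tr), function(j) {
    l <- get("l", j); g <- get("g", j); f <- get("f", j)
    s <- get("s", j); e <- get("e", j)
    sp <- l + d_g * g + f + s + e
    h2 <- d_g * g / sp
    H2 <- (l + d_g * g) / sp
    tibble::tibble(
      trait = fit$traits[j],
      statistic = c("h2", "H2", "sigma2_P"),
      estimate = c(mean(h2), mean(H2), mean(sp)),
      psd = c(stats::sd(h2), stats::sd(H2), stats::sd(sp))
    )
  })
}

#' Between-trait correlations of a bivariate fit
#'
#' For every random term (and the residual) of a bivariate model the
#' between-trait correlation `cov12 / sqrt(v1 * v2)` is computed per retained
#' draw and summarized. Draws with a zero variance are skipped and counted.
#'
#' @param fit A bivariate `gddrn_fit` (M4 or M5).
#' @return A tibble with per-effect posterior mean, posterior SD, central 95%
#'   credible bounds and the number of skipped draws.
#' @export
trait_correlations <- function(fit) {
  stopifnot(inherits(fit, "gddrn_fit"))
  if (length(fit$traits) != 2) abort("trait correlations need a bivariate fit")
  if (is.null(fit$vc_draws)) abort("fit was run with keep_draws = FALSE")
  draws <- fit$vc_draws
  effects <- unique(sub("\\.v[0-9]+$", "", colnames(draws)))

  purrr::map_dfr(effects, function(ef) {
    v1 <- draws[, paste0(ef, ".v11")]
    v12 <- draws[, paste0(ef, ".v12")]
    v2 <- draws[, paste0(ef, ".v22")]
    ok <- v1 > 0 & v2 > 0
    r <- v12[ok] / sqrt(v1[ok] * v2[ok])
    tibble::tibble(
      effect = ef, estimate = mean(r), psd = stats::sd(r),
      conf.low = unname(stats::quantile(r, 0.025)),
      conf.high = unname(stats::quantile(r, 0.975)),
      skipped = sum(!ok)
    )
  })
}

#' Chain diagnostics: effective sample size and Monte Carlo error
#'
#' The effective sample size uses Geyer's initial-positive-sequence estimator
#' on the chain autocorrelations; the Monte Carlo standard error of each
#' posterior mean is `sd / sqrt(ESS)`. Constant chains have undefined ESS and
#' are flagged.
#'
#' @param fit A `gddrn_fit`, or a numeric matrix of draws.
#' @param mcse_threshold Parameters with Monte Carlo error above this are
#'   flagged (default `Inf`).
#' @return A tibble: parameter, posterior mean and SD, `ess`, `mcse`, `flag`.
#' @export
mcmc_diagnostics <- function(fit, mcse_threshold = Inf) {
  draws <- if (inherits(fit, "gddrn_fit")) fit$vc_draws else as.matrix(fit)
  if (is.null(draws)) abort("no draws stored")
  if (nrow(draws) < 50) abort("need at least 50 retained draws for diagnostics")
  purrr::map_dfr(colnames(draws) %||% as.character(seq_len(ncol(draws))),
                 function(nm) {
    x <- draws[, nm]
    ess <- ess_ipse(x)
    mcse <- if (is.na(ess)) NA_real_ else stats::sd(x) / sqrt(ess)
    tibble::tibble(parameter = nm, mean = mean(x), sd = stats::sd(x),
                   ess = ess, mcse = mcse,
                   flag = is.na(mcse) || mcse > mcse_threshold)
  })
}

# Geyer initial positive sequence ESS
ess_ipse <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1, 2000),
                               plot = FALSE)$acf)
  m <- floor((length(rho) - 1) / 2)
  tau <- -1
  for (k in 0:m) {
    gamma_k <- rho[2 * k + 1] + rho[2 * k + 2]
    if (is.na(gamma_k) || gamma_k <= 0) break
    tau <- tau + 2 * gamma_k
  }
  n / max(tau, 1e-12)
}

#' @export
tidy.gddrn_fit <- function(x, ...) {
  out <- x$vc
  if (!is.null(x$vc_draws)) {
    ci <- apply(x$vc_draws, 2, stats::quantile, probs = c(0.025, 0.975))
    out$conf.low <- ci[1, out$component]
    out$conf.high <- ci[2, out$component]
  }
  out
}

#' @export
glance.gddrn_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model, traits = paste(x$traits, collapse = "+"),
    n_obs = x$n, n_missing = x$n_missing,
    retained = x$chain$retained, iters = x$chain$iters,
    burn_in = x$chain$burn_in, thin = x$chain$thin,
    seed = x$chain$seed %||% NA_integer_
  )
}

#' Posterior-mean genetic predictions
#'
#' Extracts the posterior means of the genomic additive effect per line
#' (`g`), optionally adding the reaction-norm interaction (`gw`) aggregated
#' to (line, environment) cells, which is the prediction the validation
#' protocol correlates with corrected line means.
#'
#' @param fit A `gddrn_fit` containing a `g` effect.
#' @param type `"g"` for the additive effect alone, `"g+gw"` to add the
#'   interaction.
#' @return A tibble: `line_id`, `env_id` (`NA` for `type = "g"`), `trait`,
#'   `pred`.
#' @export
genetic_predictions <- function(fit, type = c("g", "g+gw")) {
  type <- match.arg(type)
  if (!"g" %in% names(fit$effects)) abort("fit has no genomic effect")
  g <- fit$effects$g
  gl <- tibble::tibble(line_id = rep(rownames(g), ncol(g)),
                       trait = rep(colnames(g), each = nrow(g)),
                       g_hat = as.numeric(g))
  if (type == "g") {
    return(dplyr::mutate(gl, env_id = NA_character_, pred = .data$g_hat)[
      c("line_id", "env_id", "trait", "pred")])
  }
  if (!"gw" %in% names(fit$effects)) abort("fit has no gw effect")
  gw <- fit$effects$gw
  gw_long <- tibble::tibble(obs_id = rep(rownames(gw), ncol(gw)),
                            trait = rep(colnames(gw), each = nrow(gw)),
                            gw_hat = as.numeric(gw)) |>
    dplyr::inner_join(fit$obs, by = "obs_id") |>
    dplyr::group_by(.data$line_id, .data$env_id, .data$trait) |>
    dplyr::summarise(gw_hat = mean(.data$gw_hat), .groups = "drop")
  dplyr::inner_join(gw_long, gl, by = c("line_id", "trait")) |>
    dplyr::mutate(pred = .data$g_hat + .data$gw_hat) |>
    dplyr::select("line_id", "env_id", "trait", "pred")
}
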