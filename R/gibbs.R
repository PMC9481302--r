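#' Fit a reaction-norm mixed model by Gibbs sampling
#'
#' All random effects are Gaussian with known covariance kernels up to their
#' variance parameters. Each effect is reparameterized once into a basis in
#' which both its prior and its information matrix are diagonal: kernel
#' effects through the (truncated) eigendecomposition of the kernel followed
#' by a rotation that diagonalizes the design cross-product, incidence
#' effects directly (their cross-product is already diagonal). Full
#' conditionals are then independent univariate (single-trait) or 2 x 2
#' (bivariate) normals and are sampled in vectorized form. Variances use
#' scaled-inverse-chi-squared full conditionals; bivariate trait covariance
#' matrices use inverse-Wishart. Fixed effects carry flat priors. Missing
#' trait values (including deliberately masked validation cells and
#' trait-assisted masking) are handled by residual data augmentation, which
#' is what allows prediction for unphenotyped lines and trait-assisted
#' prediction.
#'
#' Prior scales follow the usual proportion-of-variance partition: each
#' random term's prior scale references an equal share of `r2 * var(y)`
#' (divided by the mean diagonal of its observation-level kernel), the
#' residual references `(1 - r2) * var(y)`. The scales carry only `df0`
#' prior degrees of freedom, so with the default `df0 = 0.0001` the priors
#' are effectively flat and the partition matters only for initialization.
#'
#' @param design A [build_design()] result.
#' @param iters,burn_in,thin,seed Chain controls; defaults come from the
#'   design's [model_spec()]. Retained draws are
#'   `(iters - burn_in) / thin`.
#' @param keep_draws Retain the variance-component draws matrix (default
#'   `TRUE`; needed for diagnostics, heritability and credible intervals).
#' @param blocks Precomputed effect blocks from [precompute_blocks()]. The
#'   expensive one-time eigendecompositions depend only on the kernels and
#'   incidences, not on the phenotypes, so they can be reused across refits
#'   of the same design with different masking (as [run_cv()] does).
#' @return A `gddrn_fit` with posterior summaries of variance components,
#'   posterior-mean genetic (`g`, per line) and reaction-norm (`gw`, per
#'   observation) predictions, posterior-mean fixed fitted values, and the
#'   retained draws.
#' @export
fit_gibbs <- function(design, iters = NULL, burn_in = NULL, thin = NULL,
                      seed = NULL, keep_draws = TRUE, blocks = NULL) {
  stopifnot(inherits(design, "gddrn_design"))
  spec <- design$spec
  iters <- iters %||% spec$iters
  burn_in <- burn_in %||% spec$burn_in
  thin <- thin %||% spec$thin
  if (!is.null(seed)) set.seed(seed)

  Y <- design$Y
  n <- nrow(Y)
  tr <- ncol(Y)
  mask <- is.na(Y)
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  for (j in seq_len(tr)) Y[mask[, j], j] <- mean(Y[, j], na.rm = TRUE)

  X <- design$X
  p <- ncol(X)
  XtX <- crossprod(X)
  XtXinv <- chol2inv(chol(XtX))
  tcholXtXinv <- t(chol(XtXinv))

  blocks <- blocks %||% precompute_blocks(design)
  if (!identical(names(blocks), names(design$effects))) {
    abort("blocks do not match the design's effects")
  }
  nk <- length(blocks)

  # prior scale partition
  r2 <- spec$r2
  df0 <- spec$df0
  modes <- lapply(blocks, function(b) r2 * vy / (nk * b$mdiag))
  mode_e <- (1 - r2) * vy
  # The prior scale equals the partition share itself. With df0 near zero
  # this leaves a proper prior whose density vanishes exponentially below
  # about half the share (no degenerate mass at zero, unlike a pure
  # Jeffreys limit) while adding only share/r to a posterior mean --
  # weakly informative in both directions. Matching the prior MODE to the
  # share instead (scale times df0+2, resp. nu0+t+1) multiplies that
  # repulsion several-fold and visibly inflates small variance components
  # in small designs.
  if (tr == 1) {
    S0 <- modes
    S0e <- mode_e
  } else {
    nu0 <- tr + df0
    S0 <- lapply(modes, function(m) diag(m, tr))
    S0e <- diag(mode_e, tr)
  }

  # state
  B <- matrix(0, p, tr)
  gam <- lapply(blocks, function(b) matrix(0, b$r, tr))
  Sig <- lapply(modes, function(m) diag(m, tr))
  R <- diag(mode_e, tr)
  E <- Y - X %*% B

  retained <- (iters - burn_in) %/% thin
  if (retained < 1) abort("chain settings retain no draws")
  vc_names <- unlist(lapply(c(names(blocks), "e"), function(nm) {
    if (tr == 1) nm else paste(nm, c("v11", "v12", "v22"), sep = ".")
  }))
  vc_draws <- matrix(NA_real_, retained, length(vc_names),
                     dimnames = list(NULL, vc_names))
  gam_sum <- lapply(blocks, function(b) matrix(0, b$r, tr))
  B_sum <- matrix(0, p, tr)
  kept <- 0L

  for (it in seq_len(iters)) {
    # fixed effects (flat prior): matrix-normal conditional
    Mx <- crossprod(X, E) + XtX %*% B
    Bhat <- XtXinv %*% Mx
    Bnew <- Bhat + tcholXtXinv %*% matrix(rnorm(p * tr), p, tr) %*% chol(R)
    E <- E - X %*% (Bnew - B)
    B <- Bnew

    # random effects, one diagonalized block at a time
    for (k in seq_len(nk)) {
      b <- blocks[[k]]
      Mk <- as.matrix(crossprod(b$T, E)) + gam[[k]] * b$lambda
      if (tr == 1) {
        v <- 1 / (b$lambda / R[1, 1] + 1 / Sig[[k]][1, 1])
        gnew <- matrix(v * Mk[, 1] / R[1, 1] + sqrt(v) * rnorm(b$r), ncol = 1)
      } else {
        gnew <- sample_bivariate(Mk, b$lambda, R, Sig[[k]])
      }
      E <- E - as.matrix(b$T %*% (gnew - gam[[k]]))
      gam[[k]] <- gnew
    }

    # variance components
    if (tr == 1) {
      for (k in seq_len(nk)) {
        Sig[[k]][1, 1] <- (S0[[k]] + sum(gam[[k]]^2)) /
          rchisq(1, df0 + blocks[[k]]$r)
      }
      R[1, 1] <- (S0e + sum(E^2)) / rchisq(1, df0 + n)
    } else {
      for (k in seq_len(nk)) {
        Sk <- S0[[k]] + crossprod(gam[[k]])
        Sig[[k]] <- riwish(nu0 + blocks[[k]]$r, Sk)
      }
      R <- riwish(nu0 + n, S0e + crossprod(E))
    }

    # residual data augmentation for missing / masked trait records
    if (any(mask)) {
      fitted <- Y - E
      if (tr == 1) {
        e <- rnorm(sum(mask[, 1]), 0, sqrt(R[1, 1]))
        Y[mask[, 1], 1] <- fitted[mask[, 1], 1] + e
        E[mask[, 1], 1] <- e
      } else {
        both <- mask[, 1] & mask[, 2]
        if (any(both)) {
          L <- chol(R)
          e <- matrix(rnorm(2 * sum(both)), ncol = 2) %*% L
          Y[both, ] <- fitted[both, ] + e
          E[both, ] <- e
        }
        for (j in 1:2) {
          o <- 3 - j
          only <- mask[, j] & !mask[, o]
          if (any(only)) {
            cm <- R[j, o] / R[o, o] * E[only, o]
            cv <- R[j, j] - R[j, o]^2 / R[o, o]
            e <- cm + sqrt(cv) * rnorm(sum(only))
            Y[only, j] <- fitted[only, j] + e
            E[only, j] <- e
          }
        }
      }
    }

    if (!all(is.finite(E))) {
      abort(sprintf("divergent chain: non-finite draw at iteration %d", it))
    }

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      row <- unlist(c(
        lapply(Sig, function(S) if (tr == 1) S[1, 1] else S[c(1, 2, 4)]),
        list(if (tr == 1) R[1, 1] else R[c(1, 2, 4)])
      ))
      vc_draws[kept, ] <- row
      for (k in seq_len(nk)) gam_sum[[k]] <- gam_sum[[k]] + gam[[k]]
      B_sum <- B_sum + B
    }
  }

  finalize_fit(design, blocks, vc_draws, gam_sum, B_sum, kept,
               list(iters = iters, burn_in = burn_in, thin = thin,
                    seed = seed),
               keep_draws)
}

#' Precompute the diagonalized effect blocks of a design
#'
#' Performs the one-time eigendecompositions and rotations that put every
#' random effect of a design into a basis with diagonal prior and diagonal
#' information matrix. The result depends only on the design structure and
#' kernels -- not on the phenotype values -- so it can be shared across
#' refits of the same observations with different masking patterns.
#'
#' @param design A [build_design()] result.
#' @return A list of prepared blocks for [fit_gibbs()].
#' @export
precompute_blocks <- function(design) {
  lapply(design$effects, prep_block)
}

# one-time diagonalizing preparation of an effect block
prep_block <- function(ef) {
  tol <- 1e-10
  if (ef$type == "iid") {
    Z <- ef$Z
    list(name = ef$name, type = ef$type, T = Z,
         lambda = Matrix::colSums(Z), r = ncol(Z),
         levels = colnames(Z), mdiag = 1, map = NULL)
  } else if (ef$type == "obs_kernel") {
    check_psd(ef$K, ef$name)
    eg <- eigen(ef$K, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
      abort(sprintf("kernel '%s' is not positive semidefinite", ef$name))
    }
    keep <- eg$values > tol * max(eg$values)
    Tm <- eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(eg$values[keep]), sum(keep))
    rownames(Tm) <- rownames(ef$K)
    list(name = ef$name, type = ef$type, T = Tm,
         lambda = eg$values[keep], r = sum(keep),
         levels = rownames(ef$K), mdiag = mean(diag(ef$K)), map = NULL)
  } else { # line_kernel
    check_psd(ef$K, ef$name)
    eg <- eigen(ef$K, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
      abort(sprintf("kernel '%s' is not positive semidefinite", ef$name))
    }
    keep <- eg$values > tol * max(eg$values)
    UD <- eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(eg$values[keep]), sum(keep))
    T0 <- as.matrix(ef$Z %*% UD)
    C <- crossprod(T0)
    e2 <- eigen(C, symmetric = TRUE)
    V <- e2$vectors
    Tm <- T0 %*% V
    list(name = ef$name, type = ef$type, T = Tm,
         lambda = pmax(e2$values, 0), r = ncol(Tm),
         levels = rownames(ef$K),
         mdiag = mean(as.numeric(ef$Z %*% diag(ef$K))),
         map = UD %*% V)
  }
}

check_psd <- function(K, name) {
  # cheap necessary checks; the eigendecomposition right after is the real one
  if (any(abs(K - t(K)) > 1e-8 * max(abs(K)))) {
    abort(sprintf("kernel '%s' is not symmetric", name))
  }
  invisible(TRUE)
}

# vectorized 2x2 multivariate-normal full conditionals for all rows of a
# bivariate effect: precision_j = lambda_j * R^-1 + Sigma^-1
sample_bivariate <- function(M, lambda, R, Sigma) {
  Rinv <- chol2inv(chol(R))
  Sinv <- chol2inv(chol(Sigma))
  P11 <- lambda * Rinv[1, 1] + Sinv[1, 1]
  P12 <- lambda * Rinv[1, 2] + Sinv[1, 2]
  P22 <- lambda * Rinv[2, 2] + Sinv[2, 2]
  det <- P11 * P22 - P12^2
  c11 <- P22 / det
  c12 <- -P12 / det
  c22 <- P11 / det
  rhs1 <- M[, 1] * Rinv[1, 1] + M[, 2] * Rinv[2, 1]
  rhs2 <- M[, 1] * Rinv[1, 2] + M[, 2] * Rinv[2, 2]
  mu1 <- c11 * rhs1 + c12 * rhs2
  mu2 <- c12 * rhs1 + c22 * rhs2
  l11 <- sqrt(c11)
  l21 <- c12 / l11
  l22 <- sqrt(pmax(c22 - l21^2, 0))
  z1 <- rnorm(length(lambda))
  z2 <- rnorm(length(lambda))
  cbind(mu1 + l11 * z1, mu2 + l21 * z1 + l22 * z2)
}

riwish <- function(df, S) {
  solve(rWishart(1, df, solve(S))[, , 1])
}

finalize_fit <- function(design, blocks, vc_draws, gam_sum, B_sum, kept,
                         chain, keep_draws) {
  spec <- design$spec
  tr <- length(spec$traits)
  vc_draws <- vc_draws[seq_len(kept), , drop = FALSE]

  # posterior means of effect vectors (linear in the draws)
  effects_hat <- list()
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    gbar <- gam_sum[[k]] / kept
    u <- switch(b$type,
      iid = as.matrix(gbar),
      obs_kernel = b$T %*% gbar,
      line_kernel = b$map %*% gbar
    )
    rownames(u) <- b$levels
    colnames(u) <- spec$traits
    effects_hat[[b$name]] <- u
  }
  fixed_fitted <- design$X %*% (B_sum / kept)
  colnames(fixed_fitted) <- spec$traits

  vc_mean <- colMeans(vc_draws)
  vc_sd <- apply(vc_draws, 2, stats::sd)

  structure(list(
    spec = spec, traits = spec$traits, obs = design$obs,
    n = nrow(design$Y), n_missing = sum(is.na(design$Y)),
    vc = tibble::tibble(component = colnames(vc_draws),
                        estimate = unname(vc_mean), psd = unname(vc_sd)),
    vc_draws = if (keep_draws) vc_draws else NULL,
    effects = effects_hat,
    fixed_fitted = fixed_fitted,
    mean_diag_G = design$mean_diag_G,
    chain = c(chain, retained = kept)
  ), class = "gddrn_fit")
}

#' @export
print.gddrn_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): %d observations, %d retained draws\n",
              x$spec$model, paste(x$traits, collapse = " + "),
              x$n, x$chain$retained))
  print(x$vc, n = nrow(x$vc))
  invisible(x)
}
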