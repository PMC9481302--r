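model_effects <- list(
  M1 = c("l", "f", "s"),
  M2 = c("l", "f", "s", "g"),
  M3 = c("l", "f", "s", "g", "gw"),
  M4 = c("l", "f", "s", "g"),
  M5 = c("l", "f", "s", "g", "gw")
)

#' Declare one of the five reaction-norm mixed models
#'
#' The model ladder shared by the fitting and validation machinery:
#' * **M1** (baseline): fixed trial effects plus random line (`l`),
#'   line-by-environment (`f`) and nine-neighbour spatial (`s`) effects;
#' * **M2**: M1 plus the genomic additive effect (`g`) with the genomic
#'   relationship matrix as covariance (G-BLUP);
#' * **M3**: M2 plus the genomic-by-environmental-covariate reaction-norm
#'   effect (`gw`) with the Hadamard kernel;
#' * **M4 / M5**: bivariate versions of M2 / M3 in which every random term
#'   carries an unstructured 2 x 2 between-trait covariance (Kronecker
#'   structure) and the residual is correlated across traits.
#'
#' @param model One of `"M1"`..`"M5"`.
#' @param traits Character vector of trait column names: one for M1-M3, two
#'   for M4-M5.
#' @param iters,burn_in,thin Chain length, burn-in and thinning. The defaults
#'   (5,000 / 1,000 / 5) are a desk-scale chain; production analyses use
#'   longer chains (e.g. 50,000 / 10,000 / 10).
#' @param r2 Proportion of phenotypic variance the random terms are expected
#'   to capture; drives the prior scale partition (default 0.90).
#' @param df0 Prior degrees of freedom; the default 0.0001 makes the
#'   scaled-inverse-chi-squared / inverse-Wishart priors effectively flat.
#' @return A `gddrn_spec` list.
#' @export
model_spec <- function(model = c("M1", "M2", "M3", "M4", "M5"), traits,
                       iters = 5000, burn_in = 1000, thin = 5,
                       r2 = 0.90, df0 = 1e-4) {
  model <- match.arg(model)
  n_tr <- if (model %in% c("M4", "M5")) 2L else 1L
  if (length(traits) != n_tr) {
    abort(sprintf("%s is a %s model: supply %d trait(s)", model,
                  if (n_tr == 1) "single-trait" else "bivariate", n_tr))
  }
  if (burn_in >= iters) abort("burn_in must be smaller than iters")
  structure(list(model = model, traits = traits,
                 effects = model_effects[[model]],
                 iters = as.integer(iters), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), r2 = r2, df0 = df0),
            class = "gddrn_spec")
}

#' Assemble phenotypes, design matrices and kernels for fitting
#'
#' Resolves every observation to its line, trial, environment and spatial
#' row; builds the fixed trial design (trials nested within year-location,
#' reference level dropped lexicographically) and the random-effect
#' incidences and kernels the declared model needs. Missing trait values are
#' allowed and later handled by data augmentation.
#'
#' @param phenos Data frame with `obs_id`, `line_id`, `env_id`, optionally
#'   `trial`, and the trait column(s) named in `spec`.
#' @param layout Field layout of the real plots (see [add_virtual_plots()]);
#'   required for the spatial effect.
#' @param spec A [model_spec()].
#' @param G Genomic relationship matrix over lines (models M2-M5).
#' @param omega Observation-level environmental kernel (models M3/M5).
#' @return A `gddrn_design` list with the response matrix, fixed design,
#'   and one block per random effect.
#' @export
build_design <- function(phenos, layout, spec, G = NULL, omega = NULL) {
  stopifnot(inherits(spec, "gddrn_spec"))
  phenos <- tibble::as_tibble(phenos)
  need <- c("obs_id", "line_id", "env_id", spec$traits)
  if (!all(need %in% names(phenos))) {
    abort(sprintf("phenos lacks columns: %s",
                  paste(setdiff(need, names(phenos)), collapse = ", ")))
  }
  if (!"trial" %in% names(phenos)) phenos$trial <- "t1"
  phenos$obs_id <- as.character(phenos$obs_id)
  n <- nrow(phenos)

  Y <- as.matrix(phenos[spec$traits])
  rownames(Y) <- phenos$obs_id

  # fixed trial effects nested within year-location; lexicographic reference
  tf <- factor(paste(phenos$env_id, phenos$trial, sep = "/"))
  X <- stats::model.matrix(~tf)
  colnames(X) <- sub("^tf", "trial:", colnames(X))
  if (qr(X)$rank < ncol(X)) abort("fixed-effect design is rank deficient")

  effects <- list()
  for (ef in spec$effects) {
    effects[[ef]] <- switch(ef,
      l = {
        levels <- if (!is.null(G)) rownames(G) else sort(unique(phenos$line_id))
        unknown <- setdiff(phenos$line_id, levels)
        if (length(unknown) > 0) {
          abort(sprintf("observations reference lines absent from G: %s",
                        paste(unknown[seq_len(min(5, length(unknown)))], collapse = ", ")))
        }
        list(name = "l", type = "iid", Z = incidence(phenos$line_id, levels))
      },
      f = {
        lv <- sort(unique(paste(phenos$line_id, phenos$env_id, sep = "@")))
        list(name = "f", type = "iid",
             Z = incidence(paste(phenos$line_id, phenos$env_id, sep = "@"), lv))
      },
      s = {
        if (is.null(layout)) abort("layout required for the spatial effect")
        S <- build_spatial_matrix(layout)
        missing_obs <- setdiff(phenos$obs_id, rownames(S))
        if (length(missing_obs) > 0) {
          abort(sprintf("observations lack layout coordinates: %s",
                        paste(missing_obs[seq_len(min(5, length(missing_obs)))],
                              collapse = ", ")))
        }
        S <- as.matrix(S[phenos$obs_id, phenos$obs_id])
        list(name = "s", type = "obs_kernel", K = S)
      },
      g = {
        if (is.null(G)) abort(sprintf("%s requires the genomic relationship matrix G",
                                      spec$model))
        unknown <- setdiff(phenos$line_id, rownames(G))
        if (length(unknown) > 0) {
          abort(sprintf("observations reference lines absent from G: %s",
                        paste(unknown[seq_len(min(5, length(unknown)))], collapse = ", ")))
        }
        list(name = "g", type = "line_kernel", K = G,
             Z = incidence(phenos$line_id, rownames(G)))
      },
      gw = {
        if (is.null(G) || is.null(omega)) {
          abort(sprintf("%s requires both G and omega", spec$model))
        }
        missing_obs <- setdiff(phenos$obs_id, rownames(omega))
        if (length(missing_obs) > 0) {
          abort(sprintf("observations absent from omega: %s",
                        paste(missing_obs[seq_len(min(5, length(missing_obs)))],
                              collapse = ", ")))
        }
        om <- omega[phenos$obs_id, phenos$obs_id]
        GW <- build_gw_kernel(G, om, phenos[c("obs_id", "line_id")])
        list(name = "gw", type = "obs_kernel", K = GW)
      }
    )
  }

  structure(list(
    Y = Y, X = X, effects = effects, spec = spec,
    obs = phenos[c("obs_id", "line_id", "env_id", "trial")],
    mean_diag_G = if (!is.null(G)) mean(diag(G)) else NA_real_
  ), class = "gddrn_design")
}

incidence <- function(values, levels) {
  j <- match(values, levels)
  Matrix::sparseMatrix(i = seq_along(values), j = j, x = 1,
                       dims = c(length(values), length(levels)),
                       dimnames = list(NULL, levels))
}
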