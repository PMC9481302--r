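#' Complete a field layout with virtual border plots
#'
#' Every real plot must be surrounded by its eight Chebyshev neighbours
#' (the 3 x 3 square around it) for the nine-neighbour spatial model. Virtual
#' plots carrying no observation are added on trial borders and in empty
#' cells of the X-Y grid wherever a neighbour is missing. Spatial-effect ids
#' are scoped per environment: plots in different year-locations never share
#' a square.
#'
#' @param layout Data frame of real plots with columns `obs_id`, `env_id`,
#'   `x`, `y` (integer grid coordinates) and optionally `trial`, `block`,
#'   `line_id`.
#' @return The layout extended with virtual rows (`is_virtual = TRUE`,
#'   `obs_id = NA`) and a `spat_id` column identifying each (env, x, y)
#'   square.
#' @export
add_virtual_plots <- function(layout) {
  layout <- tibble::as_tibble(layout)
  need <- c("obs_id", "env_id", "x", "y")
  if (!all(need %in% names(layout))) {
    abort("layout needs columns obs_id, env_id, x, y")
  }
  if (any(layout$x != round(layout$x) | layout$y != round(layout$y), na.rm = TRUE) ||
      anyNA(layout$x) || anyNA(layout$y)) {
    abort("plot coordinates must be non-missing integers")
  }
  if (anyDuplicated(layout[c("env_id", "x", "y")])) {
    abort("duplicated (env_id, x, y) plot coordinates")
  }
  layout$is_virtual <- FALSE

  off <- expand.grid(dx = -1:1, dy = -1:1)
  neigh <- layout |>
    dplyr::select("env_id", "x", "y") |>
    tidyr::expand_grid(off) |>
    dplyr::transmute(.data$env_id, x = .data$x + .data$dx, y = .data$y + .data$dy) |>
    dplyr::distinct()
  virt <- dplyr::anti_join(neigh, layout, by = c("env_id", "x", "y"))
  if (nrow(virt) > 0) {
    virt$obs_id <- NA_character_
    virt$is_virtual <- TRUE
    layout <- dplyr::bind_rows(layout, virt)
  }
  layout |>
    dplyr::mutate(spat_id = paste(.data$env_id, .data$x, .data$y, sep = ":")) |>
    dplyr::arrange(.data$env_id, .data$x, .data$y)
}

#' Nine-neighbour spatial incidence matrix
#'
#' Indicator matrix relating each real-plot observation to the spatial
#' effects of the square centred on it and of the eight surrounding squares;
#' every row has exactly nine ones. The layout must have been completed by
#' [add_virtual_plots()].
#'
#' @param layout Completed layout with `spat_id` and `is_virtual` columns.
#' @return A sparse indicator matrix (observations x real-plus-virtual
#'   squares) with `obs_id` rownames and `spat_id` colnames.
#' @export
spatial_incidence <- function(layout) {
  if (!all(c("spat_id", "is_virtual") %in% names(layout))) {
    abort("layout must be completed by add_virtual_plots() first")
  }
  real <- layout[!layout$is_virtual, ]
  if (nrow(real) == 0) abort("layout has no real plots")
  if (anyNA(real$obs_id)) abort("real plots must carry obs_id")

  ids <- layout$spat_id
  lookup <- setNames(seq_along(ids), ids)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  rows <- rep(seq_len(nrow(real)), each = 9L)
  keys <- paste(rep(real$env_id, each = 9L),
                rep(real$x, each = 9L) + rep(off$dx, nrow(real)),
                rep(real$y, each = 9L) + rep(off$dy, nrow(real)), sep = ":")
  cols <- lookup[keys]
  if (anyNA(cols)) abort("layout is missing neighbour squares; run add_virtual_plots()")
  X <- Matrix::sparseMatrix(i = rows, j = unname(cols), x = 1,
                            dims = c(nrow(real), length(ids)),
                            dimnames = list(real$obs_id, ids))
  X
}

#' Spatial relationship matrix
#'
#' `S = X X' / (tr(X X') / n)` for the nine-neighbour incidence `X`: the
#' proportion of 3 x 3 squares two plots share. Each row of `X` holds nine
#' ones, so the scaling constant is 9, every diagonal entry is 1 and
#' `trace(S) = n`. Entries lie in `{0, 1/9, ..., 6/9, 1}` and plots in
#' different environments are unrelated.
#'
#' @param layout Completed layout (see [add_virtual_plots()]); a raw layout
#'   of real plots is completed automatically.
#' @return A symmetric sparse matrix over observations with unit diagonal.
#' @export
build_spatial_matrix <- function(layout) {
  if (!"spat_id" %in% names(layout)) layout <- add_virtual_plots(layout)
  X <- spatial_incidence(layout)
  n <- nrow(X)
  S <- Matrix::tcrossprod(X)
  S / (sum(Matrix::diag(S)) / n)
}
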