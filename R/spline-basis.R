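#' Natural cubic spline basis definition for soil moisture
#'
#' Fixes the knots of the environmental spline term from the observed
#' moisture values of the dataset being fitted: boundary knots at the
#' observed min/max and, for `df = 2`, one interior knot at the median
#' (generally, interior knots at equally spaced quantiles). The definition is
#' frozen into fitted models so that later evaluation on a prediction grid
#' (including values beyond the boundary knots, where the natural spline
#' extrapolates linearly) uses the knots of the fit.
#'
#' @param x Observed soil-moisture values (% gravimetric).
#' @param df Spline degrees of freedom (default 2: one interior knot).
#' @return An object of class `spline_basis_def` with fields `df`,
#'   `boundary_knots`, `interior_knots`.
#' @export
spline_basis_def <- function(x, df = 2) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct moisture values to place spline knots")
  }
  if (df < 1) stop("`df` must be >= 1")
  boundary <- range(x)
  probs <- seq(0, 1, length.out = df + 1L)[-c(1L, df + 1L)]
  interior <- unname(stats::quantile(x, probs, type = 7, names = FALSE))
  if (any(interior <= boundary[1] | interior >= boundary[2])) {
    stop("interior knots must fall strictly inside the boundary knots")
  }
  structure(list(df = as.integer(df), boundary_knots = boundary,
                 interior_knots = interior),
            class = "spline_basis_def")
}

#' Evaluate the natural cubic spline basis
#'
#' Returns `df` basis columns which, together with an intercept, span the
#' natural cubic splines on the definition's knots: piecewise cubic, C2
#' continuous, linear beyond the boundary knots.
#'
#' @param x Values at which to evaluate (any range; linear extrapolation
#'   beyond the boundary knots).
#' @param def A [spline_basis_def()].
#' @return Numeric matrix with `def$df` columns named `S1`, `S2`, ...
#' @export
natural_spline_basis <- function(x, def) {
  stopifnot(inherits(def, "spline_basis_def"))
  b <- splines::ns(x, knots = def$interior_knots,
                   Boundary.knots = def$boundary_knots)
  b <- unclass(b)[, , drop = FALSE]
  colnames(b) <- paste0("S", seq_len(ncol(b)))
  attributes(b)[setdiff(names(attributes(b)), c("dim", "dimnames"))] <- NULL
  b
}
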