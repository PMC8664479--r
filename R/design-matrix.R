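# Fixed-effects model terms for trait reaction norms. H = harvest cohort,
# G = genotype, E = final soil moisture, E2 = squared moisture, S = natural
# spline basis; interactions cross genotype contrasts with the environmental
# columns. The order below is the canonical enumeration order everywhere
# (candidate moves, tie-breaks, output tables).

FVT_TERMS <- c("H", "G", "E", "E2", "S", "G:E", "G:E2", "G:S")

TERM_DEPS <- list("G:E" = c("G", "E"), "G:E2" = c("G", "E2"),
                  "G:S" = c("G", "S"))

#' The full reaction-norm term set
#'
#' All eight candidate model terms, in canonical order: harvest cohort `H`,
#' genotype `G`, soil moisture `E`, squared moisture `E2`, natural-spline
#' basis `S`, and the genotype-by-environment interactions `G:E`, `G:E2`,
#' `G:S`. Interactions are marginal to `G` and to their own environmental
#' term (e.g. `G:E2` requires `G` and `E2`, but `E2` does not require `E`).
#'
#' @return Character vector of term labels.
#' @export
full_term_set <- function() FVT_TERMS

canonical_terms <- function(terms) intersect(FVT_TERMS, terms)

check_terms <- function(terms) {
  unknown <- setdiff(terms, FVT_TERMS)
  if (length(unknown)) {
    stop("unknown model terms: ", paste(unknown, collapse = ", "))
  }
  for (t in intersect(names(TERM_DEPS), terms)) {
    miss <- setdiff(TERM_DEPS[[t]], terms)
    if (length(miss)) {
      stop(sprintf("term %s requires %s (marginality)", t,
                   paste(miss, collapse = ", ")))
    }
  }
  invisible(canonical_terms(terms))
}

# 0/1 treatment-contrast columns against the (lexicographically first)
# reference level
contrast_cols <- function(f, prefix) {
  lev <- levels(f)
  if (length(lev) < 2) {
    return(matrix(numeric(0), length(f), 0))
  }
  cols <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(length(f)))
  colnames(cols) <- paste0(prefix, lev[-1])
  cols
}

#' Build the design matrix for a term set
#'
#' Constructs the fixed-effects design matrix for a trait model: an intercept
#' always, categorical terms (`H`, `G`) as treatment contrasts against the
#' lexicographically first level, environmental columns on the raw percent
#' scale, and interactions as column-wise products of genotype contrasts with
#' the environmental columns. Note that `E` lies in the span of the intercept
#' and the natural-spline columns, so designs containing both `E` and `S` are
#' intentionally rank-deficient; the fitting routine handles the aliasing.
#'
#' @param terms Character subset of [full_term_set()] (marginality enforced).
#' @param data Data frame with (as required by `terms`) columns `genotype`,
#'   `cohort`, `soil_moisture_final`.
#' @param basis A [spline_basis_def()]; required when `S` or `G:S` is in
#'   `terms`.
#' @param genotype_levels,cohort_levels Factor levels to use (defaults: sorted
#'   unique values in `data`); pass the training levels when building
#'   prediction designs.
#' @return List with `X` (the matrix), `term_of` (named map from column to
#'   term) and the levels used.
#' @export
build_design_matrix <- function(terms, data, basis = NULL,
                                genotype_levels = NULL, cohort_levels = NULL) {
  terms <- check_terms(terms)
  n <- nrow(data)
  need <- function(col, term) {
    if (is.null(data[[col]])) {
      stop(sprintf("term %s needs column '%s' in `data`", term, col))
    }
    data[[col]]
  }

  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  term_of <- c(`(Intercept)` = "(Intercept)")

  env_cols <- list()
  if (any(c("E", "E2", "S", "G:E", "G:E2", "G:S") %in% terms)) {
    m <- need("soil_moisture_final", "E")
    if (any(!is.finite(m))) stop("non-finite soil moisture in `data`")
    env_cols$E <- matrix(m, n, 1, dimnames = list(NULL, "E"))
    env_cols$E2 <- matrix(m^2, n, 1, dimnames = list(NULL, "E2"))
    if (any(c("S", "G:S") %in% terms)) {
      if (is.null(basis)) stop("term S requires a `basis` definition")
      env_cols$S <- natural_spline_basis(m, basis)
    }
  }

  gmat <- NULL
  if (any(c("G", "G:E", "G:E2", "G:S") %in% terms)) {
    g <- as.character(need("genotype", "G"))
    if (is.null(genotype_levels)) genotype_levels <- sort(unique(g))
    if (length(genotype_levels) < 2) {
      stop("term G requires at least 2 genotypes")
    }
    if (!all(g %in% genotype_levels)) {
      stop("genotype absent from training levels: ",
           paste(setdiff(unique(g), genotype_levels), collapse = ", "))
    }
    gmat <- contrast_cols(factor(g, levels = genotype_levels), "G:")
  }

  for (t in terms) {
    blocks[[t]] <- switch(t,
      H = {
        h <- as.character(need("cohort", "H"))
        if (is.null(cohort_levels)) {
          cohort_levels <- sort(unique(need("cohort", "H")))
        }
        contrast_cols(factor(h, levels = as.character(cohort_levels)), "H:")
      },
      G = gmat,
      E = env_cols$E,
      E2 = env_cols$E2,
      S = env_cols$S,
      `G:E` = interact_cols(gmat, env_cols$E),
      `G:E2` = interact_cols(gmat, env_cols$E2),
      `G:S` = interact_cols(gmat, env_cols$S)
    )
    term_of <- c(term_of,
                 stats::setNames(rep(t, ncol(blocks[[t]])),
                                 colnames(blocks[[t]])))
  }

  X <- do.call(cbind, blocks[c("(Intercept)", terms)])
  list(X = X, term_of = term_of, genotype_levels = genotype_levels,
       cohort_levels = cohort_levels)
}

interact_cols <- function(gmat, env) {
  out <- matrix(NA_real_, nrow(gmat), ncol(gmat) * ncol(env))
  nm <- character(ncol(out))
  k <- 0L
  for (j in seq_len(ncol(env))) {
    for (i in seq_len(ncol(gmat))) {
      k <- k + 1L
      out[, k] <- gmat[, i] * env[, j]
      nm[k] <- paste0(colnames(gmat)[i], ":", colnames(env)[j])
    }
  }
  colnames(out) <- nm
  out
}

#' Rank-aware least squares
#'
#' Ordinary least squares through a rank-revealing pivoted QR
#' ([stats::lm.fit()]). Exactly collinear columns are flagged as aliased and
#' assigned a zero coefficient so predictions remain well-defined; the model
#' rank (not the column count) is what enters the AIC penalty. A fit whose
#' residual sum of squares is zero to relative tolerance `1e-13 * sum(y^2)`
#' is flagged as a perfect fit.
#'
#' @param X Design matrix (including the intercept).
#' @param y Response vector.
#' @return List of class `fvt_lsfit`: `coefficients` (aliased set to 0),
#'   `aliased` (logical), `rank`, `rss`, `n`, `fitted`, `perfect_fit`.
#' @export
fit_least_squares <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in the design or response")
  }
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  coefs[aliased] <- 0
  n <- length(y)
  if (n <= fit$rank) {
    stop(sprintf("unidentifiable fit: n = %d <= rank = %d", n, fit$rank))
  }
  rss <- sum(fit$residuals^2)
  structure(list(coefficients = coefs, aliased = aliased, rank = fit$rank,
                 rss = rss, n = n, fitted = as.numeric(fit$fitted.values),
                 perfect_fit = rss <= 1e-13 * max(sum(y^2),
                                                  .Machine$double.xmin)),
            class = "fvt_lsfit")
}

#' AIC of a least-squares fit
#'
#' `AIC = n log(RSS/n) + 2 rank`, dropping the additive constant that is
#' identical across candidate models on the same data, so AIC differences
#' between candidates are unaffected. A perfect fit (RSS = 0 to tolerance)
#' returns `-Inf`; model selection then prefers the smaller-rank perfect fit.
#'
#' @param fit An [fit_least_squares()] result.
#' @return AIC value (possibly `-Inf`).
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "fvt_lsfit"))
  if (fit$perfect_fit) return(-Inf)
  fit$n * log(fit$rss / fit$n) + 2 * fit$rank
}
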