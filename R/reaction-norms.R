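#' Specify a genotype's reaction norm for one trait
#'
#' A reaction norm is the curve of expected phenotype across the soil-moisture
#' gradient for one genotype. Four generative shapes are available:
#'
#' * `constant`: `f(m) = c1`
#' * `linear`: `f(m) = c1 + c2 m`
#' * `quadratic`: `f(m) = c1 + c2 m + c3 m^2`
#' * `spline_like`: `f(m) = c1 + c2 m + c3 h(60 - m)/100 + c4 h(m - 75)/100`
#'   where `h(u) = max(u, 0)^2`, a piecewise-quadratic shape with hinges on
#'   the dry (60%) and wet (75%) side that emulates threshold-like responses
#'   which a natural spline captures but a global polynomial does not.
#'
#' @param trait Trait name.
#' @param genotype Genotype label.
#' @param shape One of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"spline_like"`.
#' @param coefficients Numeric vector; length 1, 2, 3 or 4 to match `shape`.
#' @param cohort_effects Additive offset per harvest cohort (recycled); age
#'   differences between cohorts shift traits additively.
#' @param residual_sd Residual (within-genotype) standard deviation in trait
#'   units.
#' @return An object of class `reaction_norm_spec`.
#' @export
#' @examples
#' sp <- reaction_norm_spec("y", "g1", "quadratic", c(1, 0.1, -0.001))
#' eval_reaction_norm(sp, c(30, 65, 100))
reaction_norm_spec <- function(trait, genotype, shape, coefficients,
                               cohort_effects = 0, residual_sd = 0) {
  shape <- match.arg(shape, c("constant", "linear", "quadratic", "spline_like"))
  npar <- c(constant = 1L, linear = 2L, quadratic = 3L, spline_like = 4L)[[shape]]
  if (!is.numeric(coefficients) || length(coefficients) != npar ||
      !all(is.finite(coefficients))) {
    stop(sprintf("shape '%s' needs %d finite coefficients", shape, npar))
  }
  if (!is.numeric(residual_sd) || length(residual_sd) != 1 || residual_sd < 0) {
    stop("`residual_sd` must be a single value >= 0")
  }
  structure(list(trait = trait, genotype = genotype, shape = shape,
                 coefficients = unname(coefficients),
                 cohort_effects = unname(cohort_effects),
                 residual_sd = residual_sd),
            class = "reaction_norm_spec")
}

norm_key <- function(trait, genotype) paste(trait, genotype, sep = "|")

#' Evaluate a reaction norm at given soil-moisture values
#'
#' @param spec A [reaction_norm_spec()].
#' @param m Soil moisture values (% gravimetric).
#' @return Expected trait values (no cohort effect, no noise).
#' @export
eval_reaction_norm <- function(spec, m) {
  stopifnot(inherits(spec, "reaction_norm_spec"))
  cf <- spec$coefficients
  switch(spec$shape,
    constant = rep(cf[1], length(m)),
    linear = cf[1] + cf[2] * m,
    quadratic = cf[1] + cf[2] * m + cf[3] * m^2,
    spline_like = cf[1] + cf[2] * m +
      cf[3] * pmax(60 - m, 0)^2 / 100 +
      cf[4] * pmax(m - 75, 0)^2 / 100
  )
}

#' True genotype mean functions on a moisture grid
#'
#' Evaluates the generative reaction norms (the simulation "truth") for one
#' trait across genotypes, for comparison with model-based predicted genotype
#' means in recovery tests.
#'
#' @param norms A named list of [reaction_norm_spec()] keyed by
#'   `"trait|genotype"` (as produced by [default_reaction_norms()]).
#' @param trait Trait name.
#' @param genotypes Genotype labels.
#' @param m Moisture values (% gravimetric).
#' @return A genotypes-by-levels matrix of true means.
#' @export
reaction_norm_truth <- function(norms, trait, genotypes, m) {
  vals <- vapply(genotypes, function(g) {
    key <- norm_key(trait, g)
    if (is.null(norms[[key]])) {
      stop(sprintf("no reaction norm spec for trait '%s', genotype '%s'",
                   trait, g))
    }
    eval_reaction_norm(norms[[key]], m)
  }, numeric(length(m)))
  out <- t(matrix(vals, nrow = length(m), ncol = length(genotypes)))
  dimnames(out) <- list(genotypes, NULL)
  out
}

#' Simulate trait observations from reaction norms
#'
#' Each observation is `f_genotype(moisture) + cohort_effect + N(0, sd)`. With
#' `residual_sd = 0` and zero cohort effects the simulation is an exact,
#' reproducible function evaluation.
#'
#' @param norms Named list of [reaction_norm_spec()] keyed `"trait|genotype"`.
#' @param moisture Per-plant final soil moisture (%), positive.
#' @param genotype Per-plant genotype labels.
#' @param cohort Per-plant cohort index (1-based); `NULL` for a single cohort.
#' @param seed Optional integer seed.
#' @return A data frame with `genotype`, `cohort`, `soil_moisture_final` and
#'   one column per trait; the generative `norms` are attached as attribute
#'   `"norms"` for recovery tests.
#' @export
simulate_trait_values <- function(norms, moisture, genotype, cohort = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(moisture)) || any(moisture <= 0)) {
    stop("`moisture` values must be positive")
  }
  n <- length(moisture)
  stopifnot(length(genotype) == n)
  if (is.null(cohort)) cohort <- rep(1L, n)
  stopifnot(length(cohort) == n)

  traits <- unique(vapply(norms, function(s) s$trait, character(1)))
  out <- data.frame(genotype = as.character(genotype),
                    cohort = as.integer(cohort),
                    soil_moisture_final = moisture,
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    vals <- numeric(n)
    for (g in unique(out$genotype)) {
      key <- norm_key(tr, g)
      spec <- norms[[key]]
      if (is.null(spec)) {
        stop(sprintf("no reaction norm spec for trait '%s', genotype '%s'",
                     tr, g))
      }
      idx <- which(out$genotype == g)
      ce <- rep_len(spec$cohort_effects, max(out$cohort))
      mu <- eval_reaction_norm(spec, moisture[idx]) + ce[out$cohort[idx]]
      vals[idx] <- if (spec$residual_sd > 0) {
        mu + stats::rnorm(length(idx), 0, spec$residual_sd)
      } else {
        mu
      }
    }
    out[[tr]] <- vals
  }
  attr(out, "norms") <- norms
  out
}
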