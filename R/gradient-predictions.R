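#' Evenly spaced soil-moisture grid
#'
#' The default grid is 20 evenly spaced levels from 30% to 100% gravimetric
#' water content, the grid on which genotype means, genetic correlations,
#' plasticity and constraint statistics are evaluated.
#'
#' @param n Number of levels.
#' @param min,max Grid endpoints (% gravimetric).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
moisture_grid <- function(n = 20, min = 30, max = 100) {
  if (!(is.finite(min) && is.finite(max) && min < max && n >= 2)) {
    stop("need finite min < max and n >= 2")
  }
  seq(min, max, length.out = n)
}

#' Predict genotype trait means along the moisture grid
#'
#' Evaluates a fitted reaction-norm model for every training genotype at every
#' grid level. The harvest-cohort term is marginalised by averaging the
#' prediction over all cohort levels with equal weight (which makes the result
#' invariant to the contrast reference level); aliased coefficients contribute
#' zero. Models without a genotype term return the same curve for every
#' genotype; models without environmental terms return genotype constants.
#'
#' @param models An `fvt_model`, an `fvt_model_set`, or a list of `fvt_model`.
#' @param grid Moisture levels, default [moisture_grid()].
#' @param genotypes Genotypes to predict (default: the training genotypes;
#'   requesting a genotype absent from training is an error).
#' @return Long data frame: `species`, `trait`, `genotype`, `level`, `value`.
#' @export
predict_genotype_means <- function(models, grid = moisture_grid(),
                                   genotypes = NULL) {
  if (inherits(models, "fvt_model")) models <- list(models)
  out <- lapply(models, function(m) {
    gl <- m$genotype_levels
    if (is.null(gl)) gl <- "(pooled)"
    gs <- if (is.null(genotypes)) gl else genotypes
    bad <- setdiff(gs, gl)
    if (length(bad)) {
      stop("genotype(s) absent from training data: ",
           paste(bad, collapse = ", "))
    }
    pred <- predict_fvt_model(m, gs, grid)
    data.frame(species = if (is.null(m$species)) "all" else m$species,
               trait = m$trait,
               genotype = rep(gs, each = length(grid)),
               level = rep(grid, times = length(gs)),
               value = as.vector(t(pred)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# genotypes x levels matrix of cohort-averaged predictions
predict_fvt_model <- function(m, genotypes, levels) {
  cohorts <- m$cohort_levels
  if (is.null(cohorts) || !("H" %in% m$terms)) cohorts <- cohorts[1]
  if (is.null(cohorts) || !length(cohorts)) cohorts <- 1L
  nd <- expand.grid(cohort = cohorts, genotype = genotypes,
                    soil_moisture_final = levels,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dm <- build_design_matrix(m$terms, nd, basis = m$basis,
                            genotype_levels = m$genotype_levels,
                            cohort_levels = m$cohort_levels)
  stopifnot(identical(colnames(dm$X), names(m$coefficients)))
  p <- as.numeric(dm$X %*% m$coefficients)
  # average over cohorts, then reshape to genotypes x levels
  arr <- array(p, dim = c(length(cohorts), length(genotypes), length(levels)))
  out <- apply(arr, c(2, 3), mean)
  out <- matrix(out, length(genotypes), length(levels),
                dimnames = list(genotypes, NULL))
  out
}

#' @export
predict.fvt_model <- function(object, newdata = NULL, grid = moisture_grid(),
                              genotypes = NULL, ...) {
  if (is.null(newdata)) {
    gs <- if (is.null(genotypes)) object$genotype_levels else genotypes
    if (is.null(gs)) gs <- "(pooled)"
    return(predict_fvt_model(object, gs, grid))
  }
  dm <- build_design_matrix(object$terms, newdata, basis = object$basis,
                            genotype_levels = object$genotype_levels,
                            cohort_levels = object$cohort_levels)
  as.numeric(dm$X %*% object$coefficients)
}

#' Genetic correlation curves along the moisture grid
#'
#' Pearson correlations between the predicted genotype means of trait pairs,
#' computed at every grid level within each species. By default only traits
#' whose selected model contains the genotype term enter (pairs involving a
#' trait with no genotype signal are omitted, since its genotype "means"
#' coincide); a trait with zero variance across genotypes at some level gets
#' `NA` there rather than a spurious value.
#'
#' @param grid_means Output of [predict_genotype_means()].
#' @param models Optional `fvt_model_set` used to restrict traits to those
#'   with a genotype term.
#' @param min_genotypes Minimum genotypes required at a level (default 3).
#' @return Long data frame: `species`, `trait_a`, `trait_b`, `level`, `r`.
#' @export
correlation_curves <- function(grid_means, models = NULL, min_genotypes = 3) {
  keep <- function(sp, tr) TRUE
  if (!is.null(models)) {
    with_g <- lapply(models, function(m) {
      if ("G" %in% m$terms) c(if (is.null(m$species)) "all" else m$species,
                              m$trait)
    })
    with_g <- Filter(Negate(is.null), with_g)
    keep <- function(sp, tr) {
      any(vapply(with_g, function(x) x[1] == sp && x[2] == tr, logical(1)))
    }
  }
  out <- list()
  for (sp in sort(unique(grid_means$species))) {
    d <- grid_means[grid_means$species == sp, , drop = FALSE]
    traits <- sort(unique(d$trait))
    traits <- traits[vapply(traits, function(tr) keep(sp, tr), logical(1))]
    if (length(traits) < 2) next
    levels_ <- sort(unique(d$level))
    pairs <- utils::combn(traits, 2)
    for (k in seq_len(ncol(pairs))) {
      ta <- pairs[1, k]; tb <- pairs[2, k]
      r <- vapply(levels_, function(lv) {
        a <- d[d$trait == ta & d$level == lv, ]
        b <- d[d$trait == tb & d$level == lv, ]
        b <- b[match(a$genotype, b$genotype), ]
        if (nrow(a) < min_genotypes || anyNA(b$value) || anyNA(a$value)) {
          return(NA_real_)
        }
        if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0) {
          return(NA_real_)
        }
        stats::cor(a$value, b$value)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(species = sp, trait_a = ta,
                                            trait_b = tb, level = levels_,
                                            r = r, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(), trait_a = character(),
                      trait_b = character(), level = numeric(),
                      r = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
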