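# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# Truncated-power construction of the natural cubic spline space with knots
# xi (boundary knots included as knots). Returns the non-intercept columns:
# {x, N_k(x)} per the standard reduced basis, where
#   d_k(x) = ((x - xi_k)_+^3 - (x - xi_K)_+^3) / (xi_K - xi_k)
#   N_k(x) = d_k(x) - d_{K-1}(x).
# This spans the same space as the ns() basis up to an invertible linear map,
# so projection (fitted values) must agree for any response.
tp_natural_basis <- function(x, xi) {
  K <- length(xi)
  stopifnot(K >= 3)
  dk <- function(k) {
    (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
  }
  cols <- sapply(seq_len(K - 2), function(k) dk(k) - dk(K - 1))
  cbind(x = x, matrix(cols, nrow = length(x)))
}

# Moore-Penrose least squares via SVD, independent of lm.fit's pivoted QR.
pinv_fitted <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  beta <- s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep])
  as.numeric(X %*% beta)
}

# Closed-form Welch two-sample t-test.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Single-species layout + moisture for quick model-selection fixtures.
quick_env <- function(n_genotypes = 5, n_plants = 120, seed = 1) {
  d <- dry_down_design(n_genotypes_per_species = n_genotypes,
                       n_plants_per_genotype = n_plants, species = "only")
  lay <- plant_layout(d)
  m <- simulate_soil_moisture(d, treatments = lay$treatment, seed = seed)
  list(design = d, layout = lay, moisture = m$final,
       genotypes = sort(unique(lay$genotype)))
}

# Quadratic reaction norms for one trait across genotypes.
quad_norms <- function(trait, genotypes, a, b, cc, residual_sd = 0,
                       cohort_effects = 0) {
  norms <- list()
  for (i in seq_along(genotypes)) {
    norms[[paste(trait, genotypes[i], sep = "|")]] <- reaction_norm_spec(
      trait, genotypes[i], "quadratic",
      c(a[i], b[min(i, length(b))], cc[min(i, length(cc))]),
      cohort_effects = cohort_effects, residual_sd = residual_sd)
  }
  norms
}

# Hand-built scaled trait space (rows: genotype x level).
make_space <- function(mat, genotype, level, species = "sp") {
  structure(list(species = species, matrix = mat, genotype = genotype,
                 level = level, center = rep(0, ncol(mat)),
                 scale = rep(1, ncol(mat))),
            class = "fvt_scaled_space")
}

# Long-format grid means from a genotypes x levels matrix of values.
make_grid_means <- function(values_by_trait, genotypes, levels,
                            species = "sp") {
  out <- do.call(rbind, lapply(names(values_by_trait), function(tr) {
    v <- values_by_trait[[tr]]
    data.frame(species = species, trait = tr,
               genotype = rep(genotypes, each = length(levels)),
               level = rep(levels, times = length(genotypes)),
               value = as.vector(t(v)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
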