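#' Scale predicted genotype means into a standardised trait space
#'
#' Builds, per species, the matrix of genotype-by-level rows and trait
#' columns from predicted genotype means, then z-scores every trait over the
#' pooled genotype x level rows (mean 0, sd 1 with divisor n-1). Pooling over
#' all rows within a species keeps levels comparable, which is what the
#' between-level distance ΔT requires. Scaling constants are retained so the
#' transformation is invertible.
#'
#' @param grid_means Output of [predict_genotype_means()].
#' @param species Species to scale; default: the single species present, or
#'   an error listing them if several (scale each separately).
#' @param traits Trait columns to include (default: all present for the
#'   species).
#' @param on_constant `"error"` (default) stops on a trait with zero pooled
#'   variance, naming it; `"drop"` removes it with a warning.
#' @return Object of class `fvt_scaled_space`: `species`, `matrix` (scaled),
#'   `genotype`, `level`, `center`, `scale`.
#' @export
scale_traits <- function(grid_means, species = NULL, traits = NULL,
                         on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  sps <- sort(unique(grid_means$species))
  if (is.null(species)) {
    if (length(sps) > 1) {
      stop("several species present (", paste(sps, collapse = ", "),
           "); scale each separately")
    }
    species <- sps
  }
  d <- grid_means[grid_means$species == species, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no rows for species '%s'", species))
  if (is.null(traits)) traits <- sort(unique(d$trait))

  genotypes <- sort(unique(d$genotype))
  levels_ <- sort(unique(d$level))
  rows <- expand.grid(level = levels_, genotype = genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mat <- matrix(NA_real_, nrow(rows), length(traits),
                dimnames = list(NULL, traits))
  for (tr in traits) {
    dt <- d[d$trait == tr, , drop = FALSE]
    idx <- match(paste(rows$genotype, rows$level),
                 paste(dt$genotype, dt$level))
    if (anyNA(idx)) {
      stop(sprintf("trait '%s' is missing some genotype x level combinations",
                   tr))
    }
    mat[, tr] <- dt$value[idx]
  }
  ctr <- colMeans(mat)
  scl <- apply(mat, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (any(const)) {
    if (on_constant == "error") {
      stop("constant trait column(s): ",
           paste(traits[const], collapse = ", "))
    }
    warning("dropping constant trait column(s): ",
            paste(traits[const], collapse = ", "))
    mat <- mat[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]; traits <- traits[!const]
  }
  if (!ncol(mat)) stop("no non-constant traits left to scale")
  z <- sweep(sweep(mat, 2, ctr, "-"), 2, scl, "/")
  structure(list(species = species, matrix = z, genotype = rows$genotype,
                 level = rows$level, center = ctr, scale = scl),
            class = "fvt_scaled_space")
}

#' Invert the scaling of a standardised trait space
#' @param space An [scale_traits()] result.
#' @return Matrix on the original trait scales.
#' @export
unscale_traits <- function(space) {
  stopifnot(inherits(space, "fvt_scaled_space"))
  sweep(sweep(space$matrix, 2, space$scale, "*"), 2, space$center, "+")
}

#' Multivariate plasticity between consecutive moisture levels
#'
#' Total plasticity of genotype g over interval i is the Euclidean distance
#' between its scaled multivariate phenotypes at consecutive grid levels:
#' `ΔT(g,i) = sqrt( sum_j (p(g,i,j) - p(g,i+1,j))^2 )` over the trait
#' dimensions j. A 20-level grid yields 19 intervals per genotype.
#'
#' @param space An [scale_traits()] result, or a list of them (one per
#'   species); results are row-bound.
#' @return Data frame: `species`, `genotype`, `interval`, `moisture_from`,
#'   `moisture_to`, `deltaT`.
#' @export
delta_T <- function(space) {
  if (is.list(space) && !inherits(space, "fvt_scaled_space")) {
    out <- do.call(rbind, lapply(space, delta_T))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(space, "fvt_scaled_space"))
  levels_ <- sort(unique(space$level))
  if (length(levels_) < 2) stop("need at least two moisture levels")
  out <- list()
  for (g in sort(unique(space$genotype))) {
    idx <- which(space$genotype == g)
    idx <- idx[order(space$level[idx])]
    if (!identical(space$level[idx], levels_)) {
      stop(sprintf("genotype '%s' is missing moisture levels", g))
    }
    m <- space$matrix[idx, , drop = FALSE]
    d <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
    out[[g]] <- data.frame(species = space$species, genotype = g,
                           interval = seq_len(length(levels_) - 1L),
                           moisture_from = levels_[-length(levels_)],
                           moisture_to = levels_[-1],
                           deltaT = unname(d), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-interval species contrast of multivariate plasticity
#'
#' Compares mean ΔT between the two species at every moisture interval with
#' Welch's unequal-variance two-sample t-test (genotypes are the replicates).
#' The t statistic is oriented as first species minus second (alphabetical
#' order). No multiplicity correction is applied; significance is flagged at
#' `alpha`.
#'
#' @param series A [delta_T()] result containing exactly two species.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `interval`, `moisture_from`, `moisture_to`,
#'   `species_1`, `species_2`, `t`, `df`, `p_value`, `significant` (`NA` when
#'   fewer than 2 genotypes per species make the interval untestable).
#' @export
species_contrast <- function(series, alpha = 0.05) {
  sps <- sort(unique(series$species))
  if (length(sps) != 2) {
    stop("`series` must contain exactly two species, got: ",
         paste(sps, collapse = ", "))
  }
  ivs <- sort(unique(series$interval))
  rows <- lapply(ivs, function(i) {
    d <- series[series$interval == i, , drop = FALSE]
    x <- d$deltaT[d$species == sps[1]]
    y <- d$deltaT[d$species == sps[2]]
    base <- data.frame(interval = i,
                       moisture_from = d$moisture_from[1],
                       moisture_to = d$moisture_to[1],
                       species_1 = sps[1], species_2 = sps[2],
                       stringsAsFactors = FALSE)
    if (length(x) < 2 || length(y) < 2) {
      return(cbind(base, t = NA_real_, df = NA_real_, p_value = NA_real_,
                   significant = NA))
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      # identical degenerate groups: no difference
      return(cbind(base, t = 0, df = length(x) + length(y) - 2, p_value = 1,
                   significant = FALSE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    cbind(base, t = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, significant = tt$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA of the scaled genotype trait space
#'
#' Principal component analysis of the scaled genotype-mean matrix (rows:
#' genotype x level; columns: traits) with the sample-covariance convention
#' (centering, divisor n-1). Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' reproducible across platforms.
#'
#' @param space An [scale_traits()] result.
#' @return List of class `fvt_pca`: `loadings` (traits x components),
#'   `scores` (rows x components), `sdev`, `var_frac` (fractions of total
#'   variance, summing to 1), `genotype`, `level`.
#' @export
trait_space_pca <- function(space) {
  stopifnot(inherits(space, "fvt_scaled_space"))
  x <- space$matrix
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 rows and 2 columns")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (all(p$sdev == 0)) stop("trait space has rank 0")
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  structure(list(loadings = p$rotation, scores = p$x, sdev = p$sdev,
                 var_frac = p$sdev^2 / sum(p$sdev^2),
                 genotype = space$genotype, level = space$level,
                 species = space$species),
            class = "fvt_pca")
}
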