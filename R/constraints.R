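#' Genetic covariance matrix at one soil-moisture level
#'
#' Approximates the G matrix for one species at one grid level from predicted
#' genotype means: each trait's genotype means are mean-standardised (divided
#' by their mean across genotypes, so variances are comparable across traits
#' with different units), then the sample covariance (divisor n-1) across
#' genotypes is taken. Traits whose mean is within `drop_tol * sd` of zero
#' are dropped with a warning — dividing by a near-zero mean is numerically
#' unstable. Dividing by a signed mean flips the standardised deviations of
#' negative-mean traits (e.g. δ13C); set `abs_mean = TRUE` to divide by the
#' absolute mean instead.
#'
#' @param grid_means Output of [predict_genotype_means()].
#' @param species Species label.
#' @param level Grid level (must match a level in `grid_means`).
#' @param traits Traits to include (default: all present for the species).
#' @param abs_mean Divide by `abs(mean)` instead of the signed mean.
#' @param center `"level"` (default) standardises by the mean at this level;
#'   `"grand"` uses the trait's grand mean across all levels.
#' @param drop_tol Instability tolerance for near-zero means.
#' @return Object of class `fvt_gmatrix`: `species`, `level`, `matrix`,
#'   `traits`, `means`, `n_genotypes`.
#' @export
g_matrix <- function(grid_means, species, level, traits = NULL,
                     abs_mean = FALSE, center = c("level", "grand"),
                     drop_tol = 1e-6) {
  center <- match.arg(center)
  d <- grid_means[grid_means$species == species, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no rows for species '%s'", species))
  if (is.null(traits)) traits <- sort(unique(d$trait))
  dl <- d[d$level == level, , drop = FALSE]
  if (!nrow(dl)) stop(sprintf("level %s not present in grid means", level))
  genotypes <- sort(unique(dl$genotype))
  if (length(genotypes) < 2) stop("need at least 2 genotypes")

  mat <- matrix(NA_real_, length(genotypes), length(traits),
                dimnames = list(genotypes, traits))
  for (tr in traits) {
    dt <- dl[dl$trait == tr, , drop = FALSE]
    mat[, tr] <- dt$value[match(genotypes, dt$genotype)]
  }
  if (anyNA(mat)) stop("missing genotype means for some trait at this level")

  means <- if (center == "level") colMeans(mat) else {
    vapply(traits, function(tr) mean(d$value[d$trait == tr]), numeric(1))
  }
  sds <- apply(mat, 2, stats::sd)
  unstable <- abs(means) <= drop_tol * sds
  if (any(unstable)) {
    warning("dropping trait(s) with mean too close to zero for ",
            "mean-standardisation: ", paste(traits[unstable], collapse = ", "))
    mat <- mat[, !unstable, drop = FALSE]
    means <- means[!unstable]; traits <- traits[!unstable]
  }
  if (!ncol(mat)) stop("no traits left after dropping unstable means")
  denom <- if (abs_mean) abs(means) else means
  z <- sweep(mat, 2, denom, "/")
  structure(list(species = species, level = level, matrix = stats::cov(z),
                 traits = traits, means = means,
                 n_genotypes = length(genotypes)),
            class = "fvt_gmatrix")
}

#' Evolutionary-constraint statistics of a G matrix
#'
#' Eigen-decomposes a symmetric positive semi-definite G matrix and derives:
#'
#' * `nD` — number of effective dimensions, the eigenvalue sum divided by the
#'   largest eigenvalue; ranges from 1 (all genetic variation on one axis:
#'   high constraint) to the number of traits (no covariance: low constraint);
#' * `emax` — maximum evolvability, the square root of the largest eigenvalue
#'   (genetic standard deviation along the major axis);
#' * `vT` — total genetic variance, the eigenvalue sum (the trace of G);
#' * `prop1` — the share of variance on the first axis, `1/nD`.
#'
#' Small negative eigenvalues (within `1e-10` of zero relative to the largest)
#' are clamped to zero; a larger violation of positive semi-definiteness is
#' clamped with a warning. A zero largest eigenvalue leaves `nD` undefined
#' (`NA`).
#'
#' @param G An [g_matrix()] result or a plain symmetric matrix.
#' @return List of class `fvt_constraint`: `eigenvalues` (descending), `nD`,
#'   `emax`, `vT`, `prop1`, plus `species`/`level` when available.
#' @export
constraint_stats <- function(G) {
  sp <- NULL; lv <- NULL
  if (inherits(G, "fvt_gmatrix")) {
    sp <- G$species; lv <- G$level; G <- G$matrix
  }
  G <- as.matrix(G)
  if (nrow(G) != ncol(G) || max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G)))) {
    stop("G must be a symmetric square matrix")
  }
  lam <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(lam[1], 0)
  if (any(lam < -max(tol, 1e-10 * max(1, abs(lam[1]))))) {
    warning("G has negative eigenvalues beyond tolerance; clamping to zero")
  }
  lam <- pmax(lam, 0)
  l1 <- lam[1]
  structure(list(species = sp, level = lv, eigenvalues = lam,
                 nD = if (l1 > 0) sum(lam) / l1 else NA_real_,
                 emax = sqrt(l1), vT = sum(lam),
                 prop1 = if (sum(lam) > 0) l1 / sum(lam) else NA_real_),
            class = "fvt_constraint")
}

#' @export
print.fvt_constraint <- function(x, ...) {
  cat(sprintf("Constraint statistics%s: nD = %.3f, emax = %.4g, vT = %.4g\n",
              if (is.null(x$level)) "" else
                sprintf(" (%s @ %.1f%%)", x$species, x$level),
              x$nD, x$emax, x$vT))
  invisible(x)
}

#' Constraint statistics across the moisture grid
#'
#' Computes the G matrix and its constraint statistics for every species at
#' every grid level. By default (when `models` is supplied) only traits whose
#' selected model contains the genotype term enter G — traits without genotype
#' signal would contribute exact zero rows and columns. Levels where the
#' computation fails are flagged (`ok = FALSE`) and the run continues.
#'
#' @param grid_means Output of [predict_genotype_means()].
#' @param models Optional `fvt_model_set` used to restrict traits per species.
#' @param traits Explicit trait selection (overrides `models`).
#' @inheritParams g_matrix
#' @return Data frame: `species`, `level`, `n_traits`, `nD`, `emax`, `vT`,
#'   `prop1`, `eigenvalues` (semicolon-joined, descending), `ok`.
#' @export
constraint_curves <- function(grid_means, models = NULL, traits = NULL,
                              abs_mean = FALSE, center = c("level", "grand"),
                              drop_tol = 1e-6) {
  center <- match.arg(center)
  traits_for <- function(sp) {
    if (!is.null(traits)) return(traits)
    if (is.null(models)) return(sort(unique(
      grid_means$trait[grid_means$species == sp])))
    found <- unlist(lapply(models, function(m) {
      msp <- if (is.null(m$species)) "all" else m$species
      if (msp == sp && "G" %in% m$terms) m$trait
    }))
    sort(unique(found))
  }
  out <- list()
  for (sp in sort(unique(grid_means$species))) {
    trs <- traits_for(sp)
    if (length(trs) < 2) {
      warning(sprintf("species '%s': fewer than 2 genotype-informative traits",
                      sp))
      next
    }
    for (lv in sort(unique(grid_means$level))) {
      row <- tryCatch({
        cs <- constraint_stats(g_matrix(grid_means, sp, lv, traits = trs,
                                        abs_mean = abs_mean, center = center,
                                        drop_tol = drop_tol))
        data.frame(species = sp, level = lv,
                   n_traits = length(cs$eigenvalues),
                   nD = cs$nD, emax = cs$emax, vT = cs$vT, prop1 = cs$prop1,
                   eigenvalues = paste(signif(cs$eigenvalues, 10),
                                       collapse = ";"),
                   ok = TRUE, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(species = sp, level = lv, n_traits = NA_integer_,
                   nD = NA_real_, emax = NA_real_, vT = NA_real_,
                   prop1 = NA_real_, eigenvalues = NA_character_, ok = FALSE,
                   stringsAsFactors = FALSE)
      })
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
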