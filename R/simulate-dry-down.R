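# Default generative model for a full synthetic dry-down experiment.
#
# Nine base traits get their own reaction norms; biomass, root:shoot and C:N
# are derived from components so the composite-trait arithmetic of the
# harvesting protocol is preserved. Species templates differ qualitatively:
# the annual (first species) has the stronger dry-end SLA response, the
# perennial (second) has higher d13C and stronger leaf-composition responses.

trait_groups <- function() {
  list(A = c("green_area", "shoot_mass", "root_mass", "root_shoot", "biomass",
             "C_content", "N_content", "C_N", "d13C", "d15N"),
       B = c("SLA", "RWC"))
}

#' Trait names produced by the synthetic dry-down generator
#' @return Character vector of the twelve trait columns.
#' @export
fvt_traits <- function() unname(unlist(trait_groups()))

# Species-level templates: shape, coefficients, sd of genotype perturbations
# per coefficient (non-zero beyond the intercept => genotype-by-environment
# interaction in the truth), cohort age slope and residual sd.
default_templates <- function(which_species) {
  annual <- which_species == 1L
  list(
    RWC = list(shape = "spline_like",
               base = c(0.96, 1e-4, -0.012, -0.001),
               gsd = c(0.012, 0, 0.003, 0),
               cohort_slope = 0.002, residual_sd = 0.02),
    SLA = list(shape = "spline_like",
               base = if (annual) c(25000, 5, -250, -20) else c(21000, 5, -80, -10),
               gsd = c(900, 0, if (annual) 60 else 15, 0),
               cohort_slope = 150, residual_sd = 1200),
    green_area = list(shape = "quadratic",
                      base = c(5000, 1800, -8),
                      gsd = c(6000, 60, 0),
                      cohort_slope = 2500, residual_sd = 9000),
    shoot_mass = list(shape = "quadratic",
                      base = c(0.05, 0.012, -3e-5),
                      gsd = c(0.06, 0, 0),
                      cohort_slope = 0.02, residual_sd = 0.09),
    root_mass = list(shape = "quadratic",
                     base = c(0.05, 0.006, -2e-5),
                     gsd = c(0.04, 0, 0),
                     cohort_slope = 0.008, residual_sd = 0.05),
    C_content = list(shape = "linear",
                     base = c(41, 0.01),
                     gsd = c(0.5, 0),
                     cohort_slope = 0.1, residual_sd = 0.6),
    N_content = list(shape = "quadratic",
                     base = if (annual) c(2.6, 0.008, -6e-5) else c(2.4, 0.016, -1.2e-4),
                     gsd = c(0.18, 0, if (annual) 0 else 3e-5),
                     cohort_slope = -0.03, residual_sd = 0.25),
    d13C = list(shape = "linear",
                base = if (annual) c(-26.5, -0.04) else c(-25.2, -0.04),
                gsd = c(0.35, 0.002),
                cohort_slope = 0.05, residual_sd = 0.35),
    d15N = list(shape = "linear",
                base = c(2, 0.004),
                gsd = c(0.5, 0),
                cohort_slope = 0, residual_sd = 0.4)
  )
}

#' Default genotype-specific reaction norms for a design
#'
#' Draws genotype coefficient perturbations around species-level trait
#' templates (see the methods vignette for the rationale behind the template
#' values). Traits with non-zero perturbation of slope or curvature
#' coefficients carry genuine genotype-by-environment interaction in the
#' generative truth.
#'
#' @param design A [dry_down_design()].
#' @param seed Integer seed for the genotype draws.
#' @return Named list of [reaction_norm_spec()] keyed `"trait|genotype"`.
#' @export
default_reaction_norms <- function(design, seed = 1) {
  stopifnot(inherits(design, "dry_down_design"))
  set.seed(seed)
  norms <- list()
  cohort_idx <- seq_len(design$n_cohorts) - (design$n_cohorts + 1) / 2
  for (si in seq_along(design$species)) {
    sp <- design$species[si]
    tmpl <- default_templates(si)
    geno <- sprintf("%s_g%d", substr(sp, 1, 1),
                    seq_len(design$n_genotypes_per_species))
    for (tr in names(tmpl)) {
      tm <- tmpl[[tr]]
      for (g in geno) {
        cf <- tm$base + stats::rnorm(length(tm$base), 0, tm$gsd)
        norms[[norm_key(tr, g)]] <- reaction_norm_spec(
          trait = tr, genotype = g, shape = tm$shape, coefficients = cf,
          cohort_effects = cohort_idx * tm$cohort_slope,
          residual_sd = tm$residual_sd)
      }
    }
  }
  norms
}

#' Simulate a complete synthetic dry-down experiment
#'
#' Generates the plant layout, per-pot soil-moisture trajectories, trait
#' observations from genotype-specific reaction norms, composite traits
#' (biomass, root:shoot, C:N from their components) and, by default, the
#' destructive two-way harvest split: each plant is assessed either for the
#' biomass/composition trait group or for SLA and RWC, with the other group's
#' columns missing.
#'
#' @param design A [dry_down_design()].
#' @param norms Optional named list of [reaction_norm_spec()]; defaults to
#'   [default_reaction_norms()] drawn from `seed`.
#' @param seed Integer seed; all randomness (genotype draws, moisture
#'   dynamics, residual noise) derives from it.
#' @param split_harvest Apply the two-group destructive split (`TRUE`), or
#'   keep all traits on all plants (`FALSE`, useful for small fixtures).
#' @param as_printed_moisture Use the uncorrected gravimetric convention (see
#'   [simulate_soil_moisture()]).
#' @return A list of class `fvt_sim`: `table` (the plant-level trait table),
#'   `norms` (generative truth), `moisture` (trajectory object), `design`.
#' @export
#' @examples
#' sim <- simulate_dry_down(dry_down_design(n_plants_per_genotype = 12), seed = 1)
#' head(sim$table)
simulate_dry_down <- function(design = dry_down_design(), norms = NULL,
                              seed = 1, split_harvest = TRUE,
                              as_printed_moisture = FALSE) {
  stopifnot(inherits(design, "dry_down_design"))
  set.seed(seed)
  subseed <- sample.int(.Machine$integer.max - 1L, 3L)

  layout <- plant_layout(design)
  if (is.null(norms)) norms <- default_reaction_norms(design, seed = subseed[1])
  moist <- simulate_soil_moisture(design, treatments = layout$treatment,
                                  seed = subseed[2],
                                  as_printed = as_printed_moisture)
  vals <- simulate_trait_values(norms, moist$final, layout$genotype,
                                layout$cohort, seed = subseed[3])

  tab <- cbind(layout, soil_moisture_final = moist$final,
               vals[, setdiff(names(vals),
                              c("genotype", "cohort", "soil_moisture_final")),
                    drop = FALSE])
  # composite traits from their components
  if (all(c("shoot_mass", "root_mass") %in% names(tab))) {
    tab$biomass <- tab$shoot_mass + tab$root_mass
    tab$root_shoot <- ifelse(tab$shoot_mass > 0,
                             tab$root_mass / tab$shoot_mass, NA_real_)
  }
  if (all(c("C_content", "N_content") %in% names(tab))) {
    tab$C_N <- ifelse(tab$N_content != 0,
                      tab$C_content / tab$N_content, NA_real_)
  }

  groups <- trait_groups()
  if (split_harvest) {
    # alternate plants within genotype x treatment cells (cohort-ordered) so
    # the split is balanced across treatments and deterministic
    cell <- interaction(tab$genotype, tab$treatment, drop = TRUE)
    alt <- stats::ave(seq_len(nrow(tab)), cell, FUN = seq_along)
    tab$harvest_group <- ifelse(alt %% 2L == 1L, "A", "B")
    tab[tab$harvest_group == "B", intersect(groups$A, names(tab))] <- NA_real_
    tab[tab$harvest_group == "A", intersect(groups$B, names(tab))] <- NA_real_
  } else {
    tab$harvest_group <- "AB"
  }
  meta <- c("plant_id", "species", "genotype", "cohort", "treatment",
            "soil_moisture_final", "harvest_group")
  tab <- tab[, c(meta, intersect(fvt_traits(), names(tab))), drop = FALSE]
  rownames(tab) <- NULL

  structure(list(table = tab, norms = norms, moisture = moist,
                 design = design, seed = seed),
            class = "fvt_sim")
}

#' @export
print.fvt_sim <- function(x, ...) {
  cat("Synthetic dry-down experiment:", nrow(x$table), "plants,",
      length(unique(x$table$genotype)), "genotypes,",
      length(unique(x$table$species)), "species\n")
  cat("  final moisture range:",
      paste(round(range(x$table$soil_moisture_final), 1), collapse = " - "),
      "% gravimetric\n")
  invisible(x)
}
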