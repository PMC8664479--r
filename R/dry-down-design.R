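#' Design of a controlled dry-down experiment
#'
#' Describes a greenhouse dry-down: pots are saturated to field capacity, then
#' watered daily at one of several fixed rates while water is lost to
#' evaporation and transpiration, producing a continuous gradient of final
#' gravimetric soil moisture. Plants are split into harvest cohorts and, at
#' harvest, into two destructively-phenotyped groups.
#'
#' Water loss follows a two-stage model: above `critical_moisture` (as a
#' fraction of water-holding capacity) the pot loses water at the
#' energy-limited maximum rate `evaporation_rate * capacity` per day; below it
#' the loss falls linearly to zero at `residual_moisture` (supply-limited
#' stage). This produces the qualitative shape of observed dry-downs: pots on
#' low watering rates collapse onto the dry end of the gradient while heavily
#' watered pots remain near field capacity.
#'
#' @param n_genotypes_per_species Genotypes sampled per species.
#' @param n_plants_per_genotype Plants (pots) per genotype.
#' @param watering_levels Daily water inputs in ml/day, one pot is assigned to
#'   one level for the whole dry-down.
#' @param n_days Length of the dry-down period in days.
#' @param n_cohorts Number of consecutive-day harvest cohorts.
#' @param field_capacity_mass Pot mass (g) at field capacity (wet soil).
#' @param dry_mass Pot mass (g) with oven-dry soil.
#' @param evaporation_rate Maximum daily water loss as a fraction of the pot's
#'   water-holding capacity (stage-one, energy-limited evaporation).
#' @param critical_moisture Moisture fraction below which evaporation becomes
#'   supply-limited.
#' @param residual_moisture Moisture fraction at which evaporation stops
#'   (hygroscopic water).
#' @param loss_cv Coefficient of variation of the multiplicative day-to-day
#'   noise on water loss.
#' @param capacity_cv Coefficient of variation of per-pot water-holding
#'   capacity (pots differ slightly in packing and volume).
#' @param moisture_noise_sd Additive measurement noise (percentage points of
#'   gravimetric moisture) on the final reading.
#' @param species Character vector of species labels (genotypes are nested in
#'   species).
#'
#' @return An object of class `dry_down_design` (a validated list).
#' @seealso [simulate_soil_moisture()], [simulate_dry_down()]
#' @export
#' @examples
#' d <- dry_down_design()
#' d$watering_levels
dry_down_design <- function(n_genotypes_per_species = 5,
                            n_plants_per_genotype = 60,
                            watering_levels = c(0, 4, 8, 12, 16, 20),
                            n_days = 14,
                            n_cohorts = 5,
                            field_capacity_mass = 460,
                            dry_mass = 260,
                            evaporation_rate = 0.085,
                            critical_moisture = 0.5,
                            residual_moisture = 0.25,
                            loss_cv = 0.1,
                            capacity_cv = 0.05,
                            moisture_noise_sd = 2,
                            species = c("distachyon", "sylvaticum")) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(watering_levels) || length(watering_levels) < 1 ||
      any(watering_levels < 0)) {
    stop("`watering_levels` must be non-empty, finite and non-negative")
  }
  if (!num_ok(n_days) || n_days < 1) stop("`n_days` must be >= 1")
  if (!num_ok(n_cohorts) || n_cohorts < 1) stop("`n_cohorts` must be >= 1")
  if (!num_ok(field_capacity_mass) || !num_ok(dry_mass) ||
      field_capacity_mass <= dry_mass) {
    stop("`field_capacity_mass` must exceed `dry_mass`")
  }
  if (!num_ok(evaporation_rate) || evaporation_rate < 0) {
    stop("`evaporation_rate` must be finite and >= 0")
  }
  if (!num_ok(critical_moisture) || !num_ok(residual_moisture) ||
      !(0 <= residual_moisture && residual_moisture < critical_moisture &&
        critical_moisture <= 1)) {
    stop("need 0 <= residual_moisture < critical_moisture <= 1")
  }
  for (nm in c("n_genotypes_per_species", "n_plants_per_genotype",
               "loss_cv", "capacity_cv", "moisture_noise_sd")) {
    v <- get(nm)
    if (!num_ok(v) || v < 0) stop(sprintf("`%s` must be finite and >= 0", nm))
  }
  if (!is.character(species) || length(species) < 1 || anyDuplicated(species)) {
    stop("`species` must be distinct labels")
  }
  structure(list(
    n_genotypes_per_species = as.integer(n_genotypes_per_species),
    n_plants_per_genotype = as.integer(n_plants_per_genotype),
    watering_levels = watering_levels,
    n_days = as.integer(n_days),
    n_cohorts = as.integer(n_cohorts),
    field_capacity_mass = field_capacity_mass,
    dry_mass = dry_mass,
    evaporation_rate = evaporation_rate,
    critical_moisture = critical_moisture,
    residual_moisture = residual_moisture,
    loss_cv = loss_cv,
    capacity_cv = capacity_cv,
    moisture_noise_sd = moisture_noise_sd,
    species = species
  ), class = "dry_down_design")
}

#' @export
print.dry_down_design <- function(x, ...) {
  cat("Dry-down design:",
      length(x$species) * x$n_genotypes_per_species * x$n_plants_per_genotype,
      "plants\n")
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  cat("  genotypes: ", x$n_genotypes_per_species, "per species,",
      x$n_plants_per_genotype, "plants each\n")
  cat("  watering:  ", paste(x$watering_levels, collapse = ", "), "ml/day for",
      x$n_days, "days;", x$n_cohorts, "harvest cohorts\n")
  invisible(x)
}

#' Plant-level layout of a dry-down design
#'
#' Expands a design into one row per plant, assigning genotypes within
#' species and balancing watering treatments across harvest cohorts within
#' every genotype (each cohort contains equal numbers of each treatment, so
#' harvest day is not confounded with soil moisture). The layout is
#' deterministic.
#'
#' @param design A [dry_down_design()].
#' @return A data frame with columns `plant_id`, `species`, `genotype`,
#'   `cohort`, `treatment`.
#' @export
plant_layout <- function(design) {
  stopifnot(inherits(design, "dry_down_design"))
  cell <- expand.grid(cohort = seq_len(design$n_cohorts),
                      treatment = design$watering_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(design$species, function(sp) {
    geno <- sprintf("%s_g%d", substr(sp, 1, 1), seq_len(design$n_genotypes_per_species))
    do.call(rbind, lapply(geno, function(g) {
      idx <- rep_len(seq_len(nrow(cell)), design$n_plants_per_genotype)
      data.frame(species = sp, genotype = g,
                 cohort = cell$cohort[idx], treatment = cell$treatment[idx],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$plant_id <- sprintf("%s_p%03d", out$genotype,
                          stats::ave(seq_len(nrow(out)), out$genotype,
                                     FUN = seq_along))
  out[, c("plant_id", "species", "genotype", "cohort", "treatment")]
}

#' Simulate pot soil-moisture trajectories under a dry-down
#'
#' Runs the daily water balance for each pot: two-stage evaporative loss with
#' multiplicative daily noise, plus the treatment's fixed water input; water
#' beyond field capacity drains and is discarded. Gravimetric soil moisture on
#' day d is, by default, the corrected convention
#' `(mass_d - mass_dry) / (mass_max - mass_dry) * 100`, i.e. water mass over
#' water-holding capacity. With `as_printed = TRUE` the numerator keeps the
#' dry soil mass (`mass_d / (mass_max - mass_dry)`), a convention that can
#' exceed 100% by a large margin and is provided only for comparison.
#'
#' @param design A [dry_down_design()].
#' @param treatments Optional vector of ml/day inputs, one per pot; defaults
#'   to the balanced assignment of [plant_layout()].
#' @param seed Integer seed; all randomness in the trajectory flows from it.
#' @param as_printed Use the uncorrected gravimetric convention (see above).
#' @return A list of class `dry_down_moisture` with elements `final`
#'   (percent, measurement noise added, clipped to be positive), `treatment`,
#'   `trajectories` (pots x days+1 matrix of noiseless-measurement percent
#'   moisture) and `design`.
#' @export
#' @examples
#' m <- simulate_soil_moisture(dry_down_design(), seed = 1)
#' tapply(m$final, m$treatment, mean)
simulate_soil_moisture <- function(design, treatments = NULL, seed = NULL,
                                   as_printed = FALSE) {
  stopifnot(inherits(design, "dry_down_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(treatments)) treatments <- plant_layout(design)$treatment
  if (!all(is.finite(treatments)) || any(treatments < 0)) {
    stop("`treatments` must be finite and non-negative")
  }
  n <- length(treatments)
  cap_nominal <- design$field_capacity_mass - design$dry_mass
  cap <- cap_nominal * pmax(1 + stats::rnorm(n, 0, design$capacity_cv), 0.5)
  e_max <- design$evaporation_rate * cap

  w <- matrix(NA_real_, n, design$n_days + 1L)
  w[, 1L] <- cap
  for (d in seq_len(design$n_days)) {
    theta <- w[, d] / cap
    supply <- pmin(1, pmax(theta - design$residual_moisture, 0) /
                     (design$critical_moisture - design$residual_moisture))
    loss <- pmax(e_max * supply * (1 + stats::rnorm(n, 0, design$loss_cv)), 0)
    w[, d + 1L] <- pmin(pmax(w[, d] - loss + treatments, 0), cap)
  }

  offset <- if (as_printed) design$dry_mass else 0
  traj <- 100 * (w + offset) / cap
  final <- traj[, design$n_days + 1L] +
    stats::rnorm(n, 0, design$moisture_noise_sd)
  final <- pmax(final, 0.1)  # gravimetric moisture is strictly positive

  structure(list(final = final, treatment = treatments, trajectories = traj,
                 design = design),
            class = "dry_down_moisture")
}
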