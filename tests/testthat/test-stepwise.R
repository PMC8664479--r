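# Replay a selection trace to recover the visited term sets.
replay_states <- function(model) {
  tr <- model$trace[model$trace$accepted, , drop = FALSE]
  states <- list(strsplit("H G E E2 S G:E G:E2 G:S", " ")[[1]])
  cur <- full_term_set()
  out <- list(cur)
  for (i in seq_len(nrow(tr))) {
    if (tr$action[i] == "start") next
    cur <- if (tr$action[i] == "drop") setdiff(cur, tr$term[i]) else
      union(cur, tr$term[i])
    out[[length(out) + 1L]] <- cur
  }
  out
}

sim_quad_gxe <- function(seed, n_plants = 120, residual_sd = 0.5,
                         curvature_sd = 1, cohort_effects = c(-1, 0, 0, 0, 1)) {
  env <- quick_env(n_plants = n_plants, seed = seed)
  set.seed(seed + 5000)
  g <- env$genotypes
  norms <- quad_norms("y", g, a = 10 + seq_along(g),
                      b = 0.05, cc = rnorm(length(g), 0, curvature_sd),
                      residual_sd = residual_sd,
                      cohort_effects = cohort_effects)
  tab <- simulate_trait_values(norms, env$moisture, env$layout$genotype,
                               env$layout$cohort, seed = seed + 9000)
  list(tab = tab, norms = norms, genotypes = g)
}

test_that("stepwise selection recovers strong quadratic GxE structure", {
  s <- sim_quad_gxe(seed = 21)
  m <- stepwise_select(s$tab, "y")
  expect_true("G" %in% m$terms)
  expect_true(any(c("E2", "S", "G:E2", "G:S") %in% m$terms))
  expect_true(any(c("G:E", "G:E2", "G:S") %in% m$terms))
  expect_true("H" %in% m$terms)  # cohort effects present in the truth
})

test_that("selection never worsens AIC and respects marginality throughout", {
  for (seed in c(21, 22)) {
    s <- sim_quad_gxe(seed = seed)
    m <- stepwise_select(s$tab, "y")
    full <- fit_term_set(s$tab, "y", full_term_set())
    expect_lte(m$aic, full$aic)
    for (state in replay_states(m)) {
      for (t in intersect(c("G:E", "G:E2", "G:S"), state)) {
        deps <- switch(t, `G:E` = c("G", "E"), `G:E2` = c("G", "E2"),
                       `G:S` = c("G", "S"))
        expect_true(all(deps %in% state))
      }
    }
  }
})

test_that("refitting the selected term set reproduces the selection exactly", {
  s <- sim_quad_gxe(seed = 23)
  m <- stepwise_select(s$tab, "y")
  refit <- fit_term_set(s$tab, "y", m$terms)
  expect_identical(refit$coefficients, m$coefficients)
  expect_identical(refit$aic, m$aic)
  expect_identical(refit$rank, m$rank)
})

test_that("perfect fits are resolved toward the smallest-rank exact model", {
  env <- quick_env(n_plants = 40, seed = 2)
  tab <- data.frame(genotype = env$layout$genotype, cohort = env$layout$cohort,
                    soil_moisture_final = env$moisture)
  # exactly linear response: E and S carry duplicate information; the
  # search must land on the smaller-rank exact representation {E}
  tab$y <- 2 + 3 * tab$soil_moisture_final
  m <- stepwise_select(tab, "y", full = c("E", "S"))
  expect_identical(m$terms, "E")
  expect_identical(m$aic, -Inf)

  # pure-quadratic truth reduces to {E2}
  tab$z <- 1 - 0.002 * tab$soil_moisture_final^2
  m2 <- stepwise_select(tab, "z", full = c("E", "E2"))
  expect_identical(m2$terms, "E2")
})

test_that("noise-free data from a candidate term set is recovered exactly", {
  env <- quick_env(n_plants = 60, seed = 6)
  g <- env$genotypes
  norms <- quad_norms("y", g, a = 1 + seq_along(g), b = 0.1,
                      cc = 0.001 * seq_along(g), residual_sd = 0)
  tab <- simulate_trait_values(norms, env$moisture, env$layout$genotype,
                               env$layout$cohort)
  m <- suppressWarnings(stepwise_select(tab, "y"))
  expect_identical(m$aic, -Inf)
  truth <- vapply(seq_len(nrow(tab)), function(i) {
    eval_reaction_norm(norms[[paste0("y|", tab$genotype[i])]],
                       tab$soil_moisture_final[i])
  }, numeric(1))
  pred <- predict(m, newdata = tab)
  expect_lt(max(abs(pred - truth)), 1e-8)
})

test_that("selection agrees with MASS stepAIC on a spline-free scope", {
  skip_if_not_installed("MASS")
  for (seed in c(41, 42, 43)) {
    s <- sim_quad_gxe(seed = seed, residual_sd = 3, curvature_sd = 5e-4)
    mine <- stepwise_select(s$tab, "y", full = c("H", "G", "E", "E2"))
    d <- s$tab
    d$cohort <- factor(d$cohort)
    d$genotype <- factor(d$genotype)
    lmfull <- lm(y ~ cohort + genotype + soil_moisture_final +
                   I(soil_moisture_final^2), data = d)
    ms <- MASS::stepAIC(lmfull, direction = "both", trace = 0)
    labs <- attr(terms(ms), "term.labels")
    ref <- c(H = "cohort", G = "genotype", E = "soil_moisture_final",
             E2 = "I(soil_moisture_final^2)")
    expect_setequal(mine$terms, names(ref)[ref %in% labs])
  }
})

test_that("sparse traits warn but are still fitted when identifiable", {
  env <- quick_env(n_genotypes = 2, n_plants = 9, seed = 8)
  tab <- data.frame(genotype = env$layout$genotype, cohort = 1L,
                    soil_moisture_final = env$moisture,
                    y = rnorm(length(env$moisture)))
  expect_warning(m <- stepwise_select(tab, "y", full = c("G", "E")),
                 "non-missing rows")
  expect_s3_class(m, "fvt_model")
})

test_that("per-species selection produces the term matrix layout", {
  sim <- simulate_dry_down(dry_down_design(n_plants_per_genotype = 40,
                                           n_genotypes_per_species = 3),
                           seed = 12)
  models <- suppressWarnings(
    select_trait_models(sim$table, traits = c("shoot_mass", "RWC")))
  expect_length(models, 4)  # 2 species x 2 traits
  tm <- term_matrix(models)
  expect_setequal(names(tm), c("species", "trait", full_term_set()))
  expect_true(all(unlist(tm[full_term_set()]) %in% c("x", "-")))
  # species are fitted separately: each model only saw its own genotypes
  expect_false(any(models[[1]]$genotype_levels %in%
                     models[[3]]$genotype_levels))
})

test_that("selection failures are collected without aborting the set", {
  sim <- simulate_dry_down(dry_down_design(n_plants_per_genotype = 24,
                                           n_genotypes_per_species = 3),
                           seed = 13, split_harvest = FALSE)
  tab <- sim$table
  tab$broken <- NA_real_
  models <- suppressWarnings(
    select_trait_models(tab, traits = c("shoot_mass", "broken")))
  expect_length(models, 2)   # shoot_mass for both species
  expect_length(attr(models, "failures"), 2)
})
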