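test_that("G is the covariance of mean-standardised genotype means", {
  set.seed(23)
  g <- paste0("g", 1:5)
  lv <- c(30, 65, 100)
  A <- matrix(rnorm(15, 10, 2), 5, 3)
  B <- matrix(rnorm(15, -5, 1), 5, 3)   # negative-mean trait (like d13C)
  gm <- make_grid_means(list(a = A, b = B), g, lv)
  G <- g_matrix(gm, "sp", 65)
  # direct-formula oracle
  za <- A[, 2] / mean(A[, 2]); zb <- B[, 2] / mean(B[, 2])
  oracle <- cov(cbind(a = za, b = zb))
  expect_lt(max(abs(G$matrix - oracle)), 1e-12)
  expect_equal(G$matrix, t(G$matrix))

  # abs_mean flips the sign of covariances involving the negative-mean trait
  G2 <- g_matrix(gm, "sp", 65, abs_mean = TRUE)
  expect_equal(G2$matrix["a", "b"], -G$matrix["a", "b"], tolerance = 1e-12)
  expect_equal(G2$matrix["a", "a"], G$matrix["a", "a"], tolerance = 1e-12)
})

test_that("degenerate genotype structures give degenerate G", {
  g2 <- paste0("g", 1:2)
  gm <- make_grid_means(list(a = matrix(c(1, 2), 2, 1),
                             b = matrix(c(3, 5), 2, 1),
                             c = matrix(c(2, 1), 2, 1)), g2, 50)
  lam <- constraint_stats(g_matrix(gm, "sp", 50))$eigenvalues
  expect_lt(lam[2] / lam[1], 1e-12)  # n-1 bound: rank <= 1

  same <- make_grid_means(list(a = matrix(4, 3, 1), b = matrix(7, 3, 1)),
                          paste0("g", 1:3), 50)
  G0 <- g_matrix(same, "sp", 50)
  expect_true(all(G0$matrix == 0))
  expect_true(is.na(constraint_stats(G0)$nD))

  # near-zero trait means are unstable and dropped with a warning
  gm2 <- make_grid_means(list(a = matrix(c(1, 2, 3), 3, 1),
                              z = matrix(c(-1e-9, 1e-9, 0), 3, 1)),
                         paste0("g", 1:3), 50)
  expect_warning(Gd <- g_matrix(gm2, "sp", 50), "z")
  expect_identical(Gd$traits, "a")
})

test_that("constraint statistics match their closed forms", {
  cs <- constraint_stats(diag(12))
  expect_equal(cs$nD, 12)
  expect_equal(cs$emax, 1)
  expect_equal(cs$vT, 12)

  cs2 <- constraint_stats(diag(c(4, 1, 1)))
  expect_equal(cs2$nD, 1.5)
  expect_equal(cs2$emax, 2)
  expect_equal(cs2$vT, 6)
  expect_equal(cs2$prop1, 1 / cs2$nD, tolerance = 1e-12)

  v <- c(2, 1, -1)
  expect_equal(constraint_stats(outer(v, v))$nD, 1)  # rank-1: one dimension
  expect_error(constraint_stats(matrix(1:6, 2, 3)), "symmetric")
})

test_that("eigenvalues agree with a characteristic-polynomial oracle", {
  set.seed(24)
  for (n in c(2, 3)) {
    for (rep in 1:10) {
      X <- matrix(rnorm(n * 5), 5, n)
      G <- cov(X)
      lam <- constraint_stats(G)$eigenvalues
      # roots of det(G - lambda I) via polyroot on expanded coefficients
      coefs <- if (n == 2) {
        c(det(G), -(G[1, 1] + G[2, 2]), 1)
      } else {
        c(-det(G),
          G[1, 1] * G[2, 2] + G[1, 1] * G[3, 3] + G[2, 2] * G[3, 3] -
            G[1, 2]^2 - G[1, 3]^2 - G[2, 3]^2,
          -(G[1, 1] + G[2, 2] + G[3, 3]), 1)
      }
      roots <- sort(Re(polyroot(coefs)), decreasing = TRUE)
      expect_lt(max(abs(lam - roots)), 1e-8)
    }
  }
})

test_that("constraint invariants hold on random PSD matrices", {
  set.seed(25)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    X <- matrix(rnorm(n * (n + 3)), n + 3, n)
    G <- cov(X)
    cs <- constraint_stats(G)
    expect_gte(cs$nD, 1)
    expect_lte(cs$nD, n + 1e-10)
    expect_lte(cs$emax^2, cs$vT + 1e-10)
    expect_equal(cs$vT, sum(diag(G)), tolerance = 1e-10)
    # scale equivariance
    c2 <- constraint_stats(4 * G)
    expect_equal(c2$vT, 4 * cs$vT, tolerance = 1e-10)
    expect_equal(c2$emax, 2 * cs$emax, tolerance = 1e-10)
    expect_equal(c2$nD, cs$nD, tolerance = 1e-10)
  }
})

test_that("constraint curves span the grid and conserve the trace", {
  set.seed(26)
  g <- paste0("g", 1:5)
  lv <- moisture_grid(6, 30, 100)
  # between-genotype relative spread shrinking linearly with moisture
  spread <- seq(0.4, 0.05, length.out = length(lv))
  dev_a <- scale(rnorm(5))[, 1]
  dev_b <- scale(rnorm(5))[, 1]
  A <- 10 * (1 + outer(dev_a, spread))
  B <- 4 * (1 + outer(0.6 * dev_a + 0.8 * dev_b, spread))
  gm <- make_grid_means(list(a = A, b = B), g, lv)
  cons <- constraint_curves(gm)
  expect_equal(nrow(cons), length(lv))
  expect_true(all(cons$ok))
  # vT recovered as decreasing in moisture (variance concentrated when dry)
  expect_true(all(diff(cons$vT) < 0))
  # trace conservation at every level
  for (i in seq_along(lv)) {
    lam <- as.numeric(strsplit(cons$eigenvalues[i], ";")[[1]])
    G <- g_matrix(gm, "sp", lv[i])
    expect_equal(sum(lam), sum(diag(G$matrix)), tolerance = 1e-8)
    expect_equal(cons$prop1[i] * cons$nD[i], 1, tolerance = 1e-10)
  }

  # flat means give flat curves
  flat <- make_grid_means(list(a = matrix(rep(c(1, 2, 3), 3), 3),
                               b = matrix(rep(c(5, 2, 4), 3), 3)),
                          paste0("g", 1:3), c(30, 60, 100))
  fc <- constraint_curves(flat)
  expect_lt(diff(range(fc$vT)), 1e-12)
  expect_lt(diff(range(fc$nD)), 1e-12)
})

test_that("trait entry into G follows the genotype-term rule", {
  env <- quick_env(n_plants = 50, seed = 27)
  set.seed(27)
  tab <- data.frame(genotype = env$layout$genotype, cohort = env$layout$cohort,
                    soil_moisture_final = env$moisture)
  tab$a <- rep(c(9, 10, 11, 12, 13), each = 50) + rnorm(250, 0, 0.2)
  tab$b <- 5 + 0.01 * tab$soil_moisture_final + rnorm(250, 0, 0.2)
  tab$c <- rep(c(3, 4, 5, 6, 7), each = 50) + rnorm(250, 0, 0.2)
  models <- list(a = fit_term_set(tab, "a", "G"),
                 b = fit_term_set(tab, "b", "E"),
                 c = fit_term_set(tab, "c", "G"))
  class(models) <- "fvt_model_set"
  gm <- predict_genotype_means(models, moisture_grid(4, 30, 100))
  cons <- constraint_curves(gm, models = models)
  expect_true(all(cons$n_traits == 2))  # trait b (no G term) excluded
})
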