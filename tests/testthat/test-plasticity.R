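test_that("trait scaling gives pooled z-scores and is invertible", {
  g <- "g1"
  lv <- c(30, 65, 100)
  gm <- make_grid_means(list(a = matrix(c(1, 2, 3), 1),
                             b = matrix(c(5, 9, 7), 1)), g, lv)
  sp <- scale_traits(gm)
  expect_equal(unname(sp$matrix[, "a"]), c(-1, 0, 1))  # sd divisor n-1
  expect_lt(max(abs(colMeans(sp$matrix))), 1e-10)
  expect_lt(max(abs(apply(sp$matrix, 2, sd) - 1)), 1e-10)
  expect_lt(max(abs(unscale_traits(sp) -
                      cbind(a = c(1, 2, 3), b = c(5, 9, 7)))), 1e-12)
})

test_that("constant traits are rejected by name (or dropped on request)", {
  gm <- make_grid_means(list(flat = matrix(2, 2, 3),
                             ok = matrix(rnorm(6), 2)),
                        paste0("g", 1:2), c(30, 60, 100))
  expect_error(scale_traits(gm), "flat")
  expect_warning(sp <- scale_traits(gm, on_constant = "drop"), "flat")
  expect_identical(colnames(sp$matrix), "ok")
})

test_that("scaling the pool then subsetting differs from scaling a subset", {
  g <- paste0("g", 1:2)
  lv <- c(30, 60, 100)
  vals <- matrix(c(0, 1, 10, 0, 2, 30), 2, byrow = TRUE)
  gm <- make_grid_means(list(a = vals, b = -vals + 1), g, lv)
  pooled <- scale_traits(gm)
  keep <- pooled$level < 100
  pooled_sub <- pooled$matrix[keep, ]
  sub <- scale_traits(gm[gm$level < 100, ])
  expect_gt(max(abs(pooled_sub - sub$matrix)), 0.1)
})

test_that("deltaT is the Euclidean distance between consecutive levels", {
  # identical consecutive points -> 0; the 3-4-5 triangle -> exactly 5
  m <- rbind(c(0, 0), c(0, 0), c(3, 4))
  sp <- make_space(m, rep("g1", 3), c(30, 60, 100))
  d <- delta_T(sp)
  expect_equal(d$deltaT, c(0, 5))
  expect_equal(d$interval, c(1L, 2L))
  expect_equal(d$moisture_from, c(30, 60))

  # brute-force per-coordinate loop oracle on random spaces
  set.seed(19)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    L <- sample(c(5, 20), 1)
    mat <- matrix(rnorm(2 * L * k), 2 * L, k)
    g <- rep(c("g1", "g2"), each = L)
    lv <- rep(seq(30, 100, length.out = L), 2)
    spc <- make_space(mat, g, lv)
    d <- delta_T(spc)
    for (gi in c("g1", "g2")) {
      rows <- mat[g == gi, , drop = FALSE]
      for (i in seq_len(L - 1)) {
        acc <- 0
        for (j in seq_len(k)) acc <- acc + (rows[i, j] - rows[i + 1, j])^2
        expect_lt(abs(d$deltaT[d$genotype == gi][i] - sqrt(acc)), 1e-12)
      }
    }
  }
})

test_that("deltaT is rotation-invariant and positively homogeneous", {
  set.seed(20)
  mat <- matrix(rnorm(40 * 4), 40, 4)
  g <- rep(paste0("g", 1:2), each = 20)
  lv <- rep(seq(30, 100, length.out = 20), 2)
  base <- delta_T(make_space(mat, g, lv))$deltaT
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(delta_T(make_space(mat %*% Q, g, lv))$deltaT, base,
               tolerance = 1e-10)
  expect_equal(delta_T(make_space(2 * mat, g, lv))$deltaT, 2 * base,
               tolerance = 1e-12)
  expect_error(delta_T(make_space(mat[-1, ], g[-1], lv[-1])), "missing")
})

test_that("species contrasts reproduce the Welch t-test", {
  mk <- function(vals1, vals2) {
    rbind(data.frame(species = "a", genotype = paste0("a", seq_along(vals1)),
                     interval = 1L, moisture_from = 30, moisture_to = 33.7,
                     deltaT = vals1, stringsAsFactors = FALSE),
          data.frame(species = "b", genotype = paste0("b", seq_along(vals2)),
                     interval = 1L, moisture_from = 30, moisture_to = 33.7,
                     deltaT = vals2, stringsAsFactors = FALSE))
  }
  res <- species_contrast(mk(c(1, 2, 3), c(4, 5, 6)))
  o <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$df, o$df, tolerance = 1e-12)
  expect_equal(res$p_value, o$p, tolerance = 1e-12)
  expect_true(res$significant)

  # identical groups: no difference
  same <- species_contrast(mk(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # swapping group labels negates t, keeps p
  swapped <- species_contrast(mk(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  # one genotype per species: untestable, flagged
  tiny <- species_contrast(mk(1, 2))
  expect_true(is.na(tiny$t) && is.na(tiny$significant))
  expect_error(species_contrast(mk(1, 2)[mk(1, 2)$species == "a", ]),
               "two species")
})

test_that("trait-space PCA satisfies the spectral identities", {
  set.seed(22)
  # perfectly collinear 2-D cloud: one axis carries all variance
  x <- rnorm(30)
  gm_line <- make_space(cbind(x, x), rep(paste0("g", 1:3), each = 10),
                        rep(seq(30, 100, length.out = 10), 3))
  p1 <- trait_space_pca(gm_line)
  expect_equal(p1$var_frac[1], 1, tolerance = 1e-12)

  mat <- matrix(rnorm(60 * 5), 60, 5)
  spc <- make_space(mat, rep(paste0("g", 1:3), each = 20),
                    rep(seq(30, 100, length.out = 20), 3))
  p <- trait_space_pca(spc)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  centered <- scale(mat, center = TRUE, scale = FALSE)
  expect_lt(max(abs(p$scores %*% t(p$loadings) - centered)), 1e-10)
  # eigenvalue sum equals total variance (trace conservation)
  expect_equal(sum(p$sdev^2), sum(diag(cov(mat))), tolerance = 1e-10)
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_along(p$sdev)) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
  expect_error(trait_space_pca(make_space(matrix(0, 3, 1), rep("g", 3),
                                          c(30, 60, 100))), "2 rows")
})
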