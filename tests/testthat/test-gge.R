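# random labelled g x e means matrix
rand_means <- function(g, e, seed, rank = NULL) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(g * e, 10, 4), g, e,
                dimnames = list(sprintf("G%02d", 1:g), sprintf("E%d", 1:e)))
    if (!is.null(rank)) {
      centered <- sweep(m, 2, colMeans(m))
      sv <- svd(centered)
      k <- seq_len(rank)
      low <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], rank) %*%
        t(sv$v[, k, drop = FALSE])
      m <- sweep(low, 2, -colMeans(m))  # add column means back
      dimnames(m) <- list(sprintf("G%02d", 1:g), sprintf("E%d", 1:e))
    }
    m
  })
}

rotate_fit <- function(fit, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  fit$genotype_coords <- fit$genotype_coords %*% R
  fit$environment_coords <- fit$environment_coords %*% R
  fit
}

test_that("environment centering and the explained-variance accounting", {
  m <- rand_means(8, 3, seed = 1)
  fit <- gge_fit(m)
  expect_equal(colSums(fit$centered), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # centering an already-centered matrix is the identity
  fit2 <- gge_fit(sweep(m, 2, colMeans(m)))
  expect_equal(fit2$centered, fit$centered)
  # rank-2 centered matrix is fully explained by the 2-D view
  fit3 <- gge_fit(rand_means(8, 4, seed = 2, rank = 2))
  expect_equal(fit3$pct_explained, 100, tolerance = 1e-9)
  # sum of squared singular values equals the SS of G + GEI in the means
  ss_gge <- sum(fit$centered^2)
  expect_equal(sum(fit$singular_values^2), ss_gge, tolerance = 1e-8)
  expect_error(gge_fit(matrix(5, 4, 3)), "degenerate")
  expect_error(gge_fit(m[1:2, ]), "design error")
})

test_that("coordinate products give the same rank-2 reconstruction under both partitions", {
  m <- rand_means(8, 3, seed = 3)
  sv <- svd(sweep(m, 2, colMeans(m)))
  truth <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  for (svp in c(1, 2)) {
    fit <- gge_fit(m, svp = svp)
    expect_equal(fit$genotype_coords %*% t(fit$environment_coords), truth,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("G+GE accounting matches the SS computed from cell means", {
  sim <- generate_met(groundnut_trial_config(seed = 30))
  m <- cell_means(sim$data)
  fit <- gge_fit(m)
  gplus_ge <- sum(sweep(unclass(m), 2, colMeans(m))^2)
  expect_equal(sum(fit$singular_values^2), gplus_ge, tolerance = 1e-8)
})

test_that("which-won-where winners equal the column argmax on exactly rank-2 data", {
  for (seed in 1:12) {
    m <- rand_means(9, 4, seed = 600 + seed, rank = 2)
    fit <- gge_fit(m)
    www <- which_won_where(fit)
    centered <- sweep(m, 2, colMeans(m))
    oracle <- rownames(m)[apply(centered, 2, which.max)]
    expect_identical(www$winners$winner, oracle)
    expect_true(all(www$winners$winner %in% www$hull_vertices))
  }
})

test_that("a genotype dominating every environment direction wins all sectors", {
  gc <- rbind(big = c(10, 0.5), a = c(-1, 1), b = c(-1, -1), c = c(0.5, 0))
  ec <- rbind(E1 = c(3, 0.2), E2 = c(2, -0.1), E3 = c(4, 0.4))
  fit <- structure(list(genotype_coords = gc, environment_coords = ec,
                        svp = 2), class = "gge_fit")
  www <- which_won_where(fit)
  expect_identical(www$winners$winner, rep("big", 3))
})

test_that("boundary environments go to the counter-clockwise sector", {
  # square hull; environment along the +x boundary ray between the
  # vertices at (1,1) and (1,-1): equal dot products, CCW sector is A's
  gc <- rbind(A = c(1, 1), B = c(-1, 1), C = c(-1, -1), D = c(1, -1))
  ec <- rbind(E1 = c(2, 0))
  fit <- structure(list(genotype_coords = gc, environment_coords = ec,
                        svp = 2), class = "gge_fit")
  www <- which_won_where(fit)
  expect_identical(www$winners$winner, "A")
})

test_that("collinear genotype geometry raises a diagnostic instead of sectors", {
  gc <- cbind(seq(-2, 2), seq(-2, 2) * 0.5)
  rownames(gc) <- sprintf("G%d", 1:5)
  ec <- rbind(E1 = c(1, 0), E2 = c(0, 1))
  fit <- structure(list(genotype_coords = gc, environment_coords = ec,
                        svp = 2), class = "gge_fit")
  expect_error(which_won_where(fit), "geometry error")
})

test_that("mean-vs-stability projections satisfy the Pythagoras identity", {
  fit <- gge_fit(rand_means(10, 3, seed = 9))
  ms <- mean_vs_stability(fit)
  d2 <- rowSums(fit$genotype_coords^2)
  expect_equal(ms$aec_projection^2 + ms$aec_deviation^2, unname(d2),
               tolerance = 1e-10)
  # a genotype at the origin projects to zero with zero deviation
  fit$genotype_coords[1, ] <- 0
  ms0 <- mean_vs_stability(fit)
  expect_equal(ms0$aec_projection[1], 0)
  expect_equal(ms0$aec_deviation[1], 0)
})

test_that("environment diagnostics: alignment, orthogonality and scaling", {
  fit <- gge_fit(rand_means(10, 4, seed = 10))
  u <- c(0.6, 0.8)
  perp <- c(-u[2], u[1])
  # controlled geometry: opposing perpendicular vectors cancel in the
  # average, so the AEC axis points along u
  ec <- rbind(par = 3 * u, orth = 2 * perp, orth2 = -2 * perp, short = 0.1 * u)
  f2 <- fit; f2$environment_coords <- ec
  d <- discriminativeness_representativeness(f2)
  expect_equal(d$cos_angle_to_aec[d$environment == "par"], 1, tolerance = 1e-10)
  expect_equal(d$cos_angle_to_aec[d$environment == "orth"], 0, tolerance = 1e-10)
  expect_false(d$classification[d$environment == "orth"] == "type-2")
  expect_identical(d$classification[d$environment == "par"], "type-2")
  expect_identical(d$classification[d$environment == "short"], "type-1")
  # doubling one environment's centered column doubles its vector length
  # under svp = 2 (exact on rank-2 data, where the 2-D coordinates carry
  # the whole column)
  m <- rand_means(10, 4, seed = 11, rank = 2)
  c1 <- sweep(m, 2, colMeans(m))
  c2 <- c1; c2[, 2] <- 2 * c2[, 2]
  len1 <- sqrt(rowSums(gge_fit(c1)$environment_coords^2))
  len2 <- sqrt(rowSums(gge_fit(c2)$environment_coords^2))
  expect_equal(len2[[2]], 2 * len1[[2]], tolerance = 1e-8)
})

test_that("ideal-genotype distances match an independent geometric construction", {
  fit <- gge_fit(rand_means(12, 3, seed = 13))
  rk <- ideal_genotype_ranking(fit)
  u <- colMeans(fit$environment_coords); u <- u / sqrt(sum(u^2))
  ideal <- u * max(drop(fit$genotype_coords %*% u))
  dist <- sqrt(colSums((t(fit$genotype_coords) - ideal)^2))
  expect_equal(rk$distance_to_ideal, unname(dist), tolerance = 1e-10)
  expect_equal(rk$rank, rank_values(dist), ignore_attr = TRUE)
  # genotype placed exactly at the ideal point is rank 1 with distance 0
  f2 <- fit
  f2$genotype_coords[3, ] <- ideal * 1.2  # becomes the new max projection
  rk2 <- ideal_genotype_ranking(f2)
  expect_equal(rk2$distance_to_ideal[3], 0, tolerance = 1e-10)
  expect_equal(rk2$rank[3], 1L)
})

test_that("winners, ideal ranking and mean ordering are rotation-invariant", {
  fit <- gge_fit(rand_means(9, 4, seed = 14, rank = 2))
  www <- which_won_where(fit)
  rk <- ideal_genotype_ranking(fit)
  ms <- mean_vs_stability(fit)
  for (angle in c(0.4, 1.9, 3.7)) {
    rf <- rotate_fit(fit, angle)
    expect_identical(which_won_where(rf)$winners$winner, www$winners$winner)
    expect_identical(ideal_genotype_ranking(rf)$rank, rk$rank)
    expect_identical(mean_vs_stability(rf)$rank_projection, ms$rank_projection)
  }
})

test_that("additive data produce a rank-1 centered matrix and a single overall winner", {
  cfg <- synthetic_config(8, 3, 2, mu = 40, genotype_sd = 4, environment_sd = 7,
                          seed = 18)
  sim <- generate_met(cfg)
  m <- cell_means(sim$data)
  fit <- gge_fit(m)
  expect_lt(fit$singular_values[2] / fit$singular_values[1], 1e-8)
  # every environment column is maximized by the best-genotype row
  centered <- sweep(unclass(m), 2, colMeans(m))
  best <- names(which.max(rowMeans(m)))
  expect_true(all(rownames(m)[apply(centered, 2, which.max)] == best))
})
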