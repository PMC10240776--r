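test_that("zero-centroid projection removes the mean and is idempotent", {
  m <- matrix(c(1, 1, 1, 3, 3, 3), 2, 3, byrow = TRUE)
  expect_equal(project_zero_centroid(m),
               matrix(c(-1, -1, -1, 1, 1, 1), 2, 3, byrow = TRUE))
  set.seed(1)
  r <- matrix(rnorm(30), 10, 3)
  p1 <- project_zero_centroid(r)
  expect_equal(project_zero_centroid(p1), p1)
  expect_centered(p1, tol = 1e-12)
})

test_that("subspace Gaussian: zero for one atom, centered, reduced variance", {
  expect_equal(sample_subspace_gaussian(1, seed = 5), matrix(0, 1, 3))
  d1 <- sample_subspace_gaussian(7, seed = 9)
  expect_centered(d1, tol = 1e-12)
  expect_identical(d1, sample_subspace_gaussian(7, seed = 9))
  # projection of an isotropic Gaussian onto the mean-zero subspace has
  # per-axis variance 1 - 1/n
  set.seed(11)
  n_draw <- 5000L
  vals <- vapply(seq_len(n_draw),
                 function(i) as.numeric(sample_subspace_gaussian(10)),
                 numeric(30))
  v <- mean(vals^2)
  se <- sqrt(2) * 0.9 / sqrt(length(vals))   # conservative s.e. of the mean square
  expect_lt(abs(v - 0.9), max(3 * se, 0.01))
})

test_that("Kabsch recovers exact rigid motions and never reflects", {
  set.seed(2)
  x <- matrix(rnorm(21), 7, 3)
  fit0 <- kabsch_superpose(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  R <- pldiff:::random_rotation()
  tau <- c(2, -1, 3)
  y <- sweep(x %*% t(R), 2, tau, "+")
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # mirrored target must still yield a proper rotation
  ym <- y %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(x, ym)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD matches a brute-force rotation search on a 4-point set", {
  set.seed(3)
  x <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1.5, 0, 0.3, 0.4, 1.9), 4, 3,
              byrow = TRUE)
  y <- x + matrix(rnorm(12, sd = 0.3), 4, 3)
  fit <- kabsch_superpose(x, y)
  # oracle: quaternion sampling plus local refinement of the same objective
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  obj <- function(q) {
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    R <- matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
                  2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
                  2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
                3, 3, byrow = TRUE)
    sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
  }
  qs <- matrix(rnorm(4 * 400), ncol = 4)
  vals <- apply(qs, 1, obj)
  best_q <- qs[which.min(vals), ]
  ref <- optim(best_q, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$rmsd, ref$value, tolerance = 1e-6)
})

test_that("TM-score is exact for identical and rigidly moved structures", {
  toy <- tiny_complex(n_res = 15)
  ca <- toy$frame$coords[toy$frame$roles == "protein", ]
  expect_equal(tm_score(ca, ca), 1.0, tolerance = 1e-12)
  expect_equal(tm_score(rigid_move(ca, 4), ca), 1.0, tolerance = 1e-9)
  expect_error(tm_score(ca, ca[1:10, ]), "equal-length")
})

test_that("TM-score matches the exhaustive fragment-seeded oracle on a 20-residue pair", {
  spec <- toy_spec(n_res = 20, n_lig = 1, seed = 8)
  ca <- pldiff:::toy_backbone(spec)
  set.seed(21)
  ca2 <- rigid_move(ca + matrix(rnorm(60, sd = 0.8), 20, 3), 6)
  got <- tm_score(ca2, ca)
  oracle <- tm_score(ca2, ca, all_seeds = TRUE)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_gt(got, 0); expect_lte(got, 1)
})

test_that("TM-score is symmetric for equal-length chains and rigid-motion invariant", {
  spec <- toy_spec(n_res = 18, n_lig = 1, seed = 12)
  ca <- pldiff:::toy_backbone(spec)
  set.seed(31)
  ca2 <- ca + matrix(rnorm(54, sd = 1.2), 18, 3)
  expect_equal(tm_score(ca, ca2), tm_score(ca2, ca), tolerance = 1e-6)
  expect_equal(tm_score(rigid_move(ca2, 7), ca), tm_score(ca2, ca),
               tolerance = 1e-6)
})

test_that("L-rms: zero on self, invariant to joint rigid motion, exact on translation", {
  toy <- tiny_complex(n_res = 10, n_lig = 4)
  ref <- toy$frame
  expect_equal(ligand_rms(ref, ref), 0, tolerance = 1e-10)
  moved <- coordinate_frame(rigid_move(ref$coords, 5), ref$roles,
                            center = FALSE)
  expect_equal(ligand_rms(moved, ref), 0, tolerance = 1e-8)
  # translate the ligand only, after perfect protein alignment
  shifted <- ref$coords
  il <- ref$roles == "ligand"
  shifted[il, 1] <- shifted[il, 1] + 2
  pred <- coordinate_frame(shifted, ref$roles, center = FALSE)
  expect_equal(ligand_rms(pred, ref), 2.0, tolerance = 1e-8)
  tm_ref <- tm_score(ref$coords[!il, ], ref$coords[!il, ])
  expect_equal(tm_ref, 1.0)
})
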