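test_that("build_system counts tokens and validates inputs", {
  lig2 <- ligand_graph(data.frame(atomic_number = c(6, 6)),
                       data.frame(atom_i = 1, atom_j = 2))
  sys <- build_system("MKV", lig2)
  expect_equal(sys$n_tokens, 5L)
  expect_equal(sys$residue_index, 1:3)
  expect_equal(sys$roles, c(rep("protein", 3), rep("ligand", 2)))
  expect_equal(nrow(sys$ligand$atoms), 2L)
  expect_equal(nrow(sys$ligand$bonds), 1L)
  expect_error(build_system("MKZ", lig2), "unknown residue")
  expect_error(build_system("", lig2))
  # size cutoff: residues + ligand heavy atoms <= max_tokens
  seq380 <- paste(rep("A", 380), collapse = "")
  lig4 <- ligand_graph(data.frame(atomic_number = rep(6, 4)))
  expect_silent(build_system(seq380, lig4))
  lig10 <- ligand_graph(data.frame(atomic_number = rep(6, 10)))
  expect_error(build_system(seq380, lig10), "max_tokens")
})

test_that("ligand_graph validates atoms and bonds and fills defaults", {
  expect_error(ligand_graph(data.frame(atomic_number = 1L)), "heavy")
  expect_error(ligand_graph(data.frame(atomic_number = c(6, 6)),
                            data.frame(atom_i = 1, atom_j = 1)), "self-bonds")
  expect_error(ligand_graph(data.frame(atomic_number = c(6, 6)),
                            data.frame(atom_i = 1, atom_j = 3)),
               "out of range")
  g <- ligand_graph(data.frame(atomic_number = c(6, 7, 8),
                               hybridization = "weird_tag"),
                    data.frame(atom_i = c(1, 2), atom_j = c(2, 3)))
  expect_equal(g$atoms$degree, c(1L, 2L, 1L))          # recomputed from bonds
  expect_true(all(g$atoms$hybridization == "other"))    # unknown -> other
})

test_that("pair features use clipped relative positions depending only on j - i", {
  lig <- ligand_graph(data.frame(atomic_number = 6))
  sys <- build_system(paste(rep("A", 60), collapse = ""), lig)
  f <- featurize_tokens(sys)
  n <- f$n
  row_of <- function(i, j) (j - 1L) * n + i
  relpos_cols <- seq_len(2L * 32L + 2L)
  # offsets beyond +/-32 share the clip bucket
  expect_equal(f$pair[row_of(1, 40), relpos_cols],
               f$pair[row_of(1, 50), relpos_cols])
  # positional channel depends only on the offset
  expect_equal(f$pair[row_of(3, 10), relpos_cols],
               f$pair[row_of(20, 27), relpos_cols])
  expect_false(identical(f$pair[row_of(1, 5), relpos_cols],
                         f$pair[row_of(5, 1), relpos_cols]))
  # pairs involving the ligand token use the not-applicable bucket
  expect_equal(f$pair[row_of(1, n), 2L * 32L + 2L], 1)
})

test_that("bonded ligand pairs carry symmetric bond features", {
  lig <- ligand_graph(data.frame(atomic_number = c(6, 6, 8)),
                      data.frame(atom_i = c(1, 2), atom_j = c(2, 3),
                                 bond_type = c("double", "single")))
  sys <- build_system("MK", lig)
  f <- featurize_tokens(sys)
  n <- f$n
  row_of <- function(i, j) (j - 1L) * n + i
  i1 <- 3L; i2 <- 4L  # ligand atoms 1 and 2 as tokens
  expect_equal(f$pair[row_of(i1, i2), ], f$pair[row_of(i2, i1), ])
  # bonded vs unbonded ligand pairs are distinguished
  expect_false(identical(f$pair[row_of(3, 4), ], f$pair[row_of(3, 5), ]))
})

test_that("distance embedding is symmetric, rigid-motion invariant, maximal at zero", {
  set.seed(4)
  co <- matrix(rnorm(15, sd = 3), 5, 3)
  e <- distance_embedding(co, k = 16, d_max = 30)
  m <- function(i, j) e[(j - 1L) * 5L + i, ]
  expect_equal(m(2, 4), m(4, 2))
  # diagonal (zero distance) activates the first center maximally
  expect_equal(m(1, 1)[1], 1)
  expect_true(all(m(1, 1)[1] >= m(1, 1)))
  e2 <- distance_embedding(rigid_move(co, 2), k = 16, d_max = 30)
  expect_equal(e, e2, tolerance = 1e-10)
})

test_that("time embedding: zero pattern at t = 0, injective, deterministic", {
  e0 <- time_embedding(0, dim = 16)
  expect_equal(e0[seq(1, 16, by = 2)], rep(0, 8))   # sines
  expect_equal(e0[seq(2, 16, by = 2)], rep(1, 8))   # cosines
  ts <- seq(0.05, 0.95, by = 0.1)
  em <- sapply(ts, time_embedding, dim = 16)
  expect_equal(ncol(unique(t(em))), 16L)
  expect_false(any(duplicated(t(em))))
  expect_identical(time_embedding(0.37), time_embedding(0.37))
  expect_error(time_embedding(1.5), "0, 1")
})

test_that("single representation: lookup structure and PLM additivity", {
  model <- tiny_model(cfg = tiny_config(plm_dim = 4L))
  lig <- ligand_graph(data.frame(atomic_number = c(6, 8)),
                      data.frame(atom_i = 1, atom_j = 2))
  sys <- build_system("MAMA", lig)
  s0 <- build_single_repr(model, sys)
  # same residue letter, no PLM -> identical rows
  expect_equal(s0[1, ], s0[3, ])
  expect_equal(s0[2, ], s0[4, ])
  expect_false(isTRUE(all.equal(s0[1, ], s0[2, ])))
  set.seed(5)
  plm <- matrix(rnorm(16), 4, 4)
  s1 <- build_single_repr(model, sys, plm = plm)
  expect_false(isTRUE(all.equal(s1[1:4, ], s0[1:4, ])))   # protein rows move
  expect_equal(s1[5:6, ], s0[5:6, ])                      # ligand rows fixed
  expect_error(build_single_repr(model, sys, plm = plm[1:3, ]), "one row")
})

test_that("toy generator: determinism, geometry, clash-free frames, splits", {
  spec <- toy_spec(n_res = 10, n_lig = 4, pocket_jitter = 0, seed = 13)
  a <- make_toy_complex(spec); b <- make_toy_complex(spec)
  expect_identical(a$frame$coords, b$frame$coords)
  expect_centered(a$frame$coords)
  ext <- toy_spec(n_res = 8, n_lig = 2, backbone_mode = "extended", seed = 2)
  fr <- make_toy_complex(ext)$frame
  ca <- fr$coords[fr$roles == "protein", ]
  expect_equal(sqrt(rowSums(diff(ca)^2)), rep(3.8, 7), tolerance = 1e-10)
  ds <- make_dataset(toy_spec(n_res = 8, n_lig = 3, seed = 4), 11)
  expect_length(ds$frames, 11L)
  expect_equal(ds$split$train, 1:9)    # ceiling(0.8 * 11)
  expect_equal(ds$split$val, 10:11)
  for (f in ds$frames) expect_gt(min(dist(f$coords)), 0.5)
})

test_that("toy dataset pocket distances match the placement distribution", {
  # Monte Carlo oracle: distance from anchor || offset + N(0, j^2 I) ||
  j <- 0.8
  spec <- toy_spec(n_res = 12, n_lig = 4, pocket_jitter = j, seed = 19)
  ds <- make_dataset(spec, 600, seed = 20)
  d <- vapply(ds$frames, pocket_distance, 1.0,
              pocket_residue = ds$pocket_residue)
  set.seed(99)
  oracle <- sqrt(rowSums((matrix(rnorm(3e4 * 3, sd = j), ncol = 3) +
                            matrix(c(4, 0, 0), 3e4, 3, byrow = TRUE))^2))
  se <- sd(oracle) / sqrt(length(d))
  # rejection sampling (clash veto) trims the close tail slightly
  expect_lt(abs(mean(d) - mean(oracle)), max(4 * se, 0.1))
  expect_lt(abs(sd(d) - sd(oracle)), 0.15)
})
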