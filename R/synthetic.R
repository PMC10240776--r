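# Deterministic toy protein-ligand generator.
#
# Desk-scale stand-in for a curated complex-structure corpus: a bead-chain
# protein (ideal helix or extended chain), a small ring-or-chain ligand placed
# next to a designated pocket residue with isotropic Gaussian placement noise.
# The generating distribution is explicit, so parameter-recovery tests have a
# closed-form (or Monte-Carlo-oracle) target.

#' Specification of a toy protein-ligand complex
#'
#' @param n_res Residue count (`>= 4`).
#' @param n_lig Ligand heavy-atom count (`>= 1`).
#' @param pocket_jitter Standard deviation (angstroms, per axis) of the
#'   Gaussian noise on the ligand placement.
#' @param backbone_mode `"helix"` (rise 1.5 A, radius 2.3 A, 100 degrees per
#'   residue) or `"extended"` (3.8 A consecutive C-alpha spacing).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `toy_spec`.
#' @export
toy_spec <- function(n_res = 12L, n_lig = 4L, pocket_jitter = 1.0,
                     backbone_mode = c("helix", "extended"), seed = 1L) {
  backbone_mode <- match.arg(backbone_mode)
  stopifnot(n_res >= 4L, n_lig >= 1L, pocket_jitter >= 0)
  structure(list(n_res = as.integer(n_res), n_lig = as.integer(n_lig),
                 pocket_jitter = pocket_jitter, backbone_mode = backbone_mode,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

toy_backbone <- function(spec) {
  i <- seq_len(spec$n_res) - 1L
  if (spec$backbone_mode == "helix") {
    theta <- i * 100 * pi / 180
    cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    cbind(3.8 * i, 0, 0)
  }
}

toy_sequence <- function(n_res) {
  paste(rep_len(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_res), collapse = "")
}

# Ligand template centered at the origin: a regular ring for >= 3 atoms
# (1.5 A bonds, closing bond included), a bonded chain otherwise.
toy_ligand <- function(n_lig) {
  els <- rep_len(c(6L, 6L, 8L, 7L), n_lig)
  if (n_lig >= 3L) {
    r <- 1.5 / (2 * sin(pi / n_lig))
    th <- 2 * pi * (seq_len(n_lig) - 1L) / n_lig
    xyz <- cbind(r * cos(th), r * sin(th), 0)
    bonds <- data.frame(atom_i = seq_len(n_lig),
                        atom_j = c(seq_len(n_lig)[-1L], 1L))
    ring <- TRUE
  } else {
    xyz <- cbind(1.5 * (seq_len(n_lig) - 1L), 0, 0)
    xyz <- project_zero_centroid(xyz)
    bonds <- if (n_lig == 2L) data.frame(atom_i = 1L, atom_j = 2L) else NULL
    ring <- FALSE
  }
  deg <- if (is.null(bonds)) rep(0L, n_lig) else
    tabulate(c(bonds$atom_i, bonds$atom_j), nbins = n_lig)
  atoms <- data.frame(atomic_number = els,
                      degree = deg,
                      n_hydrogens = pmax(0L, 3L - deg),
                      hybridization = "sp3",
                      is_in_ring = ring)
  list(graph = ligand_graph(atoms, bonds), coords = xyz)
}

# One draw of the ligand placement: rigid random orientation about its
# centroid plus isotropic Gaussian displacement of the centroid. Rejects
# placements bringing any two atoms within 0.5 A.
place_ligand <- function(lig_xyz, anchor, jitter, ca, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    R <- random_rotation()
    delta <- stats::rnorm(3L, sd = jitter)
    placed <- sweep(lig_xyz %*% t(R), 2L, anchor + delta, "+")
    all_xyz <- rbind(ca, placed)
    if (min(stats::dist(all_xyz)) > 0.5) return(placed)
  }
  stop("could not place ligand without steric clash; reduce pocket_jitter")
}

#' Generate one toy complex
#'
#' Builds the bead-chain protein, places the ligand adjacent to the pocket
#' residue (the middle residue, 4 A outward from the backbone) with Gaussian
#' placement noise of `pocket_jitter`, and returns zero-centered coordinates.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [toy_spec()].
#' @return A list with `system` (a [build_system()] result), `frame` (a
#'   centered [coordinate_frame()]), and `pocket_residue` (index of the
#'   anchor residue).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  out <- toy_complex_draw(spec)
  out
}

toy_complex_draw <- function(spec) {
  ca <- toy_backbone(spec)
  lig <- toy_ligand(spec$n_lig)
  pocket <- as.integer(ceiling(spec$n_res / 2))
  anchor_dir <- if (spec$backbone_mode == "helix") {
    v <- ca[pocket, ] - c(0, 0, ca[pocket, 3])      # radially outward
    v / sqrt(sum(v^2))
  } else c(0, 1, 0)
  anchor <- ca[pocket, ] + 4.0 * anchor_dir
  placed <- place_ligand(lig$coords, anchor, spec$pocket_jitter, ca)
  system <- build_system(toy_sequence(spec$n_res), lig$graph)
  frame <- coordinate_frame(rbind(ca, placed), system$roles, center = TRUE)
  list(system = system, frame = frame, pocket_residue = pocket)
}

#' Generate a toy conformer dataset
#'
#' One fixed system with `n_conformers` frames drawn from the ligand placement
#' distribution: the ground-truth ensemble whose pairwise-distance statistics
#' a trained model is expected to recover. Frames are split 80/20
#' (`ceiling(0.8 n)` training frames) by index.
#'
#' @param spec A [toy_spec()].
#' @param n_conformers Number of frames (`>= 1`).
#' @param seed Integer seed for the conformer draws (the system geometry uses
#'   `spec$seed`).
#' @return A list with `system`, `frames` (list of [coordinate_frame()]),
#'   `pocket_residue`, and `split` (`$train`, `$val` index vectors).
#' @export
make_dataset <- function(spec, n_conformers, seed = spec$seed) {
  stopifnot(inherits(spec, "toy_spec"), n_conformers >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  base <- toy_complex_draw(spec)
  ca <- toy_backbone(spec)
  lig <- toy_ligand(spec$n_lig)
  pocket <- base$pocket_residue
  anchor_dir <- if (spec$backbone_mode == "helix") {
    v <- ca[pocket, ] - c(0, 0, ca[pocket, 3]); v / sqrt(sum(v^2))
  } else c(0, 1, 0)
  anchor <- ca[pocket, ] + 4.0 * anchor_dir
  set.seed(seed)
  frames <- lapply(seq_len(n_conformers), function(k) {
    placed <- place_ligand(lig$coords, anchor, spec$pocket_jitter, ca)
    coordinate_frame(rbind(ca, placed), base$system$roles, center = TRUE)
  })
  n_train <- as.integer(ceiling(0.8 * n_conformers))
  list(system = base$system, frames = frames, pocket_residue = pocket,
       split = list(train = seq_len(n_train),
                    val = if (n_train < n_conformers)
                      (n_train + 1L):n_conformers else integer(0)))
}

#' Ligand-centroid-to-pocket distance of a frame
#'
#' Convenience statistic used by recovery tests: the Euclidean distance from
#' the pocket residue's C-alpha to the ligand centroid.
#'
#' @param frame A [coordinate_frame()].
#' @param pocket_residue Index of the pocket residue among protein rows.
#' @return Distance in angstroms.
#' @export
pocket_distance <- function(frame, pocket_residue) {
  ip <- which(frame$roles == "protein")
  il <- frame$roles == "ligand"
  ca <- frame$coords[ip[pocket_residue], ]
  cen <- colMeans(frame$coords[il, , drop = FALSE])
  sqrt(sum((ca - cen)^2))
}
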