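# Zero-centroid subspace geometry and structural comparison metrics.

#' Coordinate frame for a protein-ligand complex
#'
#' Holds an `N x 3` coordinate matrix (angstroms) together with a per-row role
#' tag distinguishing protein C-alpha rows from ligand heavy-atom rows.
#'
#' @param coords `N x 3` numeric matrix.
#' @param roles Character vector of length `N` with values `"protein"` or
#'   `"ligand"`.
#' @param center If `TRUE` (default) the coordinates are projected to the
#'   zero-centroid subspace.
#' @return An object of class `coordinate_frame` with fields `coords`, `roles`,
#'   `centered`.
#' @export
coordinate_frame <- function(coords, roles, center = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  if (length(roles) != nrow(coords)) stop("one role per coordinate row")
  if (!all(roles %in% c("protein", "ligand")))
    stop("roles must be 'protein' or 'ligand'")
  if (center) coords <- project_zero_centroid(coords)
  structure(list(coords = coords, roles = roles, centered = center),
            class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat(sprintf("<coordinate_frame %d atoms (%d protein CA, %d ligand)%s>\n",
              nrow(x$coords), sum(x$roles == "protein"), sum(x$roles == "ligand"),
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Project coordinates onto the zero-centroid subspace
#'
#' Subtracts the centroid so the mean position is the origin. Idempotent.
#'
#' @param coords `N x 3` numeric matrix.
#' @return `N x 3` matrix with zero column means.
#' @export
project_zero_centroid <- function(coords) {
  coords <- as.matrix(coords)
  sweep(coords, 2L, colMeans(coords), "-")
}

#' Draw from the standard Gaussian on the zero-centroid subspace
#'
#' Draws i.i.d. standard normals per coordinate, then removes the centroid.
#' The result is the standard Gaussian restricted to the linear subspace of
#' point sets whose centroid is the origin (per-axis marginal variance
#' `1 - 1/n` after projection). For a single atom the subspace is `{0}`.
#'
#' @param n_atoms Number of atoms (rows).
#' @param seed Optional integer seed; when given the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return `n_atoms x 3` matrix with zero column means.
#' @export
sample_subspace_gaussian <- function(n_atoms, seed = NULL) {
  stopifnot(n_atoms >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  eps <- matrix(stats::rnorm(3L * n_atoms), n_atoms, 3L)
  project_zero_centroid(eps)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum_i || R mobile_i + t - target_i ||^2` with correspondence by row index.
#' Reflections are never returned: if the optimal orthogonal transform has
#' determinant -1 the smallest singular direction is flipped.
#'
#' @param mobile,target `N x 3` matrices, `N >= 3` (degenerate inputs still
#'   return a valid transform).
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `rmsd` (angstroms), and
#'   `transform(x)`, a function applying the fit to arbitrary coordinates.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target))) stop("shape mismatch")
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # target ~ mobile %*% t(R)
  trans <- as.numeric(ct - R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  transform <- function(x) sweep(as.matrix(x) %*% t(R), 2L, trans, "+")
  list(rotation = R, translation = trans, rmsd = rmsd, transform = transform)
}

# TM-score inner loop: superpose on the seed subset, then iteratively
# re-superpose on the residues within a distance cutoff, tracking the best
# score seen under any superposition along the way. Several selection
# cutoffs are tried per seed (the standard scheme), since the objective has
# many local optima for short chains.
tm_refine <- function(pred, ref, seed_idx, d0, max_iter = 20L) {
  d0_search <- max(d0, 0.5)
  best <- 0
  for (d_cut0 in unique(c(d0_search, d0_search + 1, d0_search + 2.5, 5, 8))) {
    idx <- seed_idx
    prev <- integer(0)
    for (iter in seq_len(max_iter)) {
      if (length(idx) < 3L) break
      fit <- kabsch_superpose(pred[idx, , drop = FALSE],
                              ref[idx, , drop = FALSE])
      moved <- fit$transform(pred)
      d <- sqrt(rowSums((moved - ref)^2))
      best <- max(best, mean(1 / (1 + (d / d0)^2)))
      d_cut <- d_cut0
      repeat {
        keep <- which(d < d_cut)
        if (length(keep) >= 3L) break
        d_cut <- d_cut + 0.5
      }
      if (identical(keep, idx) || identical(keep, prev)) break
      prev <- idx
      idx <- keep
    }
  }
  best
}

#' TM-score between two same-sequence C-alpha traces
#'
#' Length-normalized structural similarity in `(0, 1]`:
#' `TM = max over superpositions of (1/L) sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped from below at 0.5 angstrom (the
#' standard formula goes non-positive for chains shorter than about 21
#' residues). Correspondence is one-to-one by row index (the generated and
#' reference proteins share a sequence), so no alignment step is involved; the
#' maximization uses the standard iterative scheme seeded from contiguous
#' fragments at several lengths, re-superposing on the close residues until
#' the selected set stabilizes.
#'
#' @param pred_ca,ref_ca `L x 3` C-alpha coordinate matrices, equal `L >= 3`.
#' @param all_seeds If `TRUE`, seed from every contiguous fragment of every
#'   length `>= 4` (exhaustive; used for cross-checks); otherwise the standard
#'   ladder of fragment lengths `L, L/2, L/4, ..., 4`.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(pred_ca, ref_ca, all_seeds = FALSE) {
  pred_ca <- as.matrix(pred_ca); ref_ca <- as.matrix(ref_ca)
  if (!identical(dim(pred_ca), dim(ref_ca)))
    stop("TM-score requires equal-length same-sequence chains")
  L <- nrow(pred_ca)
  if (L < 3L) stop("TM-score needs at least 3 residues")
  d0 <- if (L > 15L) max(1.24 * (L - 15)^(1/3) - 1.8, 0.5) else 0.5
  # short chains: enumerate every fragment length (cheap, avoids the local
  # optima that the spiky d0-clamped objective creates); longer chains use
  # the standard ladder of fragment lengths
  lens <- if (all_seeds || L <= 24L) seq(4L, L)
          else unique(pmax(4L, c(L, floor(L / 2), floor(L / 4),
                                 floor(L / 8), 4L)))
  best <- 0
  for (len in lens) {
    # all start positions for short chains; stride len/2 for long ones
    stride <- if (L <= 60L) 1L else max(1L, len %/% 2L)
    starts <- if (all_seeds) seq_len(L - len + 1L)
              else unique(pmin(seq(1L, L - len + 1L, by = stride),
                               L - len + 1L))
    for (s in starts) {
      idx <- s:(s + len - 1L)
      best <- max(best, tm_refine(pred_ca, ref_ca, idx, d0))
    }
  }
  best
}

#' Ligand RMSD after protein superposition (L-rms)
#'
#' Superposes the predicted frame onto the reference using protein C-alpha
#' atoms only, applies that rigid transform to the predicted ligand, and
#' returns the plain heavy-atom RMSD over ligand atoms. No graph-symmetry
#' correction is applied: atom correspondence is by index.
#'
#' @param pred,ref [coordinate_frame()] objects with matching role layouts.
#' @return L-rms in angstroms.
#' @export
ligand_rms <- function(pred, ref) {
  stopifnot(inherits(pred, "coordinate_frame"), inherits(ref, "coordinate_frame"))
  if (!identical(pred$roles, ref$roles))
    stop("frames must share the same atom roles, in the same order")
  ip <- pred$roles == "protein"; il <- pred$roles == "ligand"
  if (sum(ip) < 3L) stop("need at least 3 protein C-alpha atoms for alignment")
  if (!any(il)) stop("frames contain no ligand atoms")
  fit <- kabsch_superpose(pred$coords[ip, , drop = FALSE],
                          ref$coords[ip, , drop = FALSE])
  moved <- fit$transform(pred$coords[il, , drop = FALSE])
  sqrt(mean(rowSums((moved - ref$coords[il, , drop = FALSE])^2)))
}

# Uniform random rotation matrix (used by tests and the toy generator).
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}
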