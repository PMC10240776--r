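# Molecular system construction and input featurization.
#
# Tokens are ordered protein-first then ligand. Pair feature matrices are
# stored flattened with row index (j - 1) * N + i for the token pair (i, j)
# (column-major over an N x N grid), so as.vector(outer(u, v)) lines up with
# the (i, j) layout.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y","X")

CHIRALITY_TAGS <- c("none", "cw", "ccw", "other")
HYBRIDIZATION_TAGS <- c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
BOND_TYPE_TAGS <- c("single", "double", "triple", "aromatic", "other")
BOND_STEREO_TAGS <- c("none", "z", "e", "cis", "trans", "other")
ELEMENT_BUCKETS <- c(5, 6, 7, 8, 9, 15, 16, 17, 35, 53)  # B C N O F P S Cl Br I, then other

RELPOS_CLIP <- 32L

canon_tag <- function(x, vocab) {
  x <- tolower(as.character(x))
  ifelse(x %in% vocab, x, "other")
}

#' Construct a ligand molecular graph
#'
#' Atoms carry the nine features used for featurization (atomic number,
#' chirality, degree, formal charge, attached hydrogens, radical electrons,
#' hybridization, aromaticity, ring membership); bonds carry bond type, stereo
#' configuration and conjugation. Hydrogens are not atoms of the graph: they
#' are folded into the `n_hydrogens` count of their heavy neighbor. Unknown
#' categorical values map to an explicit `"other"` bucket.
#'
#' @param atoms A data.frame with columns `atomic_number`, and optionally
#'   `chirality`, `degree`, `formal_charge`, `n_hydrogens`,
#'   `n_radical_electrons`, `hybridization`, `is_aromatic`, `is_in_ring`
#'   (missing columns are filled with defaults; `degree` is recomputed from
#'   the bonds when absent).
#' @param bonds A data.frame with columns `atom_i`, `atom_j` (1-based), and
#'   optionally `bond_type`, `stereo`, `is_conjugated`.
#' @return An object of class `ligand_graph`.
#' @export
ligand_graph <- function(atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) < 1L) stop("ligand must have at least one heavy atom")
  if (is.null(atoms$atomic_number)) stop("atoms need an atomic_number column")
  if (any(atoms$atomic_number < 1) || any(atoms$atomic_number == 1))
    stop("ligand atoms must be heavy (atomic_number > 1)")
  n <- nrow(atoms)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(atom_i = integer(0), atom_j = integer(0),
                        bond_type = character(0), stereo = character(0),
                        is_conjugated = logical(0))
  } else {
    bonds <- as.data.frame(bonds)
    if (any(bonds$atom_i == bonds$atom_j)) stop("self-bonds are not allowed")
    if (any(bonds$atom_i < 1 | bonds$atom_i > n | bonds$atom_j < 1 | bonds$atom_j > n))
      stop("bond endpoint out of range")
  }
  fill <- function(col, default) if (is.null(atoms[[col]])) rep(default, n) else atoms[[col]]
  deg <- tabulate(c(bonds$atom_i, bonds$atom_j), nbins = n)
  atoms <- data.frame(
    atomic_number = as.integer(atoms$atomic_number),
    chirality = canon_tag(fill("chirality", "none"), CHIRALITY_TAGS),
    degree = if (is.null(atoms$degree)) deg else as.integer(atoms$degree),
    formal_charge = as.integer(fill("formal_charge", 0L)),
    n_hydrogens = as.integer(fill("n_hydrogens", 0L)),
    n_radical_electrons = as.integer(fill("n_radical_electrons", 0L)),
    hybridization = canon_tag(fill("hybridization", "other"), HYBRIDIZATION_TAGS),
    is_aromatic = as.logical(fill("is_aromatic", FALSE)),
    is_in_ring = as.logical(fill("is_in_ring", FALSE)),
    stringsAsFactors = FALSE)
  bfill <- function(col, default) if (is.null(bonds[[col]])) rep(default, nrow(bonds)) else bonds[[col]]
  bonds <- data.frame(
    atom_i = as.integer(bonds$atom_i),
    atom_j = as.integer(bonds$atom_j),
    bond_type = canon_tag(bfill("bond_type", "single"), BOND_TYPE_TAGS),
    stereo = canon_tag(bfill("stereo", "none"), BOND_STEREO_TAGS),
    is_conjugated = as.logical(bfill("is_conjugated", FALSE)),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds), class = "ligand_graph")
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("<ligand_graph %d heavy atoms, %d bonds>\n",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Build a molecular system from a sequence and a ligand graph
#'
#' The modeled entity: one token per protein residue (its C-alpha) followed by
#' one token per ligand heavy atom. The total token count is capped at
#' `max_tokens` (default 384), the size cutoff applied to training systems.
#'
#' @param sequence Amino-acid string over the 20 canonical letters plus `X`.
#' @param ligand A [ligand_graph()] (or a list coercible to one).
#' @param max_tokens Maximum residues + ligand heavy atoms.
#' @return An object of class `molecular_system` with fields `sequence`,
#'   `residue_index`, `ligand`, `n_res`, `n_lig`, `n_tokens`, `roles`.
#' @export
build_system <- function(sequence, ligand, max_tokens = 384L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters_seq <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(letters_seq), AA_LETTERS)
  if (length(bad))
    stop("unknown residue letters: ", paste(bad, collapse = ", "))
  if (!inherits(ligand, "ligand_graph"))
    ligand <- ligand_graph(ligand$atoms, ligand$bonds)
  n_res <- length(letters_seq)
  n_lig <- nrow(ligand$atoms)
  n_tokens <- n_res + n_lig
  if (n_tokens > max_tokens)
    stop(sprintf("system has %d tokens, exceeding max_tokens = %d",
                 n_tokens, max_tokens))
  structure(list(sequence = paste(letters_seq, collapse = ""),
                 residue_index = seq_len(n_res),
                 ligand = ligand,
                 n_res = n_res, n_lig = n_lig, n_tokens = n_tokens,
                 roles = c(rep("protein", n_res), rep("ligand", n_lig))),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system %d residues + %d ligand atoms = %d tokens>\n",
              x$n_res, x$n_lig, x$n_tokens))
  invisible(x)
}

one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

clamp_bucket <- function(x, lo, hi) pmin(pmax(x, lo), hi) - lo + 1L

# Per-atom ligand feature one-hot block (fixed width).
ligand_atom_features <- function(atoms) {
  el <- match(atoms$atomic_number, ELEMENT_BUCKETS)
  el[is.na(el)] <- length(ELEMENT_BUCKETS) + 1L
  cbind(one_hot(el, length(ELEMENT_BUCKETS) + 1L),
        one_hot(match(atoms$chirality, CHIRALITY_TAGS), length(CHIRALITY_TAGS)),
        one_hot(clamp_bucket(atoms$degree, 0L, 6L), 7L),
        one_hot(clamp_bucket(atoms$formal_charge, -2L, 2L), 5L),
        one_hot(clamp_bucket(atoms$n_hydrogens, 0L, 4L), 5L),
        one_hot(clamp_bucket(atoms$n_radical_electrons, 0L, 2L), 3L),
        one_hot(match(atoms$hybridization, HYBRIDIZATION_TAGS),
                length(HYBRIDIZATION_TAGS)),
        as.numeric(atoms$is_aromatic),
        as.numeric(atoms$is_in_ring))
}

ligand_bond_features <- function(bonds) {
  cbind(one_hot(match(bonds$bond_type, BOND_TYPE_TAGS), length(BOND_TYPE_TAGS)),
        one_hot(match(bonds$stereo, BOND_STEREO_TAGS), length(BOND_STEREO_TAGS)),
        as.numeric(bonds$is_conjugated))
}

n_single_feat <- function() 21L + 2L + (10L + 1L + 4L + 7L + 5L + 5L + 3L + 7L + 2L)
n_pair_feat <- function() (2L * RELPOS_CLIP + 2L) + 4L + (5L + 6L + 1L)

#' Fixed token features of a molecular system
#'
#' Deterministic one-hot encodings consumed by the learned input embeddings:
#' per-token features (amino-acid identity for protein rows, the nine atom
#' features for ligand rows, plus a token-type flag) and per-pair features
#' (relative residue-position buckets clipped at +/-32 with a dedicated
#' not-applicable bucket for pairs involving ligand tokens, a relation-type
#' block distinguishing protein-protein / protein-ligand / bonded and
#' unbonded ligand-ligand pairs, and bond features on bonded ligand pairs,
#' symmetrized).
#'
#' @param system A [build_system()] result.
#' @return A list with `single` (`N x d_s`), `pair` (`N^2 x d_p`, rows in
#'   column-major (i, j) order) and `n` (token count).
#' @export
featurize_tokens <- function(system) {
  n <- system$n_tokens; nr <- system$n_res; nl <- system$n_lig
  # --- single ---
  aa <- matrix(0, n, 21L)
  aa_idx <- match(strsplit(system$sequence, "")[[1]], AA_LETTERS)
  aa[cbind(seq_len(nr), aa_idx)] <- 1
  ttype <- cbind(as.numeric(system$roles == "protein"),
                 as.numeric(system$roles == "ligand"))
  lig <- matrix(0, n, 44L)
  if (nl > 0L) lig[(nr + 1L):n, ] <- ligand_atom_features(system$ligand$atoms)
  single <- cbind(aa, ttype, lig)
  # --- pair ---
  np <- n * n
  ii <- rep(seq_len(n), times = n)   # row (i) varies fastest
  jj <- rep(seq_len(n), each = n)
  is_p_i <- ii <= nr; is_p_j <- jj <= nr
  # relative position: 2*clip+1 offset buckets + 1 "not applicable"
  relpos <- matrix(0, np, 2L * RELPOS_CLIP + 2L)
  pp <- is_p_i & is_p_j
  off <- pmin(pmax(jj[pp] - ii[pp], -RELPOS_CLIP), RELPOS_CLIP) + RELPOS_CLIP + 1L
  relpos[cbind(which(pp), off)] <- 1
  relpos[!pp, 2L * RELPOS_CLIP + 2L] <- 1
  # relation type + bond features
  bond_feat <- matrix(0, np, 12L)
  bonded <- rep(FALSE, np)
  if (nl > 0L && nrow(system$ligand$bonds) > 0L) {
    b <- system$ligand$bonds
    bi <- nr + b$atom_i; bj <- nr + b$atom_j
    bf <- ligand_bond_features(b)
    for (k in seq_len(nrow(b))) {
      r1 <- (bj[k] - 1L) * n + bi[k]
      r2 <- (bi[k] - 1L) * n + bj[k]
      bond_feat[r1, ] <- bf[k, ]; bond_feat[r2, ] <- bf[k, ]
      bonded[c(r1, r2)] <- TRUE
    }
  }
  rel_type <- cbind(as.numeric(pp),
                    as.numeric(xor(is_p_i, is_p_j)),
                    as.numeric(!is_p_i & !is_p_j & !bonded),
                    as.numeric(bonded))
  pair <- cbind(relpos, rel_type, bond_feat)
  list(single = single, pair = pair, n = n)
}

#' Radial basis embedding of pairwise distances
#'
#' Gaussian radial basis functions on the pairwise Euclidean distance matrix,
#' with `k` centers evenly spanning `[0, d_max]` and width equal to the center
#' spacing. Symmetric in (i, j) and invariant to rigid motion of the input;
#' recomputed from the current latent coordinates at every denoising call.
#'
#' @param coords `N x 3` matrix (angstroms).
#' @param k Number of basis centers.
#' @param d_max Span of the centers in angstroms.
#' @return `N^2 x k` matrix, rows in column-major (i, j) order.
#' @export
distance_embedding <- function(coords, k = 64L, d_max = 30) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.vector(as.matrix(stats::dist(coords)))  # n x n, column-major; diag 0
  if (n == 1L) d <- 0
  centers <- seq(0, d_max, length.out = k)
  width <- if (k > 1L) centers[2] - centers[1] else d_max
  exp(-(outer(d, centers, "-"))^2 / (2 * width^2))
}

#' Sinusoidal embedding of diffusion time
#'
#' Interleaved `sin`/`cos` features at geometrically spaced frequencies
#' `omega_k = (pi / 2) * 2^k`. At `t = 0` all sines are 0 and all cosines 1;
#' the leading frequency is injective on `[0, 1]`.
#'
#' @param t Scalar diffusion time in `[0, 1]`.
#' @param dim Embedding width (even).
#' @return Numeric vector of length `dim`.
#' @export
time_embedding <- function(t, dim = 32L) {
  check_time(t)
  stopifnot(length(t) == 1L, dim %% 2L == 0L)
  omega <- (pi / 2) * 2^(seq_len(dim %/% 2L) - 1L)
  as.numeric(rbind(sin(omega * t), cos(omega * t)))
}
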