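# Readers and writers: FASTA sequences, ligand graphs (SDF/MOL via ChemmineR,
# plus a minimal JSON dialect), complex PDB files (bio3d), multi-model PDB
# ensembles (hand-written fixed-width records; bio3d has no multi-MODEL
# writer), PLM embedding tables, YAML run configuration, TSV metrics, and
# versioned checkpoints.
#
# Conventions: single chain, single ligand; residue numbering is 1-based
# (PDB convention) at this layer, token indices elsewhere are row indices.

ELEMENT_SYMS <- c("H", "D", "B", "C", "N", "O", "F", "NA", "MG", "P", "S",
                  "CL", "K", "CA", "FE", "ZN", "SE", "BR", "I")
ELEMENT_NUMS <- c(1L, 1L, 5L, 6L, 7L, 8L, 9L, 11L, 12L, 15L, 16L,
                  17L, 19L, 20L, 26L, 30L, 34L, 35L, 53L)

element_to_z <- function(sym) {
  z <- ELEMENT_NUMS[match(toupper(sym), ELEMENT_SYMS)]
  if (any(is.na(z)))
    stop("unknown element symbol: ", paste(unique(sym[is.na(z)]), collapse = ", "))
  z
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA file.
#' @return Character scalar (the sequence), named by the record header.
#' @export
read_fasta <- function(path) {
  set_ <- Biostrings::readAAStringSet(path)
  if (length(set_) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set_)
  stats::setNames(seqs[1L], names(set_)[1L])
}

#' Write a single-record FASTA file
#'
#' @param sequence Amino-acid string.
#' @param path Output file.
#' @param name Record header.
#' @export
write_fasta <- function(sequence, path, name = "protein") {
  writeLines(c(paste0(">", name), sequence), path)
  invisible(path)
}

#' Read a per-residue embedding matrix
#'
#' A whitespace-separated table, one row per residue.
#'
#' @param path Table file.
#' @return Numeric matrix.
#' @export
read_plm <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

## ---- ligand input ----

#' Read a ligand molecular graph
#'
#' Dispatches on the file extension: `.json` uses the minimal JSON dialect
#' (`atoms`: a list of feature records; `bonds`: a list of
#' `[i, j, type, stereo, conjugated]`); anything else is parsed as an SDF/MOL
#' file. Explicit hydrogens are stripped and folded into the `n_hydrogens`
#' count of their heavy neighbor.
#'
#' @param path Ligand file.
#' @return A [ligand_graph()].
#' @export
read_ligand <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_ligand_json(path)
  else read_ligand_sdf(path)
}

read_ligand_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$atoms) || length(obj$atoms) == 0L)
    stop("ligand JSON has no atoms")
  atoms <- do.call(rbind, lapply(obj$atoms, function(a)
    data.frame(atomic_number = a$atomic_number,
               chirality = a$chirality %||% "none",
               degree = a$degree %||% NA_integer_,
               formal_charge = a$formal_charge %||% 0L,
               n_hydrogens = a$n_hydrogens %||% 0L,
               n_radical_electrons = a$n_radical_electrons %||% 0L,
               hybridization = a$hybridization %||% "other",
               is_aromatic = a$is_aromatic %||% FALSE,
               is_in_ring = a$is_in_ring %||% FALSE)))
  if (all(is.na(atoms$degree))) atoms$degree <- NULL
  bonds <- if (length(obj$bonds))
    do.call(rbind, lapply(obj$bonds, function(b)
      data.frame(atom_i = b[[1]], atom_j = b[[2]],
                 bond_type = if (length(b) >= 3) b[[3]] else "single",
                 stereo = if (length(b) >= 4) b[[4]] else "none",
                 is_conjugated = if (length(b) >= 5) isTRUE(b[[5]]) else FALSE)))
  ligand_graph(atoms, bonds)
}

#' Write a ligand graph in the JSON dialect
#'
#' @param graph A [ligand_graph()].
#' @param path Output file.
#' @export
write_ligand_json <- function(graph, path) {
  atoms <- lapply(seq_len(nrow(graph$atoms)), function(i)
    as.list(graph$atoms[i, ]))
  bonds <- lapply(seq_len(nrow(graph$bonds)), function(i) {
    b <- graph$bonds[i, ]
    list(b$atom_i, b$atom_j, b$bond_type, b$stereo, b$is_conjugated)
  })
  jsonlite::write_json(list(atoms = atoms, bonds = bonds), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_ligand_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  if (length(sdfs) == 0L) stop("unparsable SDF/MOL file: ", path)
  sdf <- sdfs[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_.*$", "", rownames(ab))
  z <- element_to_z(sym)
  n_all <- length(z)
  bi <- if (NROW(bb)) as.integer(bb[, 1L]) else integer(0)
  bj <- if (NROW(bb)) as.integer(bb[, 2L]) else integer(0)
  border <- if (NROW(bb)) as.integer(bb[, 3L]) else integer(0)
  is_h <- z == 1L
  # explicit hydrogens fold into the heavy neighbor's count
  n_h <- integer(n_all)
  for (k in seq_along(bi)) {
    if (is_h[bi[k]] && !is_h[bj[k]]) n_h[bj[k]] <- n_h[bj[k]] + 1L
    if (is_h[bj[k]] && !is_h[bi[k]]) n_h[bi[k]] <- n_h[bi[k]] + 1L
  }
  keep <- which(!is_h)
  if (length(keep) == 0L) stop("ligand has no heavy atoms")
  remap <- match(seq_len(n_all), keep)
  bkeep <- !is_h[bi] & !is_h[bj]
  bi <- remap[bi[bkeep]]; bj <- remap[bj[bkeep]]; border <- border[bkeep]
  n <- length(keep)
  # ring membership: an atom is in a ring iff it touches a non-bridge edge
  in_ring <- rep(FALSE, n)
  aromatic_atom <- rep(FALSE, n)
  if (length(bi)) {
    g <- igraph::graph_from_edgelist(cbind(bi, bj), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_edge <- setdiff(seq_along(bi), as.integer(br))
    in_ring[unique(c(bi[ring_edge], bj[ring_edge]))] <- TRUE
    arom_edge <- which(border == 4L)
    aromatic_atom[unique(c(bi[arom_edge], bj[arom_edge]))] <- TRUE
  }
  hyb <- vapply(seq_len(n), function(a) {
    inc <- which(bi == a | bj == a)
    ords <- border[inc]
    if (any(ords == 3L) || sum(ords == 2L) >= 2L) "sp"
    else if (any(ords == 2L) || any(ords == 4L)) "sp2"
    else "sp3"
  }, "")
  charge <- if ("charge" %in% colnames(ab)) {
    ch <- as.integer(ab[keep, "charge"])
    # V2000 atom-block charge codes: 0 none, 1:+3 ... 7:-3
    ifelse(ch == 0L, 0L, 4L - ch)
  } else rep(0L, n)
  atoms <- data.frame(
    atomic_number = z[keep],
    chirality = "none",
    formal_charge = charge,
    n_hydrogens = n_h[keep],
    n_radical_electrons = 0L,
    hybridization = hyb,
    is_aromatic = aromatic_atom,
    is_in_ring = in_ring)
  bonds <- if (length(bi))
    data.frame(atom_i = bi, atom_j = bj,
               bond_type = c("single", "double", "triple",
                             "aromatic")[pmin(border, 4L)],
               stereo = "none",
               is_conjugated = border == 4L)
  ligand_graph(atoms, bonds)
}

## ---- PDB input ----

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Read a protein-ligand complex from a PDB file
#'
#' Extracts one C-alpha per residue from the single protein chain (choosing
#' the highest-occupancy, then alphabetically first, alternate location) and
#' the heavy atoms of the single non-water HETATM ligand. Hydrogens and
#' waters are dropped; residues without a C-alpha are skipped with a warning.
#' Ligand bonds are inferred from inter-atom distances (1.9 angstrom cutoff)
#' since PDB files carry no bond orders.
#'
#' @param path PDB file.
#' @return A list with `system` (a [build_system()] skeleton), `frame` (an
#'   uncentered [coordinate_frame()] echoing the file coordinates), and
#'   `resno` (the original residue numbers).
#' @export
read_complex_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein ATOM records in ", path)
  chains <- unique(prot$chain)
  if (length(chains) > 1L)
    stop("multiple protein chains are out of scope (found: ",
         paste(chains, collapse = ", "), ")")
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  resids <- unique(prot$resno)
  rows <- integer(0); resno_kept <- integer(0); seq3 <- character(0)
  for (rn in resids) {
    cand <- ca[ca$resno == rn, , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning("residue ", rn, " has no C-alpha; skipped")
      next
    }
    cand <- cand[order(-cand$o, cand$alt, na.last = TRUE), , drop = FALSE]
    rows <- c(rows, as.integer(rownames(cand)[1L]))
    resno_kept <- c(resno_kept, rn)
    seq3 <- c(seq3, cand$resid[1L])
  }
  seq1 <- suppressWarnings(bio3d::aa321(seq3))
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  het <- at[at$type == "HETATM" & !(at$resid %in% WATER_RESNAMES), ,
            drop = FALSE]
  elem <- toupper(ifelse(is.na(het$elesy) | het$elesy == "",
                         substr(gsub("[0-9 ]", "", het$elety), 1L, 2L),
                         het$elesy))
  heavy <- het[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(heavy) == 0L) stop("no ligand heavy atoms in ", path)
  lig_ids <- unique(paste(heavy$resid, heavy$resno, heavy$chain))
  if (length(lig_ids) > 1L)
    stop("multiple ligands are out of scope (found: ",
         paste(lig_ids, collapse = "; "), ")")
  elem_heavy <- toupper(ifelse(is.na(heavy$elesy) | heavy$elesy == "",
                               substr(gsub("[0-9 ]", "", heavy$elety), 1L, 2L),
                               heavy$elesy))
  lig_xyz <- as.matrix(heavy[, c("x", "y", "z")])
  zed <- element_to_z(elem_heavy)
  bonds <- NULL
  if (nrow(lig_xyz) > 1L) {
    dmat <- as.matrix(stats::dist(lig_xyz))
    idx <- which(upper.tri(dmat) & dmat < 1.9, arr.ind = TRUE)
    if (nrow(idx)) bonds <- data.frame(atom_i = idx[, 1L], atom_j = idx[, 2L])
  }
  graph <- ligand_graph(data.frame(atomic_number = zed), bonds)
  system <- build_system(paste(seq1, collapse = ""), graph)
  ca_xyz <- as.matrix(prot[as.character(rows), c("x", "y", "z")])
  frame <- coordinate_frame(rbind(ca_xyz, lig_xyz), system$roles,
                            center = FALSE)
  list(system = system, frame = frame, resno = resno_kept)
}

## ---- multi-model PDB output ----

pdb_atom_line <- function(record, serial, name, resname, chain, resseq,
                          xyz, element) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resname, chain, resseq, " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' One MODEL per frame, numbered 1..n: the protein as C-alpha ATOM records on
#' chain A and the ligand as HETATM records (residue LIG) on chain L.
#' Coordinates round-trip through [read_complex_pdb()] within the fixed-width
#' PDB precision (1e-3 angstroms).
#'
#' @param ensemble A `structure_ensemble`, or a list of
#'   [coordinate_frame()]s plus a `system`.
#' @param path Output file.
#' @param system Required when `ensemble` is a plain frame list.
#' @export
write_ensemble_pdb <- function(ensemble, path, system = NULL) {
  if (inherits(ensemble, "structure_ensemble")) {
    frames <- ensemble$frames; system <- ensemble$system
  } else frames <- ensemble
  stopifnot(!is.null(system))
  seq3 <- bio3d::aa123(strsplit(system$sequence, "")[[1]])
  seq3[is.na(seq3)] <- "UNK"
  lig_z <- system$ligand$atoms$atomic_number
  lig_el <- ELEMENT_SYMS[match(lig_z, ELEMENT_NUMS)]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    co <- frames[[m]]$coords
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- character(0)
    for (i in seq_len(system$n_res))
      lines <- c(lines, pdb_atom_line("ATOM", i, " CA", seq3[i], "A",
                                      i, co[i, ], "C"))
    for (j in seq_len(system$n_lig)) {
      nm <- sprintf(" %s%d", lig_el[j], j)
      lines <- c(lines, pdb_atom_line("HETATM", system$n_res + j, nm, "LIG",
                                      "L", 1L, co[system$n_res + j, ],
                                      lig_el[j]))
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB ensemble
#'
#' @param path File written by [write_ensemble_pdb()] (or any multi-MODEL
#'   PDB with one protein chain and one ligand).
#' @return A list with `system` and `frames` (uncentered
#'   [coordinate_frame()]s).
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  first <- read_complex_pdb(path)
  n_models <- nrow(pdb$xyz)
  frames <- lapply(seq_len(n_models), function(m) {
    co <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    keep <- seq_len(first$system$n_tokens)
    coordinate_frame(co[keep, , drop = FALSE], first$system$roles,
                     center = FALSE)
  })
  list(system = first$system, frames = frames)
}

## ---- checkpoints, config, TSV ----

CHECKPOINT_VERSION <- 1L

#' Save a training checkpoint
#'
#' A single versioned file holding the model configuration and schedule, the
#' raw parameters, the running EMA shadow, and the best-validation EMA
#' snapshot used at inference.
#'
#' @param checkpoint A `pl_checkpoint` from [train_loop()] (or a bare
#'   `pl_denoiser`).
#' @param path Output file (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  model <- if (inherits(checkpoint, "pl_checkpoint")) checkpoint$model
           else checkpoint
  obj <- list(version = CHECKPOINT_VERSION,
              config = model$config, schedule = model$schedule,
              params = model$params,
              ema = model$ema, best_ema = model$best_ema,
              train_config = if (inherits(checkpoint, "pl_checkpoint"))
                checkpoint$train_config else NULL,
              log = if (inherits(checkpoint, "pl_checkpoint"))
                checkpoint$log else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `pl_denoiser` with `ema` and `best_ema` attached (plus
#'   `train_log` when present).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", obj$version)
  model <- structure(list(config = obj$config, schedule = obj$schedule,
                          params = obj$params),
                     class = "pl_denoiser")
  model$ema <- obj$ema
  model$best_ema <- obj$best_ema
  model$train_log <- obj$log
  model
}

#' Read a YAML run configuration
#'
#' Sections `schedule`, `denoiser`, `train`, `sampler` map onto
#' [noise_schedule()], [denoiser_config()], [train_config()] and
#' [sampler_config()]; every section validates before any compute starts.
#'
#' @param path YAML file.
#' @return A list with the four constructed configuration objects and any
#'   `paths`/`seed` entries.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(section, fn) {
    args <- y[[section]] %||% list()
    do.call(fn, args)
  }
  list(schedule = build("schedule", noise_schedule),
       denoiser = build("denoiser", denoiser_config),
       train = build("train", train_config),
       sampler = build("sampler", sampler_config),
       paths = y$paths, seed = y$seed)
}

#' Write per-frame ensemble metrics as TSV
#'
#' Columns: `frame_id`, `tm_score`, `l_rms`.
#'
#' @param metrics An [score_ensemble()] result.
#' @param path Output file.
#' @export
write_metrics_tsv <- function(metrics, path) {
  df <- data.frame(frame_id = seq_along(metrics$tm_score),
                   tm_score = sprintf("%.6f", metrics$tm_score),
                   l_rms = sprintf("%.6f", metrics$l_rms))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a threshold curve as TSV
#'
#' @param curve A [threshold_curve()] result.
#' @param path Output file.
#' @export
write_curve_tsv <- function(curve, path) {
  curve$threshold <- sprintf("%.4f", curve$threshold)
  curve$fraction <- sprintf("%.6f", curve$fraction)
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write toy fixtures for the end-to-end pipeline
#'
#' Emits the FASTA sequence, the JSON ligand graph, a single-model reference
#' PDB of one toy complex, and a multi-model PDB of training conformers,
#' exercising every reader in the package.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [toy_spec()].
#' @param n_conformers Training conformers written to `conformers.pdb`.
#' @return Named list of file paths.
#' @export
write_toy_fixtures <- function(dir, spec = toy_spec(), n_conformers = 60L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_complex(spec)
  ds <- make_dataset(spec, n_conformers)
  paths <- list(fasta = file.path(dir, "protein.fasta"),
                ligand = file.path(dir, "ligand.json"),
                pdb = file.path(dir, "reference.pdb"),
                conformers = file.path(dir, "conformers.pdb"))
  write_fasta(toy$system$sequence, paths$fasta, "toy_protein")
  write_ligand_json(toy$system$ligand, paths$ligand)
  write_ensemble_pdb(list(toy$frame), paths$pdb, system = toy$system)
  write_ensemble_pdb(ds$frames, paths$conformers, system = ds$system)
  paths
}
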