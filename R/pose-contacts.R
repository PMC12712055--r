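#' Read a PDB structure into an atom table
#'
#' Thin wrapper around [bio3d::read.pdb()]. The ligand flag is set by
#' HETATM residue-name match (default residue name `LIG`).
#'
#' @param path Path to a PDB file.
#' @param ligand_resname Residue name(s) marking ligand atoms.
#' @return Data frame of class `pose_structure` with columns `type, chain,
#'   resno, resid, elety, x, y, z, ligand`.
#' @export
read_structure <- function(path, ligand_resname = "LIG") {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("could not parse PDB file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path, call. = FALSE)
  if (!any(at$type == "HETATM")) {
    warning("no HETATM records in ", path, "; zero ligand atoms",
            call. = FALSE)
  }
  out <- data.frame(
    type = at$type, chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, x = at$x, y = at$y, z = at$z,
    ligand = at$type == "HETATM" & at$resid %in% ligand_resname,
    stringsAsFactors = FALSE)
  class(out) <- c("pose_structure", "data.frame")
  out
}

# minimum distance from each receptor atom set (by residue) to any ligand atom
.residue_min_dist <- function(receptor, ligand) {
  rl <- as.matrix(receptor[, c("x", "y", "z")])
  ll <- as.matrix(ligand[, c("x", "y", "z")])
  # squared distances, atoms x ligand atoms
  d2 <- outer(rowSums(rl^2), rep(1, nrow(ll))) +
    outer(rep(1, nrow(rl)), rowSums(ll^2)) - 2 * rl %*% t(ll)
  d2[d2 < 0] <- 0
  atom_min <- sqrt(apply(d2, 1, min))
  key <- paste(receptor$chain, receptor$resno, sep = "|")
  tapply(atom_min, key, min)
}

#' Receptor residues within a cutoff of the ligand
#'
#' A residue is included if any of its atoms lies within `cutoff`
#' (inclusive) of any ligand atom. All atoms present in the structure
#' participate by default; `heavy_only` restricts to non-hydrogen atoms.
#'
#' @param receptor Atom table (receptor atoms, e.g. `ligand == FALSE` rows
#'   of a [read_structure()] result).
#' @param ligand Atom table of ligand atoms (nonempty).
#' @param cutoff Distance cutoff in Angstrom (default 3.5).
#' @param heavy_only Drop hydrogens before the distance check.
#' @return Data frame `chain, resno, resid` of contacting residues.
#' @export
residues_within <- function(receptor, ligand, cutoff = 3.5,
                            heavy_only = FALSE) {
  if (nrow(ligand) == 0) stop("empty ligand atom set", call. = FALSE)
  if (nrow(receptor) == 0) stop("empty receptor atom set", call. = FALSE)
  if (heavy_only) {
    receptor <- receptor[!grepl("^H", trimws(receptor$elety)), , drop = FALSE]
    ligand <- ligand[!grepl("^H", trimws(ligand$elety)), , drop = FALSE]
  }
  mind <- .residue_min_dist(receptor, ligand)
  keys <- names(mind)[mind <= cutoff]
  all_keys <- paste(receptor$chain, receptor$resno, sep = "|")
  idx <- match(keys, all_keys)
  data.frame(chain = receptor$chain[idx], resno = receptor$resno[idx],
             resid = receptor$resid[idx], stringsAsFactors = FALSE)
}

#' Pose ensemble container
#'
#' @param receptor Receptor atom table (no ligand atoms).
#' @param poses List of ligand atom tables, one per docking pose; the
#'   receptor is fixed across poses.
#' @return An object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(receptor, poses) {
  stopifnot(length(poses) >= 1)
  structure(list(receptor = receptor, poses = poses),
            class = "pose_ensemble")
}

#' Per-residue ligand contact frequency across a pose ensemble
#'
#' For every receptor residue, the fraction of docking poses in which at
#' least one of its atoms lies within `cutoff` of the ligand. Residues that
#' contact no pose are omitted (fraction 0). Fractions are multiples of
#' `1/n_poses` by construction.
#'
#' @param ensemble A [pose_ensemble()].
#' @param cutoff Distance cutoff in Angstrom (default 3.5).
#' @param heavy_only Passed to [residues_within()].
#' @return Data frame of class `contact_profile`, sorted by descending
#'   fraction: `chain, resno, resid, n_contact, fraction, n_poses`.
#' @export
contact_frequency <- function(ensemble, cutoff = 3.5, heavy_only = FALSE) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  n <- length(ensemble$poses)
  tallies <- new.env(parent = emptyenv())
  info <- new.env(parent = emptyenv())
  for (pose in ensemble$poses) {
    hits <- residues_within(ensemble$receptor, pose, cutoff, heavy_only)
    if (nrow(hits) == 0) next
    keys <- paste(hits$chain, hits$resno, sep = "|")
    for (i in seq_along(keys)) {
      k <- keys[i]
      tallies[[k]] <- (if (is.null(tallies[[k]])) 0L else tallies[[k]]) + 1L
      info[[k]] <- hits[i, ]
    }
  }
  keys <- ls(tallies)
  if (length(keys) == 0) {
    out <- data.frame(chain = character(), resno = integer(),
                      resid = character(), n_contact = integer(),
                      fraction = numeric(), n_poses = integer())
  } else {
    rows <- do.call(rbind, lapply(keys, function(k) info[[k]]))
    out <- data.frame(rows,
                      n_contact = vapply(keys, function(k) tallies[[k]],
                                         integer(1)),
                      row.names = NULL, stringsAsFactors = FALSE)
    out$fraction <- out$n_contact / n
    out$n_poses <- n
    out <- out[order(-out$fraction, out$resno), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("contact_profile", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

#' Generate a toy docking-pose ensemble with planned contact fractions
#'
#' Builds a synthetic receptor of well-separated single-atom residues (20 A
#' spacing) and `n_poses` ligand copies positioned so that each planned
#' residue is within 3.5 A of the ligand in exactly
#' `round(fraction * n_poses)` poses: in a contacting pose the ligand
#' carries an atom ~1-2.5 A from that residue; in all other poses the
#' nearest ligand atom is >= 15 A away. Two never-contacted decoy residues
#' are added. This is a synthetic fixture for exercising the contact
#' quantification, not a physical pose model.
#'
#' @param n_poses Number of poses (>= 1).
#' @param contact_plan Named numeric vector, residue name (e.g. `"PHE1715"`
#'   is not required — any 1-3 letter residue code works) to planned
#'   contact fraction in `[0, 1]`. May be empty (all frequencies 0).
#' @param seed Integer seed for the small positional jitter.
#' @return A [pose_ensemble()] with attribute `plan` (the realized
#'   per-residue contact counts).
#' @export
generate_toy_pose_ensemble <- function(n_poses, contact_plan = c(),
                                       seed = 1L) {
  stopifnot(n_poses >= 1)
  fracs <- as.numeric(contact_plan)
  if (length(fracs) > 0 && (any(!is.finite(fracs)) || any(fracs < 0) ||
                            any(fracs > 1))) {
    stop("contact fractions must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  res_names <- names(contact_plan)
  if (length(contact_plan) > 0 && is.null(res_names)) {
    res_names <- sprintf("R%02d", seq_along(contact_plan))
  }
  all_names <- c(res_names, "DC1", "DC2")   # two decoys, never contacted
  n_res <- length(all_names)
  pos_x <- (seq_len(n_res) - 1) * 20       # 20 A spacing along x
  receptor <- data.frame(
    type = "ATOM", chain = "A", resno = seq_len(n_res),
    resid = substr(all_names, 1, 3), elety = "CA",
    x = pos_x, y = 0, z = 0, ligand = FALSE, stringsAsFactors = FALSE)
  counts <- if (length(fracs)) round(fracs * n_poses) else integer(0)
  anchor_y <- 40                            # far from every residue
  poses <- lapply(seq_len(n_poses), function(j) {
    contact_idx <- which(counts >= j)       # residue r contacts poses 1..k_r
    xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
    for (r in contact_idx) {
      # within the 3.5 A cutoff, jittered but safely inside
      off <- stats::runif(3, -0.8, 0.8)
      off <- off / max(1, sqrt(sum(off^2)) / 1.5)
      xs <- c(xs, pos_x[r] + off[1]); ys <- c(ys, 1 + off[2])
      zs <- c(zs, off[3])
    }
    # anchor atom keeps the ligand nonempty and far from all residues
    xs <- c(xs, stats::runif(1, -5, 5))
    ys <- c(ys, anchor_y + stats::runif(1, 0, 5))
    zs <- c(zs, stats::runif(1, -2, 2))
    data.frame(type = "HETATM", chain = "L", resno = 9000L,
               resid = "LIG", elety = sprintf("C%d", seq_along(xs)),
               x = xs, y = ys, z = zs, ligand = TRUE,
               stringsAsFactors = FALSE)
  })
  ens <- pose_ensemble(receptor, poses)
  attr(ens, "plan") <- data.frame(residue = res_names,
                                  fraction = fracs,
                                  n_contact = counts)
  ens
}

#' Write a pose ensemble as PDB files
#'
#' Writes `receptor.pdb` plus one `pose_###.pdb` per docking pose (ligand
#' as HETATM records with residue name `LIG`) into a directory.
#'
#' @param ensemble A [pose_ensemble()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written pose paths, invisibly;
#'   the receptor path is the first element.
#' @export
write_pose_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_atoms <- function(at, path) {
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
      type = at$type, resno = at$resno, resid = at$resid,
      eleno = seq_len(nrow(at)), elety = at$elety, chain = at$chain)
    path
  }
  rp <- write_atoms(ensemble$receptor, file.path(dir, "receptor.pdb"))
  pp <- vapply(seq_along(ensemble$poses), function(j) {
    write_atoms(ensemble$poses[[j]],
                file.path(dir, sprintf("pose_%03d.pdb", j)))
  }, character(1))
  invisible(c(rp, pp))
}

#' Read a pose ensemble from PDB files
#'
#' @param receptor_path Receptor PDB.
#' @param pose_paths One PDB per pose; ligand atoms are the HETATM records
#'   whose residue name matches `ligand_resname`.
#' @param ligand_resname Ligand residue name(s).
#' @return A [pose_ensemble()].
#' @export
read_pose_ensemble <- function(receptor_path, pose_paths,
                               ligand_resname = "LIG") {
  receptor <- read_structure(receptor_path, ligand_resname)
  receptor <- receptor[!receptor$ligand, , drop = FALSE]
  poses <- lapply(pose_paths, function(p) {
    s <- suppressWarnings(read_structure(p, ligand_resname))
    lig <- s[s$ligand, , drop = FALSE]
    if (nrow(lig) == 0) stop("no ligand atoms in pose file ", p,
                             call. = FALSE)
    lig
  })
  pose_ensemble(receptor, poses)
}
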