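# Residue-level protein-ligand interaction fingerprints.
#
# Interactions are detected with generic geometric criteria (all cutoffs are
# arguments): hydrophobic contact between apolar heavy atoms within 4.5 A,
# and hydrogen bonds with donor-acceptor distance <= 3.5 A plus a
# donor-H-acceptor angle >= 120 degrees whenever explicit hydrogens are
# present. Fluorine counts as apolar/hydrophobic on the ligand side (the
# perfluoroalkyl chain is the hydrophobic moiety of a PFAS) and is not a
# hydrogen-bond acceptor by default.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "TIP", "SOL")
LIGAND_APOLAR <- c("C", "S", "F", "CL", "BR", "I")
RESIDUE_APOLAR <- c("C", "S")
PLIF_BITS <- c("hydrophobic_contact", "hbond_donor_to_ligand",
               "hbond_acceptor_from_ligand")

#' Parse a protein-ligand complex from a PDB file
#'
#' Protein `ATOM` records are grouped by residue (key `chain:RESNOresno`,
#' e.g. `"A:LEU10"`); the ligand is selected among non-water `HETATM`
#' residues either by residue name or by `"chain:resno"`. Waters are
#' ignored entirely, so selecting a water name is an error, as is a
#' selector matching zero or several ligand instances.
#'
#' @param path PDB file.
#' @param ligand Ligand selector: a HETATM residue name (e.g. `"LIG"`) or
#'   `"chain:resno"`.
#' @return A `plif_complex`: list with data frames `residues` (columns
#'   `residue_key`, `resname`, `atom`, `element`, `x`, `y`, `z`) and
#'   `ligand` (same minus `residue_key`).
#' @export
parse_complex <- function(path, ligand) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at$element <- toupper(trimws(ifelse(
    is.na(at$elesy) | !nzchar(trimws(at$elesy)),
    substr(trimws(at$elety), 1, 1), at$elesy
  )))
  at <- at[!at$resid %in% WATER_RESNAMES, , drop = FALSE]
  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM", , drop = FALSE]
  if (grepl(":", ligand, fixed = TRUE)) {
    sel <- strsplit(ligand, ":", fixed = TRUE)[[1]]
    pick <- het$chain == sel[1] & het$resno == as.integer(sel[2])
  } else {
    pick <- het$resid == ligand
  }
  lig <- het[pick, , drop = FALSE]
  n_instances <- nrow(unique(lig[, c("chain", "resno", "resid")]))
  if (n_instances != 1L) {
    stop("ligand selector '", ligand, "' matches ", n_instances,
         " residue instance(s); expected exactly 1 (waters are ignored)")
  }
  residues <- data.frame(
    residue_key = sprintf("%s:%s%d", prot$chain, prot$resid, prot$resno),
    resname = prot$resid, atom = trimws(prot$elety),
    element = prot$element,
    x = prot$x, y = prot$y, z = prot$z, stringsAsFactors = FALSE
  )
  ligand_df <- data.frame(
    atom = trimws(lig$elety), element = lig$element,
    x = lig$x, y = lig$y, z = lig$z, stringsAsFactors = FALSE
  )
  structure(list(residues = residues, ligand = ligand_df,
                 ligand_name = ligand), class = "plif_complex")
}

#' @export
print.plif_complex <- function(x, ...) {
  cat("Protein-ligand complex:", length(unique(x$residues$residue_key)),
      "residues,", nrow(x$ligand), "ligand atoms\n")
  invisible(x)
}

#' Apply a rigid-body transform to a complex
#'
#' Rotates and translates every atom; interaction geometry (distances and
#' angles) is preserved exactly.
#'
#' @param cx A [parse_complex()] object.
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 offset.
#' @return The transformed `plif_complex`.
#' @export
transform_complex <- function(cx, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, "+")
    df[, c("x", "y", "z")] <- xyz
    df
  }
  cx$residues <- move(cx$residues)
  cx$ligand <- move(cx$ligand)
  cx
}

#' Uniformly distributed random rotation matrix
#'
#' Drawn from the current RNG state (set a seed for reproducibility).
#'
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation_matrix <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

pairwise_dist <- function(a, b) {
  # a, b: data frames with x, y, z
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * tcrossprod(am, bm)
  sqrt(pmax(d2, 0))
}

#' Detect hydrophobic contacts
#'
#' A residue is flagged when any apolar ligand heavy atom (C, S, or a
#' halogen including F) lies within `cutoff` of any apolar residue heavy
#' atom (C or S).
#'
#' @param cx A [parse_complex()] object.
#' @param cutoff Contact distance, Angstrom.
#' @return Sorted character vector of flagged residue keys.
#' @export
detect_hydrophobic <- function(cx, cutoff = 4.5) {
  lig <- cx$ligand[cx$ligand$element %in% LIGAND_APOLAR, , drop = FALSE]
  res <- cx$residues[cx$residues$element %in% RESIDUE_APOLAR, , drop = FALSE]
  if (nrow(lig) == 0L || nrow(res) == 0L) return(character(0))
  d <- pairwise_dist(res, lig)
  hit <- apply(d <= cutoff, 1, any)
  sort(unique(res$residue_key[hit]))
}

# Hydrogens attached to each heavy atom of `df` (same molecule side):
# indices of H atoms within `bond_max` of the heavy atom.
attached_hydrogens <- function(df, heavy_idx, bond_max = 1.25) {
  h <- which(df$element == "H")
  if (length(h) == 0L) return(vector("list", length(heavy_idx)))
  d <- pairwise_dist(df[heavy_idx, , drop = FALSE], df[h, , drop = FALSE])
  lapply(seq_along(heavy_idx), function(i) h[d[i, ] <= bond_max])
}

hbond_angle_ok <- function(donor_xyz, h_xyz_list, acceptor_xyz, angle_min) {
  if (length(h_xyz_list) == 0L) return(TRUE) # no explicit H: distance-only
  for (h in h_xyz_list) {
    v1 <- donor_xyz - h
    v2 <- acceptor_xyz - h
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    if (ang >= angle_min) return(TRUE)
  }
  FALSE
}

#' Detect hydrogen bonds between residues and the ligand
#'
#' Donors and acceptors are nitrogen and oxygen atoms; an N/O with an
#' attached explicit hydrogen (within 1.25 A) is a donor, any N/O is an
#' acceptor (fluorine optionally too). A bond is flagged when the
#' donor-acceptor heavy-atom distance is at most `d_max` and, whenever the
#' donor carries explicit hydrogens, some donor-H-acceptor angle (measured
#' at the hydrogen) is at least `angle_min`; without explicit hydrogens the
#' distance criterion alone decides.
#'
#' @param cx A [parse_complex()] object.
#' @param d_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Minimum donor-H-acceptor angle, degrees.
#' @param fluorine_acceptor Treat ligand fluorine as an acceptor.
#' @return Data frame with columns `residue_key` and `direction`
#'   (`"donor_to_ligand"`: residue donates; `"acceptor_from_ligand"`:
#'   residue accepts from a ligand donor).
#' @export
detect_hbonds <- function(cx, d_max = 3.5, angle_min = 120,
                          fluorine_acceptor = FALSE) {
  res <- cx$residues
  lig <- cx$ligand
  acceptor_elements <- c("N", "O", if (fluorine_acceptor) "F")
  out <- list()
  res_no <- which(res$element %in% c("N", "O"))
  lig_no <- which(lig$element %in% c("N", "O"))
  lig_acc <- which(lig$element %in% acceptor_elements)
  res_h <- attached_hydrogens(res, res_no)
  lig_h <- attached_hydrogens(lig, lig_no)
  xyz <- function(df, i) as.numeric(df[i, c("x", "y", "z")])

  # residue donor -> ligand acceptor
  for (ii in seq_along(res_no)) {
    d_idx <- res_no[ii]
    hs <- res_h[[ii]]
    if (length(hs) == 0L) next # not a donor without an attached H
    for (a_idx in lig_acc) {
      dv <- xyz(res, d_idx) - xyz(lig, a_idx)
      if (sqrt(sum(dv^2)) > d_max) next
      h_list <- lapply(hs, function(h) xyz(res, h))
      if (hbond_angle_ok(xyz(res, d_idx), h_list, xyz(lig, a_idx),
                         angle_min)) {
        out[[length(out) + 1L]] <- data.frame(
          residue_key = res$residue_key[d_idx],
          direction = "donor_to_ligand", stringsAsFactors = FALSE
        )
        break
      }
    }
  }
  # ligand donor -> residue acceptor (any residue N/O accepts)
  for (ii in seq_along(lig_no)) {
    d_idx <- lig_no[ii]
    hs <- lig_h[[ii]]
    if (length(hs) == 0L) next
    for (a_idx in res_no) {
      dv <- xyz(lig, d_idx) - xyz(res, a_idx)
      if (sqrt(sum(dv^2)) > d_max) next
      h_list <- lapply(hs, function(h) xyz(lig, h))
      if (hbond_angle_ok(xyz(lig, d_idx), h_list, xyz(res, a_idx),
                         angle_min)) {
        out[[length(out) + 1L]] <- data.frame(
          residue_key = res$residue_key[a_idx],
          direction = "acceptor_from_ligand", stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(residue_key = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  uniq <- unique(do.call(rbind, out))
  uniq <- uniq[order(uniq$residue_key, uniq$direction), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

#' Build a residue-level interaction fingerprint
#'
#' One row per residue of the universe (sorted residue keys), three bits per
#' residue: hydrophobic contact, residue-donated hydrogen bond, and
#' residue-accepted hydrogen bond. Fingerprints built over the same universe
#' are comparable with [plif_similarity()].
#'
#' @param cx A [parse_complex()] object.
#' @param residue_universe Residue keys defining the bit order; defaults to
#'   all residues of the complex.
#' @param hydrophobic_cutoff,d_max,angle_min,fluorine_acceptor Geometric
#'   criteria (see [detect_hydrophobic()], [detect_hbonds()]).
#' @return A `plif`: logical matrix (residues x bits) with the universe as
#'   rownames.
#' @export
build_plif <- function(cx, residue_universe = NULL,
                       hydrophobic_cutoff = 4.5, d_max = 3.5,
                       angle_min = 120, fluorine_acceptor = FALSE) {
  if (is.null(residue_universe)) {
    residue_universe <- unique(cx$residues$residue_key)
  }
  residue_universe <- sort(residue_universe)
  fp <- matrix(FALSE, nrow = length(residue_universe), ncol = 3,
               dimnames = list(residue_universe, PLIF_BITS))
  hyd <- detect_hydrophobic(cx, hydrophobic_cutoff)
  fp[intersect(hyd, residue_universe), "hydrophobic_contact"] <- TRUE
  hb <- detect_hbonds(cx, d_max, angle_min, fluorine_acceptor)
  don <- intersect(hb$residue_key[hb$direction == "donor_to_ligand"],
                   residue_universe)
  acc <- intersect(hb$residue_key[hb$direction == "acceptor_from_ligand"],
                   residue_universe)
  fp[don, "hbond_donor_to_ligand"] <- TRUE
  fp[acc, "hbond_acceptor_from_ligand"] <- TRUE
  class(fp) <- c("plif", class(fp))
  fp
}

#' Tanimoto similarity of two interaction fingerprints
#'
#' @param fp_a,fp_b Fingerprints from [build_plif()] over the same residue
#'   universe.
#' @return Tanimoto coefficient in `[0, 1]`; 1 when both are empty.
#' @export
plif_similarity <- function(fp_a, fp_b) {
  if (!identical(rownames(fp_a), rownames(fp_b))) {
    stop("fingerprints were built over different residue universes")
  }
  tanimoto(as.vector(unclass(fp_a)), as.vector(unclass(fp_b)))
}

#' Write an interaction fingerprint to CSV
#'
#' @param fp A [build_plif()] fingerprint.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plif <- function(fp, path) {
  df <- data.frame(residue_key = rownames(fp),
                   as.data.frame(unclass(fp)[, , drop = FALSE]),
                   stringsAsFactors = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
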