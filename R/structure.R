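# Parsing of atomic models and the conformational-cascade descriptors:
# Kabsch superposition, domain rotation, chromophore ring flip, helix
# scissoring, atom-pair distances.

#' Read an atomic model from PDB or mmCIF
#'
#' Loads all atoms of the first model. Alternate locations other than blank
#' or 'A' are dropped with a message. Residue numbering is kept exactly as
#' deposited (author numbering).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param id model label; defaults to the file stem.
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- withCallingHandlers(
    tryCatch(
      if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
      error = function(e) stop("cannot parse ", format, " file '", path,
                               "': ", conditionMessage(e))),
    warning = function(w) {
      # known parser chatter (beta notice, absent helix/sheet records)
      if (grepl("beta version|helix/sheet|ALT records", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  at <- pdb$atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")
  if (any(!keep))
    message("dropped ", sum(!keep), " alternate-location atoms (kept blank/'A')")
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.numeric(at$resno),
    resid = as.character(at$resid), elety = as.character(at$elety),
    elesy = as.character(at$elesy %||% ""),
    x = at$x, y = at$y, z = at$z,
    o = if (!is.null(at$o)) at$o else 1,
    alt = alt[keep],
    type = as.character(at$type %||% "ATOM"),
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- ""
  new("StructureModel",
      id = id %||% sub("\\.[^.]*$", "", basename(path)), atoms = atoms)
}

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with at least `chain, resno, resid, elety, x, y, z`.
#' @param id model label.
#' @return a [StructureModel-class].
#' @export
StructureModel <- function(atoms, id = "model") {
  defaults <- list(elesy = "", o = 1, alt = "", type = "ATOM")
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  new("StructureModel", id = id, atoms = atoms)
}

#' Write a StructureModel as a PDB file
#'
#' @param structure a [StructureModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStructurePdb <- function(structure, path) {
  at <- structure@atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = at$type, resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = at$o, b = rep(0, nrow(at)),
                   elesy = at$elesy)
  invisible(path)
}

#' Resolve a Selection against a structure
#'
#' @param structure a [StructureModel-class].
#' @param sel a [Selection-class].
#' @return the matching subset of the atom table, ordered by (chain, resno,
#'   atom name) or, for ligand selections with named atoms, by the stated
#'   atom-name order.
#' @export
resolveSelection <- function(structure, sel) {
  stopifnot(is(structure, "StructureModel"), is(sel, "Selection"))
  at <- structure@atoms
  if (!is.na(sel@ligand)) {
    at <- at[at$resid == sel@ligand, , drop = FALSE]
    if (!is.na(sel@chain)) at <- at[at$chain == sel@chain, , drop = FALSE]
    if (!anyNA(sel@atomNames)) {
      at <- at[at$elety %in% sel@atomNames, , drop = FALSE]
      at <- at[order(match(at$elety, sel@atomNames)), , drop = FALSE]
    }
    return(at)
  }
  if (!is.na(sel@chain)) at <- at[at$chain == sel@chain, , drop = FALSE]
  at <- at[at$resno >= sel@residueRange[1] &
           at$resno <= sel@residueRange[2], , drop = FALSE]
  if (!anyNA(sel@atomNames))
    at <- at[at$elety %in% sel@atomNames, , drop = FALSE]
  at[order(at$chain, at$resno, at$elety), , drop = FALSE]
}

# Pair atoms present in both states by (chain, resno, elety); returns the
# two coordinate matrices in a common order.
pair_common_atoms <- function(atA, atB) {
  keyA <- paste(atA$chain, atA$resno, atA$elety)
  keyB <- paste(atB$chain, atB$resno, atB$elety)
  common <- intersect(keyA, keyB)
  if (length(common) == 0) stop("selection error: no common atoms")
  iA <- match(common, keyA); iB <- match(common, keyB)
  list(a = as.matrix(atA[iA, c("x", "y", "z")]),
       b = as.matrix(atB[iB, c("x", "y", "z")]),
       n = length(common))
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`; reflections are excluded by the determinant correction,
#' so the returned rotation always has det = +1. Aligned coordinates are
#' `mobile %*% t(rotation) + translation` (rows are atoms).
#'
#' @param mobile,reference n x 3 coordinate matrices, paired rows, n >= 3
#'   and non-collinear.
#' @return a [SuperpositionResult-class]; `rmsd` is the minimized value.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3)
    stop("need paired n x 3 coordinate sets")
  n <- nrow(mobile)
  if (n < 3) stop("ill-posed: need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (svd(P)$d[2] < 1e-8 * max(1, svd(P)$d[1]))
    stop("ill-posed: degenerate (collinear) geometry")
  H <- crossprod(P, Q)                      # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cr - R %*% cm), rmsd = rmsd,
      nAtoms = as.integer(n))
}

# Apply a superposition to a full atom table.
apply_superposition <- function(atoms, sup) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(sup@rotation) +
    matrix(sup@translation, nrow(xyz), 3, byrow = TRUE)
  atoms$x <- moved[, 1]; atoms$y <- moved[, 2]; atoms$z <- moved[, 3]
  atoms
}

#' Rotation angle and axis of a rotation matrix
#'
#' Angle from `acos((trace - 1)/2)` (argument clamped to `[-1, 1]` to absorb
#' rounding); the axis sign is fixed to a nonnegative z-component (ties:
#' nonnegative y, then x).
#'
#' @param rotation 3x3 rotation matrix, orthogonal within 1e-6.
#' @return list with `angle` (degrees in `[0, 180]`) and `axis` (unit
#'   3-vector).
#' @export
rotationAngle <- function(rotation) {
  R <- as.matrix(rotation)
  if (!identical(dim(R), c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("input is not a proper rotation matrix (within 1e-6)")
  ang <- acos(clamp1((sum(diag(R)) - 1) / 2))
  if (ang < 1e-9) return(list(angle = 0, axis = c(0, 0, 1)))
  if (abs(pi - ang) > 1e-6) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
  } else {
    # near 180 deg: R + I ~ 2 a a', take the dominant column
    M <- R + diag(3)
    axis <- M[, which.max(colSums(M^2))]
  }
  axis <- axis / sqrt(sum(axis^2))
  tol <- 1e-10
  flip <- axis[3] < -tol ||
    (abs(axis[3]) <= tol && (axis[2] < -tol ||
                             (abs(axis[2]) <= tol && axis[1] < 0)))
  if (flip) axis <- -axis
  list(angle = ang * 180 / pi, axis = axis)
}

#' Rigid-body rotation of a domain between two states
#'
#' Both states are first aligned on `alignSel` (e.g. the GAF domain, the
#' common frame of the photocycle comparisons); the rotation that then maps
#' the `measureSel` atoms of state A onto those of state B is extracted by
#' Kabsch superposition and reported as an angle. Atoms are paired by
#' (chain, residue, atom name) intersection.
#'
#' @param stateA,stateB [StructureModel-class] objects.
#' @param alignSel,measureSel [Selection-class] objects resolving to >= 3
#'   common Calpha atoms in both states.
#' @return list with `angle` (degrees), `axis`, `rmsd` of the measured-domain
#'   superposition, and `nAlign`/`nMeasure` atom counts.
#' @export
domainRotation <- function(stateA, stateB, alignSel, measureSel) {
  pA <- pair_common_atoms(resolveSelection(stateA, alignSel),
                          resolveSelection(stateB, alignSel))
  supAlign <- superpose(pA$b, pA$a)        # B into A's frame
  atB <- apply_superposition(stateB@atoms, supAlign)
  stateBaligned <- new("StructureModel", id = stateB@id, atoms = atB)
  pM <- pair_common_atoms(resolveSelection(stateA, measureSel),
                          resolveSelection(stateBaligned, measureSel))
  supM <- superpose(pM$a, pM$b)            # rotation carrying A-domain to B-domain
  ra <- rotationAngle(supM@rotation)
  list(angle = ra$angle, axis = ra$axis, rmsd = supM@rmsd,
       nAlign = pA$n, nMeasure = pM$n)
}

# Least-squares plane normal of ordered ring atoms, oriented by the
# right-hand rule over the stated atom order (Newell-style sum of cross
# products around the centroid).
oriented_plane_normal <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3) stop("ill-posed: need >= 3 ring atoms")
  C <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(C)
  if (s$d[2] < 1e-8 * max(1, s$d[1]))
    stop("ill-posed: ring atoms are collinear")
  normal <- s$v[, 3]
  rh <- c(0, 0, 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    rh <- rh + pracma::cross(C[i, ], C[j, ])
  }
  if (sum(rh * normal) < 0) normal <- -normal
  normal
}

#' Plane-flip angle of a ring between two states
#'
#' After aligning state B onto state A via `alignSel`, a least-squares plane
#' is fit to the ordered ring atoms in each state, the normals are oriented
#' by the right-hand rule over the stated atom order, and the angle between
#' the oriented normals is returned -- so a genuine ring flip exceeds 90
#' degrees. Used for the bilin D-ring reorientation between photostates.
#'
#' @param stateA,stateB [StructureModel-class] objects.
#' @param ringSel [Selection-class] resolving to >= 3 non-collinear ring
#'   atoms in both states; `atomNames` gives the ring-atom order.
#' @param alignSel [Selection-class] for the common frame.
#' @return angle in degrees, `[0, 180]`.
#' @export
planeFlipAngle <- function(stateA, stateB, ringSel, alignSel) {
  pA <- pair_common_atoms(resolveSelection(stateA, alignSel),
                          resolveSelection(stateB, alignSel))
  supAlign <- superpose(pA$b, pA$a)
  atB <- apply_superposition(stateB@atoms, supAlign)
  stateBaligned <- new("StructureModel", id = stateB@id, atoms = atB)
  ringA <- resolveSelection(stateA, ringSel)
  ringB <- resolveSelection(stateBaligned, ringSel)
  if (nrow(ringA) < 3 || nrow(ringB) < 3)
    stop("ill-posed: ring selection resolves to fewer than 3 atoms")
  nA <- oriented_plane_normal(as.matrix(ringA[, c("x", "y", "z")]))
  nB <- oriented_plane_normal(as.matrix(ringB[, c("x", "y", "z")]))
  acos(clamp1(sum(nA * nB))) * 180 / pi
}

#' Distance between two named atoms
#'
#' @param structure a [StructureModel-class].
#' @param atomA,atomB atom specifiers: either a list
#'   `list(chain =, resno =, elety =)` or a string `"chain:resno:atom"`
#'   (e.g. `"A:177:CA"`).
#' @return Euclidean distance in Angstrom.
#' @export
pairDistance <- function(structure, atomA, atomB) {
  getxyz <- function(spec) {
    if (is.character(spec)) {
      parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
      if (length(parts) != 3) stop("atom spec must be 'chain:resno:atom'")
      spec <- list(chain = parts[1], resno = as.numeric(parts[2]),
                   elety = parts[3])
    }
    at <- structure@atoms
    hit <- at$chain == spec$chain & at$resno == spec$resno &
      at$elety == spec$elety
    if (!any(hit))
      stop("atom not found: ", spec$chain, ":", spec$resno, ":", spec$elety)
    as.numeric(at[which(hit)[1], c("x", "y", "z")])
  }
  sqrt(sum((getxyz(atomA) - getxyz(atomB))^2))
}

#' Inter-helix (scissoring) angle within one state
#'
#' Each helix axis is the dominant principal direction of its Calpha set,
#' sign-fixed N-terminus to C-terminus; the acute angle between the two axes
#' is returned. Computed per state so Pr/Pfr deltas can be tabulated.
#'
#' @param state a [StructureModel-class].
#' @param selA,selB [Selection-class] objects, each resolving to >= 5
#'   consecutive Calpha atoms.
#' @return angle in degrees, `[0, 90]`.
#' @export
helixScissorAngle <- function(state, selA, selB) {
  axis_of <- function(sel) {
    at <- resolveSelection(state, sel)
    if (nrow(at) < 5) stop("ill-posed: need >= 5 Calpha atoms per helix")
    at <- at[order(at$resno), , drop = FALSE]
    xyz <- as.matrix(at[, c("x", "y", "z")])
    C <- sweep(xyz, 2, colMeans(xyz))
    ax <- svd(C)$v[, 1]
    if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
    ax
  }
  a <- axis_of(selA); b <- axis_of(selB)
  acos(clamp1(abs(sum(a * b)))) * 180 / pi
}

#' Conformational comparison report between two photostate models
#'
#' Runs the full descriptor set the photocycle comparisons use: domain
#' rotation of a measured domain in a common alignment frame, optional ring
#' flip, optional atom-pair distances in each state, and optional
#' helix-scissoring angles, each metric naming its selections.
#'
#' @param stateA,stateB [StructureModel-class] objects (e.g. Pr and Pfr).
#' @param alignSel alignment-frame [Selection-class] (e.g. GAF Calpha).
#' @param measureSel measured-domain [Selection-class] (e.g. PHY Calpha).
#' @param ringSel optional ring [Selection-class] for the flip angle.
#' @param distancePairs optional list of `list(a =, b =)` atom specifiers.
#' @param helixSels optional list of two [Selection-class] objects for the
#'   scissor angle (computed in each state).
#' @return data.frame of metric records (name, stateA, stateB, selection,
#'   value, units).
#' @export
compareStructures <- function(stateA, stateB, alignSel, measureSel,
                              ringSel = NULL, distancePairs = NULL,
                              helixSels = NULL) {
  fmt_sel <- function(s)
    if (!is.na(s@ligand)) paste0("ligand ", s@ligand)
    else sprintf("%s:%g-%g:%s", s@chain, s@residueRange[1],
                 s@residueRange[2], paste(s@atomNames, collapse = "+"))
  rows <- list()
  dr <- domainRotation(stateA, stateB, alignSel, measureSel)
  rows[[1]] <- data.frame(
    name = "domain_rotation", stateA = stateA@id, stateB = stateB@id,
    selection = paste0("align ", fmt_sel(alignSel), "; measure ",
                       fmt_sel(measureSel)),
    value = dr$angle, units = "degree", stringsAsFactors = FALSE)
  if (!is.null(ringSel)) {
    fl <- planeFlipAngle(stateA, stateB, ringSel, alignSel)
    rows[[length(rows) + 1]] <- data.frame(
      name = "ring_flip", stateA = stateA@id, stateB = stateB@id,
      selection = paste0("ring ", fmt_sel(ringSel), "; align ",
                         fmt_sel(alignSel)),
      value = fl, units = "degree", stringsAsFactors = FALSE)
  }
  for (dp in distancePairs %||% list()) {
    lab <- paste(unlist(dp$a), collapse = ":")
    lab2 <- paste(unlist(dp$b), collapse = ":")
    for (st in list(stateA, stateB)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0("pair_distance_", st@id), stateA = stateA@id,
        stateB = stateB@id, selection = paste(lab, "to", lab2),
        value = pairDistance(st, dp$a, dp$b), units = "angstrom",
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(helixSels)) {
    for (st in list(stateA, stateB)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0("helix_scissor_", st@id), stateA = stateA@id,
        stateB = stateB@id,
        selection = paste(fmt_sel(helixSels[[1]]), "vs",
                          fmt_sel(helixSels[[2]])),
        value = helixScissorAngle(st, helixSels[[1]], helixSels[[2]]),
        units = "degree", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
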