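# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# EMG by brute-force numerical convolution: Gaussian(mu, sigma) elution
# profile convolved with a one-sided Exponential(lam) tail, times amp.
emg_convolution_oracle <- function(amp, lam, mu, sigma, v) {
  vapply(v, function(vi) {
    amp * stats::integrate(function(s)
      stats::dnorm(vi - s, mean = mu, sd = sigma) * lam * exp(-lam * s),
      0, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Tetramer mole fraction by direct mass balance: root-find the free dimer
# concentration from Ctot = [D] + 2 K2 [D]^2, then Ybar = 2 K2 [D]^2 / Ctot.
yfrac_massbalance_oracle <- function(k2, cTot) {
  if (cTot == 0) return(0)
  D <- stats::uniroot(function(d) d + 2 * k2 * d^2 - cTot,
                      lower = 0, upper = cTot, tol = 1e-18)$root
  2 * k2 * D^2 / cTot
}

# Rotation matrix about an arbitrary axis (Rodrigues), independent of the
# package's internal version.
rotmat_axis <- function(angle_deg, axis) {
  th <- angle_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Quaternion composition oracle for rotation angles about a common axis.
quat_from_axis <- function(angle_deg, axis) {
  a <- axis / sqrt(sum(axis^2))
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * a)
}
quat_mult <- function(p, q) {
  c(p[1] * q[1] - sum(p[-1] * q[-1]),
    p[1] * q[-1] + q[1] * p[-1] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}
quat_angle_deg <- function(q) 2 * acos(min(1, abs(q[1]))) * 180 / pi

# Random rigid transform for frame-invariance checks.
random_rigid <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qrd <- qr(M)
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(structure, rigid) {
  at <- structure@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rigid$R) +
    matrix(rigid$t, nrow(at), 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  StructureModel(at, id = structure@id)
}

# Tiny 3-atom fixture rendered in both coordinate dialects.
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  path
}

write_mini_cif <- function(path) {
  writeLines(c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 0.00 ? 1 ALA A C 1"),
    path)
  path
}
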