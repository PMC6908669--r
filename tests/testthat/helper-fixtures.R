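# Shared fixtures: tiny hand-written PDB snippets and toy geometries.

pdb_atom_line <- function(serial, name, resname, chain, resnum, x, y, z,
                          element = substr(name, 1, 1), record = "ATOM",
                          icode = " ", altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resnum, icode, x, y, z, element)
}

# three residues with CA (+ optional extras), as PDB text
three_res_pdb <- function() {
  paste(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.0, 1.2, 0.0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0.0, 0.0),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0.0, 0.0),
    "END"), collapse = "\n")
}

# two cysteines with SG atoms a given distance apart
cys_pair_pdb <- function(sg_dist) {
  paste(c(
    pdb_atom_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "SG", "CYS", "A", 1, 0, 0, 1.8, element = "S"),
    pdb_atom_line(3, "CA", "CYS", "A", 2, 5, 0, 0),
    pdb_atom_line(4, "SG", "CYS", "A", 2, 0, 0, 1.8 + sg_dist, element = "S"),
    "END"), collapse = "\n")
}

# straight-chain structure: n beads along x, spacing (Angstrom), with CA
# atom records so contact rules need no C-alpha fallback
line_structure <- function(n, spacing = 1) {
  coords <- cbind(seq_len(n) * spacing - spacing, 0, 0)
  keys <- sprintf("A:%d:", seq_len(n))
  calpha_structure(
    data.frame(chain = "A", resnum = seq_len(n), icode = "",
               aa = rep("A", n), stringsAsFactors = FALSE),
    coords,
    atoms = data.frame(key = keys, atom = "CA", element = "C",
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE))
}

# random rotation matrix (det +1), for invariance tests
rot3 <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(st, R, shift = c(0, 0, 0)) {
  st$coords <- sweep(st$coords %*% R, 2, shift, "+")
  if (!is.null(st$atoms)) {
    xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% R
    st$atoms$x <- xyz[, 1] + shift[1]
    st$atoms$y <- xyz[, 2] + shift[2]
    st$atoms$z <- xyz[, 3] + shift[3]
  }
  if (!is.null(st$ion_sites)) {
    xyz <- as.matrix(st$ion_sites[, c("x", "y", "z")]) %*% R
    st$ion_sites$x <- xyz[, 1] + shift[1]
    st$ion_sites$y <- xyz[, 2] + shift[2]
    st$ion_sites$z <- xyz[, 3] + shift[3]
  }
  st
}

# mirror-symmetric (non-planar) two-domain toy: beads at +/- x clusters,
# symmetric under the permutation that swaps the halves
mirror_toy <- function(m = 6, gap = 4) {
  half <- sweep(make_bead_chain(m, "helix")$coords, 2, c(gap + 3, 0, 0), "+")
  coords <- rbind(half, cbind(-half[, 1], half[, 2], half[, 3]))
  calpha_structure(
    data.frame(chain = "A", resnum = seq_len(2 * m), icode = "",
               aa = "A", stringsAsFactors = FALSE),
    coords)
}
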