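test_that("PDB parsing builds the C-alpha model in file order", {
  st <- read_calpha_structure(three_res_pdb())
  expect_s3_class(st, "calpha_structure")
  expect_equal(n_residues(st), 3)
  expect_equal(st$residues$aa, c("A", "G", "S"))
  expect_equal(st$residues$resnum, 1:3)
  expect_equal(unname(st$coords[, 1]), c(0, 3.8, 7.6))

  # residue lacking a CA is dropped with a warning
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "N",  "GLY", "A", 2, 3.8, 0, 1.2),
             pdb_atom_line(3, "CA", "SER", "A", 3, 7.6, 0, 0), "END")
  expect_warning(st2 <- read_calpha_structure(paste(lines, collapse = "\n")),
                 "without a C-alpha")
  expect_equal(n_residues(st2), 2)

  # ZN HETATM captured as an ion site
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
             pdb_atom_line(3, "ZN", "ZN", "A", 90, 1, 1, 1,
                           element = "ZN", record = "HETATM"), "END")
  st3 <- read_calpha_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(st3$ion_sites), 1)
  expect_equal(st3$ion_sites$element, "ZN")
  expect_equal(unlist(st3$ion_sites[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 1, 1))
})

test_that("PDB parsing errors: format, selection, ambiguity", {
  expect_error(read_calpha_structure("not a pdb at all"), "ATOM")
  expect_error(read_calpha_structure(three_res_pdb(), chains = "Q"),
               "empty selection")
  dup <- paste(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                 pdb_atom_line(2, "CA", "GLY", "A", 1, 3.8, 0, 0)),
               collapse = "\n")
  expect_error(read_calpha_structure(dup), "ambiguous|duplicate")
})

test_that("disulfide detection applies the cutoff and closest-pair matching", {
  st <- read_calpha_structure(cys_pair_pdb(2.05))
  br <- detect_disulfides(st, sg_cutoff = 2.3)
  expect_equal(nrow(br), 1)
  expect_equal(br$sg_distance, 2.05, tolerance = 1e-9)
  expect_length(attr(br, "unpaired"), 0)

  st2 <- read_calpha_structure(cys_pair_pdb(3.0))
  br2 <- detect_disulfides(st2, sg_cutoff = 2.3)
  expect_equal(nrow(br2), 0)
  expect_length(attr(br2, "unpaired"), 2)

  # three CYS: A-B 2.0, B-C 2.2 -> closest-distance matching keeps A-B only.
  # Oracle: brute force over all pairings of SG atoms.
  lines <- c(pdb_atom_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "SG", "CYS", "A", 1, 0, 0, 0, element = "S"),
             pdb_atom_line(3, "CA", "CYS", "A", 2, 5, 0, 0),
             pdb_atom_line(4, "SG", "CYS", "A", 2, 2.0, 0, 0, element = "S"),
             pdb_atom_line(5, "CA", "CYS", "A", 3, 10, 0, 0),
             pdb_atom_line(6, "SG", "CYS", "A", 3, 4.2, 0, 0, element = "S"))
  st3 <- read_calpha_structure(paste(lines, collapse = "\n"))
  sg <- st3$atoms[st3$atoms$atom == "SG", ]
  d <- as.matrix(dist(sg[, c("x", "y", "z")]))
  cand <- which(upper.tri(d) & d <= 2.3, arr.ind = TRUE)
  # brute force: among all sets of disjoint pairs, greedy min-distance
  expect_equal(nrow(cand), 2)            # A-B (2.0) and B-C (2.2) candidates
  best <- cand[which.min(d[cand]), ]     # minimal-distance pair wins
  br3 <- detect_disulfides(st3, 2.3)
  expect_equal(nrow(br3), 1)
  expect_equal(br3$residue_a, sg$key[best[1]])
  expect_equal(br3$residue_b, sg$key[best[2]])
  expect_equal(attr(br3, "unpaired"), "A:3:")

  # no SG atoms at all is a capability error, not "no bridges"
  st4 <- read_calpha_structure(three_res_pdb())
  st4$residues$aa[1] <- "C"
  expect_error(detect_disulfides(st4), "SG")
})

test_that("disulfide detection is invariant under rigid transforms", {
  st <- read_calpha_structure(cys_pair_pdb(2.05))
  st_r <- apply_rigid(st, rot3(11), shift = c(5, -3, 2))
  expect_equal(detect_disulfides(st_r, 2.3)$sg_distance,
               detect_disulfides(st, 2.3)$sg_distance, tolerance = 1e-9)
})

test_that("ion contacts follow the any-atom rule and are monotone in radius", {
  mk <- function(atom_offsets) {
    # one residue per offset; each has one CA plus optional extra atom
    n <- length(atom_offsets)
    res <- data.frame(chain = "A", resnum = seq_len(n), icode = "", aa = "A",
                      stringsAsFactors = FALSE)
    coords <- cbind(unlist(lapply(atom_offsets, `[`, 1)), 0, 0)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(key = sprintf("A:%d:", i), atom = "CA", element = "C",
                 x = atom_offsets[[i]], y = 0, z = 0)))
    calpha_structure(res, coords, atoms = atoms,
                     ion_sites = data.frame(element = "ZN", x = 0, y = 0, z = 0))
  }
  st <- mk(list(3.0, 10))
  expect_equal(ion_contact_residues(st, "ZN", 3.5), "A:1:")
  st2 <- mk(list(3.6, 10))
  expect_length(ion_contact_residues(st2, "ZN", 3.5), 0)
  # residue with atoms at 4.0 and 3.2: any-atom rule includes it
  st3 <- mk(list(c(4.0, 3.2), 10))
  expect_equal(ion_contact_residues(st3, "ZN", 3.5), "A:1:")
  expect_error(ion_contact_residues(st, "MG", 3.5), "MG")
  # monotone in radius
  st4 <- mk(list(2.0, 3.4, 5.0, 8.0))
  r1 <- ion_contact_residues(st4, "ZN", 3.5)
  r2 <- ion_contact_residues(st4, "ZN", 6.0)
  expect_true(all(r1 %in% r2))
})

test_that("interface residues: radius rule, separation, mirror symmetry", {
  a <- line_structure(5, spacing = 3)
  shift_y <- function(st, dy) {
    st$coords[, 2] <- st$coords[, 2] + dy
    st$atoms$y <- st$atoms$y + dy
    st
  }
  b <- shift_y(line_structure(5, spacing = 3), 3.9)  # partner 3.9 A away in y
  expect_true("A:1:" %in% interface_residues(a, b, 4))
  b <- shift_y(b, 96.1)
  expect_length(interface_residues(a, b, 4), 0)

  # symmetric pair of touching chains: interface sets are mirror images.
  # Oracle: brute-force all-pairs distance check.
  b <- shift_y(b, -96.5)
  ia <- interface_residues(a, b, 4)
  ib <- interface_residues(b, a, 4)
  brute <- function(p, q, r) {
    hit <- apply(as.matrix(dist(rbind(p, q)))[seq_len(nrow(p)),
                                              nrow(p) + seq_len(nrow(q))],
                 1, min) <= r
    unname(which(hit))
  }
  expect_equal(match(ia, a$residues$key), brute(a$coords, b$coords, 4))
  expect_equal(match(ib, b$residues$key), brute(b$coords, a$coords, 4))
})

test_that("contact rules degrade gracefully to C-alpha-only with a warning", {
  a <- line_structure(4, spacing = 3)
  b <- line_structure(4, spacing = 3)
  a$atoms <- NULL
  b$coords[, 2] <- 3.5
  expect_warning(res <- interface_residues(a, b, 4), "C-alpha positions only")
  expect_true(length(res) > 0)
})

test_that("rigid transforms preserve residue keys and pairwise distances", {
  st <- read_calpha_structure(three_res_pdb())
  st_r <- apply_rigid(st, rot3(7), shift = c(1, 2, 3))
  expect_equal(st_r$residues$key, st$residues$key)
  expect_equal(as.matrix(dist(st_r$coords)), as.matrix(dist(st$coords)),
               tolerance = 1e-6)
})

test_that("residue sets round-trip through TSV with verbatim numbering", {
  st <- read_calpha_structure(three_res_pdb())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_residue_set(st, c("A:1:", "A:3:"), path)
  back <- read.delim(path)
  expect_equal(back$resnum, c(1L, 3L))
  expect_equal(back$aa, c("A", "S"))
})
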