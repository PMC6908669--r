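## Coarse-grained C-alpha structure model: PDB reading, residue keys, and the
## structural annotations used throughout (disulfide bridges, ion contacts,
## binding-interface residues).

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

#' Residue key from author (chain, resnum, icode)
#'
#' Residue identity is the author triple; numbering round-trips verbatim.
#' @keywords internal
residue_key <- function(chain, resnum, icode) {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  sprintf("%s:%d:%s", chain, as.integer(resnum), icode)
}

#' Construct a CalphaStructure
#'
#' @param residues data.frame with columns chain, resnum, icode, aa (one-letter)
#' @param coords N x 3 numeric matrix of C-alpha positions, Angstrom
#' @param atoms optional data.frame of full-atom records with columns
#'   key, atom, element, x, y, z
#' @param ion_sites optional data.frame with columns element, x, y, z
#' @return object of class `calpha_structure`
#' @export
calpha_structure <- function(residues, coords, atoms = NULL, ion_sites = NULL) {
  stopifnot(is.data.frame(residues), is.matrix(coords),
            nrow(residues) == nrow(coords), ncol(coords) == 3)
  if (nrow(residues) < 2) stop("a structure needs at least 2 residues")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  residues$icode <- ifelse(is.na(residues$icode) | residues$icode == " ",
                           "", residues$icode)
  keys <- residue_key(residues$chain, residues$resnum, residues$icode)
  if (anyDuplicated(keys)) {
    stop("ambiguous structure: duplicate (chain, resnum, icode): ",
         paste(keys[duplicated(keys)], collapse = ", "))
  }
  residues$key <- keys
  if (!is.null(atoms) && nrow(atoms) > 0) {
    bad <- setdiff(unique(atoms$key), keys)
    if (length(bad)) stop("atom records reference unknown residues: ",
                          paste(utils::head(bad, 5), collapse = ", "))
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("non-finite atom coordinates")
  }
  rownames(coords) <- keys
  structure(list(residues = residues, coords = coords,
                 atoms = atoms, ion_sites = ion_sites),
            class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("calpha_structure: %d residues, %s atom records, %d ion sites\n",
              nrow(x$residues),
              if (is.null(x$atoms)) "no" else nrow(x$atoms),
              if (is.null(x$ion_sites)) 0L else nrow(x$ion_sites)))
  invisible(x)
}

#' Number of residues
#' @export
n_residues <- function(x) nrow(x$residues)

pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Read a C-alpha coarse-grained structure from PDB-format text
#'
#' Parses fixed-column ATOM/HETATM records of the first MODEL only; altloc
#' other than blank or 'A' is ignored. Residues lacking a C-alpha atom are
#' dropped with a warning. HETATM ions whose element matches `ion_elements`
#' are collected into `ion_sites`.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#' @param chains optional chain selection (character vector)
#' @param resnum_range optional length-2 integer range of author residue numbers
#' @param ion_elements HETATM element symbols captured as ion sites
#' @param keep_atoms keep full-atom records (needed for disulfide detection and
#'   heavy-atom contact rules)
#' @return a [calpha_structure()]
#' @export
read_calpha_structure <- function(source, chains = NULL, resnum_range = NULL,
                                  ion_elements = c("ZN", "CA"),
                                  keep_atoms = TRUE) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source))
    readLines(source) else unlist(strsplit(source, "\n", fixed = TRUE))
  if (!length(lines)) stop("empty PDB input")

  ## first MODEL only
  mdl <- grep("^ENDMDL", lines)
  if (length(mdl)) lines <- lines[seq_len(mdl[1] - 1L)]

  rec <- pdb_field(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records: not PDB format?")
  al <- lines[is_atom]
  rec <- rec[is_atom]

  altloc <- pdb_field(al, 17, 17)
  ok_alt <- altloc %in% c(" ", "", "A")
  al <- al[ok_alt]; rec <- rec[ok_alt]

  atom_name <- trimws(pdb_field(al, 13, 16))
  resname <- trimws(pdb_field(al, 18, 20))
  chain <- pdb_field(al, 22, 22)
  resnum <- suppressWarnings(as.integer(pdb_field(al, 23, 26)))
  icode <- pdb_field(al, 27, 27)
  x <- suppressWarnings(as.numeric(pdb_field(al, 31, 38)))
  y <- suppressWarnings(as.numeric(pdb_field(al, 39, 46)))
  z <- suppressWarnings(as.numeric(pdb_field(al, 47, 54)))
  element <- toupper(trimws(pdb_field(al, 77, 78)))
  element[element == ""] <- toupper(substr(atom_name[element == ""], 1, 1))
  if (anyNA(resnum) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("malformed ATOM/HETATM record: not PDB fixed-column format")

  ## ion sites from HETATM
  het <- rec == "HETATM"
  ion_idx <- het & element %in% toupper(ion_elements)
  ion_sites <- if (any(ion_idx)) {
    data.frame(element = element[ion_idx], x = x[ion_idx], y = y[ion_idx],
               z = z[ion_idx], stringsAsFactors = FALSE)
  } else NULL

  ## polymer residues: ATOM records (plus HETATM MSE)
  poly <- rec == "ATOM  " | (het & resname == "MSE")
  if (!is.null(chains)) poly <- poly & chain %in% chains
  if (!is.null(resnum_range))
    poly <- poly & resnum >= resnum_range[1] & resnum <= resnum_range[2]
  if (!any(poly)) stop("empty selection after chain/range filtering")

  pk <- residue_key(chain[poly], resnum[poly], icode[poly])
  first <- !duplicated(pk)
  res_order <- pk[first]

  ca <- poly & atom_name == "CA"
  ca_keys <- residue_key(chain[ca], resnum[ca], icode[ca])
  if (anyDuplicated(ca_keys))
    stop("ambiguous structure: duplicate C-alpha for ",
         paste(unique(ca_keys[duplicated(ca_keys)]), collapse = ", "))
  missing_ca <- setdiff(res_order, ca_keys)
  if (length(missing_ca)) {
    warning(length(missing_ca), " residue(s) without a C-alpha atom dropped: ",
            paste(utils::head(missing_ca, 5), collapse = ", "))
    res_order <- setdiff(res_order, missing_ca)
  }
  if (length(res_order) < 2) stop("fewer than 2 residues with C-alpha atoms")

  ord <- match(res_order, ca_keys)
  ca_i <- which(ca)[ord]
  residues <- data.frame(
    chain = chain[ca_i], resnum = resnum[ca_i],
    icode = ifelse(icode[ca_i] == " ", "", icode[ca_i]),
    aa = unname(ifelse(resname[ca_i] %in% names(AA3TO1),
                       AA3TO1[resname[ca_i]], "X")),
    stringsAsFactors = FALSE)
  coords <- cbind(x = x[ca_i], y = y[ca_i], z = z[ca_i])

  atoms <- NULL
  if (keep_atoms) {
    keep <- which(poly)[pk %in% res_order]
    ak <- residue_key(chain[keep], resnum[keep], icode[keep])
    atoms <- data.frame(key = ak, atom = atom_name[keep],
                        element = element[keep],
                        x = x[keep], y = y[keep], z = z[keep],
                        stringsAsFactors = FALSE)
  }
  calpha_structure(residues, coords, atoms = atoms, ion_sites = ion_sites)
}

#' Detect disulfide bridges from SG-SG distances
#'
#' Every unordered cysteine pair with SG-SG distance at or below `sg_cutoff`
#' is a candidate; candidates are resolved by greedy closest-distance matching
#' so each cysteine joins at most one bridge. Unpaired cysteines are reported
#' in the `unpaired` attribute.
#'
#' @param structure a [calpha_structure()] with full-atom records
#' @param sg_cutoff SG-SG distance cutoff, Angstrom (default 2.3)
#' @return data.frame with columns residue_a, residue_b, sg_distance, sorted by
#'   the chain-order position of residue_a; attribute `unpaired` lists cysteine
#'   residue keys not in any bridge
#' @export
detect_disulfides <- function(structure, sg_cutoff = 2.3) {
  at <- structure$atoms
  cys_keys <- structure$residues$key[structure$residues$aa == "C"]
  sg <- if (!is.null(at)) at[at$atom == "SG" & at$key %in% cys_keys, , drop = FALSE] else NULL
  if (is.null(sg) || nrow(sg) == 0) {
    if (!length(cys_keys)) {
      out <- data.frame(residue_a = character(), residue_b = character(),
                        sg_distance = numeric(), stringsAsFactors = FALSE)
      attr(out, "unpaired") <- character()
      return(out)
    }
    stop("no SG atoms present: disulfide detection needs full-atom records")
  }
  pos <- match(sg$key, structure$residues$key)
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  n <- nrow(sg)
  cand <- NULL
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
    if (nrow(idx)) {
      cand <- data.frame(i = idx[, 1], j = idx[, 2],
                         dist = d[idx])
    }
  }
  paired <- logical(n)
  bridges <- list()
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (paired[i] || paired[j]) next
      paired[i] <- paired[j] <- TRUE
      a <- if (pos[i] < pos[j]) i else j
      b <- if (pos[i] < pos[j]) j else i
      bridges[[length(bridges) + 1L]] <-
        data.frame(residue_a = sg$key[a], residue_b = sg$key[b],
                   sg_distance = cand$dist[r], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(bridges)) do.call(rbind, bridges) else
    data.frame(residue_a = character(), residue_b = character(),
               sg_distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(out)) out <- out[order(match(out$residue_a, structure$residues$key)), ,
                            drop = FALSE]
  rownames(out) <- NULL
  unpaired_sg <- sg$key[!paired]
  attr(out, "unpaired") <- union(unpaired_sg, setdiff(cys_keys, sg$key))
  out
}

## atom coordinate table used by contact rules; falls back to C-alpha only
contact_atoms <- function(structure, warn_context) {
  if (!is.null(structure$atoms) && nrow(structure$atoms) > 0) {
    data.frame(key = structure$atoms$key,
               x = structure$atoms$x, y = structure$atoms$y,
               z = structure$atoms$z, stringsAsFactors = FALSE)
  } else {
    warning(warn_context, ": no full-atom records, using C-alpha positions only")
    data.frame(key = structure$residues$key,
               x = structure$coords[, 1], y = structure$coords[, 2],
               z = structure$coords[, 3], stringsAsFactors = FALSE)
  }
}

min_dist_to_points <- function(atoms_df, pts) {
  ax <- as.matrix(atoms_df[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(pts^2), "+") - 2 * ax %*% t(pts)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Residues in contact with bound ions
#'
#' A residue is reported when ANY of its atoms lies within `radius` of any ion
#' site carrying `ion_label` (default rule: all recorded atoms; C-alpha-only
#' fallback when full-atom records are absent).
#'
#' @param structure a [calpha_structure()] with `ion_sites`
#' @param ion_label element label, e.g. "ZN" or "CA"
#' @param radius contact radius, Angstrom (default 3.5)
#' @return character vector of residue keys, in chain order
#' @export
ion_contact_residues <- function(structure, ion_label, radius = 3.5) {
  ions <- structure$ion_sites
  if (is.null(ions) || !any(ions$element == toupper(ion_label)))
    stop("no ion sites labelled '", ion_label, "' in structure")
  pts <- as.matrix(ions[ions$element == toupper(ion_label), c("x", "y", "z")])
  at <- contact_atoms(structure, "ion_contact_residues")
  dmin <- min_dist_to_points(at, pts)
  hit <- unique(at$key[dmin <= radius])
  structure$residues$key[structure$residues$key %in% hit]
}

#' Residues at a binding interface with a partner structure
#'
#' Residues of `structure` having any atom within `radius` of any atom of
#' `partner` (both in the same coordinate frame).
#'
#' @param structure,partner [calpha_structure()] objects
#' @param radius contact radius, Angstrom (default 4.0)
#' @return character vector of residue keys of `structure`, in chain order
#' @export
interface_residues <- function(structure, partner, radius = 4.0) {
  at <- contact_atoms(structure, "interface_residues")
  pat <- contact_atoms(partner, "interface_residues(partner)")
  dmin <- min_dist_to_points(at, as.matrix(pat[, c("x", "y", "z")]))
  hit <- unique(at$key[dmin <= radius])
  structure$residues$key[structure$residues$key %in% hit]
}

#' Write a residue set as TSV (chain, resnum, icode, aa)
#' @param structure a [calpha_structure()]
#' @param keys residue keys to write
#' @param path output path
#' @export
write_residue_set <- function(structure, keys, path) {
  df <- structure$residues[structure$residues$key %in% keys,
                           c("chain", "resnum", "icode", "aa")]
  write_tsv_file(df, path)
}
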