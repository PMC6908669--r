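## Seeded synthetic-data generators with recorded ground truth. These stand in
## for the study inputs that cannot ship with the package: crystal-derived
## bead structures (with disulfide-like crosslinks and ion sites), MD-like
## Gaussian ensembles, AFM force-extension curves, and aligned sequence sets.
## Every generator is a pure function of its arguments including the seed.

#' Synthetic C-alpha bead structure
#'
#' Geometries: `"helix"` places beads on an alpha-helix-like spiral (rise
#' 1.5 A, 100 degree turn, radius 2.3 A, consecutive C-alpha spacing ~3.8 A);
#' `"two_domain"` builds two compact globular clusters joined by an extended
#' linker (optionally separated by `domain_gap` to create a disconnected
#' network). Crosslinks become synthetic cysteine pairs carrying SG
#' pseudo-atoms 2.05 A apart; ion placements become HETATM-like ion sites
#' near the given residues.
#'
#' @param n number of beads (>= 2)
#' @param geometry "helix" or "two_domain"
#' @param crosslinks optional 2-column matrix/list of residue index pairs
#' @param ions optional data.frame(element, residue) placing an ion 3 A from
#'   the given residue's C-alpha
#' @param domain_gap extra separation between the two domains, A
#'   (two_domain only; default 0)
#' @param seed RNG seed
#' @return a [calpha_structure()]; ground truth (crosslink indices, geometry)
#'   in attribute `ground_truth`
#' @export
make_bead_chain <- function(n, geometry = c("helix", "two_domain"),
                            crosslinks = NULL, ions = NULL,
                            domain_gap = 0, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n >= 2)
  set.seed(seed)
  if (geometry == "helix") {
    i <- seq_len(n) - 1
    theta <- i * 100 * pi / 180
    coords <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    n1 <- n %/% 2
    ## compact clusters: jittered points on small spirals, linker implicit
    cluster <- function(m, center) {
      g <- ceiling(m^(1 / 3))
      pts <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g),
                                   z = seq_len(g)))[seq_len(m), , drop = FALSE]
      pts <- pts * 3.8 + matrix(stats::rnorm(3 * m, sd = 0.3), ncol = 3)
      sweep(pts, 2, center, "+")
    }
    sep <- 3.8 * ceiling((n - n1)^(1 / 3)) + 8 + domain_gap
    coords <- rbind(cluster(n1, c(0, 0, 0)),
                    cluster(n - n1, c(sep, 0, 0)))
  }
  aa <- rep("A", n)
  atoms <- data.frame(key = character(), atom = character(),
                      element = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE)
  if (!is.null(crosslinks)) {
    cl <- if (is.list(crosslinks) && !is.data.frame(crosslinks))
      do.call(rbind, crosslinks) else as.matrix(crosslinks)
    if (any(cl < 1) || any(cl > n)) stop("crosslink indices out of range")
    aa[as.vector(cl)] <- "C"
  }
  residues <- data.frame(chain = "A", resnum = seq_len(n), icode = "",
                         aa = aa, stringsAsFactors = FALSE)
  keys <- residue_key(residues$chain, residues$resnum, residues$icode)
  ## every bead carries its CA as an atom record
  atoms <- data.frame(key = keys, atom = "CA", element = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(crosslinks)) {
    cl <- if (is.list(crosslinks) && !is.data.frame(crosslinks))
      do.call(rbind, crosslinks) else as.matrix(crosslinks)
    for (r in seq_len(nrow(cl))) {
      i <- cl[r, 1]; j <- cl[r, 2]
      mid <- (coords[i, ] + coords[j, ]) / 2
      u <- coords[j, ] - coords[i, ]
      u <- u / sqrt(sum(u^2))
      sg1 <- mid - u * 1.025
      sg2 <- mid + u * 1.025      # SG-SG distance 2.05 A
      atoms <- rbind(atoms,
        data.frame(key = keys[c(i, j)], atom = "SG", element = "S",
                   x = c(sg1[1], sg2[1]), y = c(sg1[2], sg2[2]),
                   z = c(sg1[3], sg2[3]), stringsAsFactors = FALSE))
    }
  }
  ion_sites <- NULL
  if (!is.null(ions) && nrow(ions) > 0) {
    pos <- coords[ions$residue, , drop = FALSE]
    ion_sites <- data.frame(element = toupper(ions$element),
                            x = pos[, 1] + 3, y = pos[, 2], z = pos[, 3],
                            stringsAsFactors = FALSE)
  }
  st <- calpha_structure(residues, coords, atoms = atoms, ion_sites = ion_sites)
  attr(st, "ground_truth") <- list(geometry = geometry, n = n,
                                   crosslinks = crosslinks, seed = seed)
  st
}

#' Sample a Gaussian ensemble consistent with a prescribed mode covariance
#'
#' Frames are `reference + sum_k sqrt(var_k) z_k u_k` with standard-normal
#' z (seeded), i.e. draws from the low-rank covariance
#' `C = sum_k var_k u_k u_k'`. With `rigid_jitter`, each frame additionally
#' receives a random rigid rotation + translation to exercise superposition.
#'
#' @param modes a [mode_set()] whose non-rigid modes define the sampling basis
#' @param variances per-mode variances, A^2 (length = number of sampled modes)
#' @param n_frames number of frames
#' @param reference a [calpha_structure()] congruent with the modes
#' @param rigid_jitter add random rigid motions per frame
#' @param seed RNG seed
#' @return an [ensemble()]; generator covariance basis in attribute
#'   `ground_truth` (modes, variances, seed)
#' @export
sample_ensemble <- function(modes, variances, n_frames, reference,
                            rigid_jitter = FALSE, seed = 1) {
  if (any(variances < 0)) stop("variances must be non-negative")
  keep <- select_modes(modes, length(variances))
  U <- modes$vectors[, keep, drop = FALSE]
  stopifnot(length(variances) == ncol(U))
  set.seed(seed)
  n <- n_residues(reference)
  ref_vec <- as.numeric(t(reference$coords))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    z <- stats::rnorm(length(variances))
    v <- ref_vec + as.numeric(U %*% (sqrt(variances) * z))
    xyz <- matrix(v, ncol = 3, byrow = TRUE)
    if (rigid_jitter) {
      R <- random_rotation()
      shift <- stats::rnorm(3, sd = 10)
      ctr <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% R, 2, ctr + shift, "+")
    }
    frames[[f]] <- xyz
  }
  e <- ensemble(frames, reference, aligned = !rigid_jitter)
  gt_modes <- mode_set("PCA", variances, U, n)
  attr(e, "ground_truth") <- list(modes = gt_modes, variances = variances,
                                  seed = seed, rigid_jitter = rigid_jitter)
  e
}

## uniform random rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate a piecewise-WLC force-extension curve
#'
#' Within segment s the force follows `wlc_force(x; Lc_s)` until it reaches
#' `rupture_forces[s]`; the contour length then advances to the next entry of
#' the schedule (an unfolding event). The default schedule encodes
#' contour-length increments of 20, 40 and 60 nm — the major peaks seen in
#' AFM increment histograms of reelin dimers — and the default force noise of
#' 8.5 pN matches the stated force-determination accuracy of the instrument.
#'
#' With `dimer_parallel`, the curve emulates two chains stretched in
#' parallel: each true increment appears as two unfolding events of half the
#' increment, so apparent fitted increments are halved and the event count
#' doubles.
#'
#' @param lc_schedule strictly increasing contour lengths, nm
#' @param rupture_forces per-segment rupture forces, pN (recycled)
#' @param p persistence length, nm
#' @param noise_sd Gaussian force noise, pN (default 8.5)
#' @param grid_step extension grid step, nm (default 0.2)
#' @param dimer_parallel emulate parallel two-chain stretching
#' @param detach append a final detachment drop to baseline after the last
#'   rupture (default TRUE)
#' @param adhesion_spike prepend a short nonspecific-adhesion dip before the
#'   zero-force crossing
#' @param kT thermal energy, pN nm
#' @param seed RNG seed
#' @return a [force_curve()]; ground-truth events (segment contour lengths,
#'   rupture extensions/forces, apparent increments) in `metadata$ground_truth`
#' @export
simulate_force_curve <- function(lc_schedule = c(30, 50, 90, 150),
                                 rupture_forces = 50, p = 0.4,
                                 noise_sd = 8.5, grid_step = 0.2,
                                 dimer_parallel = FALSE, detach = TRUE,
                                 adhesion_spike = FALSE, kT = KT_ROOM,
                                 seed = 1) {
  stopifnot(all(diff(lc_schedule) > 0), p > 0, grid_step > 0, noise_sd >= 0)
  if (dimer_parallel) {
    ## two chains share the extension: each true increment unfolds once per
    ## chain, appearing as two apparent events of half the increment
    incr <- diff(lc_schedule)
    lc_app <- lc_schedule[1] + cumsum(rep(incr / 2, each = 2))
    lc_schedule <- c(lc_schedule[1], lc_app)
  }
  ns <- length(lc_schedule)
  rupture_forces <- rep_len(rupture_forces, ns)
  ## rupture extension of each segment
  x_rupt <- vapply(seq_len(ns), function(s)
    wlc_extension_at_force(rupture_forces[s], p, lc_schedule[s], kT),
    numeric(1))
  if (any(diff(x_rupt) <= 0))
    stop("schedule error: rupture force unreachable before the next ",
         "contour length (rupture extensions must increase)")
  x_end <- x_rupt[ns] + if (detach) max(10, 0.1 * x_rupt[ns]) else 0
  x <- seq(grid_step, x_end, by = grid_step)
  f <- numeric(length(x))
  seg <- findInterval(x, x_rupt, left.open = TRUE) + 1L  # segment index per x
  inside <- seg <= ns
  for (s in seq_len(ns)) {
    m <- inside & seg == s
    f[m] <- wlc_force(x[m], p, lc_schedule[s], kT)
  }
  f[!inside] <- 0                       # detached baseline
  set.seed(seed)
  if (adhesion_spike) {
    n_adh <- max(3L, as.integer(2 / grid_step))
    f[seq_len(n_adh)] <- f[seq_len(n_adh)] -
      seq(60, 0, length.out = n_adh)
  }
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), sd = noise_sd)
  gt <- list(lc_schedule = lc_schedule, rupture_forces = rupture_forces,
             rupture_extensions = x_rupt, delta_lc = diff(lc_schedule),
             dimer_parallel = dimer_parallel, noise_sd = noise_sd,
             seed = seed, p = p)
  force_curve(x, f, metadata = list(source = "synthetic", seed = seed,
                                    ground_truth = gt))
}

#' Simulate an MSA with a controlled conservation profile
#'
#' Without a tree, each sequence keeps the root symbol of column c with
#' probability `conservation[c]` and otherwise substitutes uniformly among
#' the other 19 amino acids. With an ultrametric tree (ape `phylo`),
#' substitutions accumulate along branches with a per-column rate chosen so a
#' root-to-leaf path retains the root symbol with probability
#' ~`conservation[c]`, making expected Hamming distances tree-consistent.
#'
#' @param n_seqs number of sequences (ignored when a tree supplies tips;
#'   default 67, the size of the study's cross-species reelin set)
#' @param length alignment length
#' @param conservation per-column retention probability in \[0, 1\] (recycled)
#' @param tree optional rooted ultrametric `ape::phylo` with branch lengths
#' @param seed RNG seed
#' @return an [msa()]; root sequence, profile and tree in attribute
#'   `ground_truth`
#' @export
simulate_msa <- function(n_seqs = 67, length = 360, conservation = 0.9,
                         tree = NULL, seed = 1) {
  conservation <- rep_len(conservation, length)
  stopifnot(all(conservation >= 0), all(conservation <= 1))
  set.seed(seed)
  aas <- AA_ALPHABET[1:20]
  root <- sample(aas, length, replace = TRUE)
  mutate_from <- function(sym, pr_keep) {
    change <- stats::runif(length(sym)) > pr_keep
    if (any(change)) {
      sym[change] <- vapply(sym[change], function(s)
        sample(setdiff(aas, s), 1), character(1))
    }
    sym
  }
  if (is.null(tree)) {
    ids <- sprintf("seq%03d", seq_len(n_seqs))
    rows <- do.call(rbind, lapply(seq_len(n_seqs), function(i)
      mutate_from(root, conservation)))
  } else {
    depth <- max(ape::node.depth.edgelength(tree))
    rate <- ifelse(conservation >= 1, 0,
                   -log(pmax(conservation, 1e-12)) / depth)
    nt <- ape::Ntip(tree)
    seqs_at <- vector("list", nt + tree$Nnode)
    root_node <- nt + 1L
    seqs_at[[root_node]] <- root
    ## preorder traversal over edges
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    for (r in seq_len(nrow(ord))) {
      parent <- ord[r, 1]; child <- ord[r, 2]
      t_br <- tree$edge.length[which(tree$edge[, 1] == parent &
                                     tree$edge[, 2] == child)]
      pr_keep <- exp(-rate * t_br)
      seqs_at[[child]] <- mutate_from(seqs_at[[parent]], pr_keep)
    }
    ids <- tree$tip.label
    rows <- do.call(rbind, lapply(seq_len(nt), function(i) seqs_at[[i]]))
  }
  out <- msa(ids, apply(rows, 1, paste, collapse = ""),
             reference_id = ids[1])
  attr(out, "ground_truth") <- list(root = paste(root, collapse = ""),
                                    conservation = conservation,
                                    tree = tree, seed = seed)
  out
}

#' Write a JSON ground-truth sidecar for a synthetic artifact
#' @param obj object with a `ground_truth` attribute (or metadata entry)
#' @param path output path
#' @export
write_ground_truth <- function(obj, path) {
  gt <- attr(obj, "ground_truth")
  if (is.null(gt) && !is.null(obj$metadata)) gt <- obj$metadata$ground_truth
  if (is.null(gt)) stop("object carries no ground truth")
  keep <- gt[!vapply(gt, function(v)
    inherits(v, c("phylo", "mode_set")), logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a CalphaStructure as single-model PDB text
#' @param structure a [calpha_structure()]
#' @param path output path
#' @export
write_structure_pdb <- function(structure, path) {
  res <- structure$residues
  aa3 <- names(AA3TO1)[match(res$aa, AA3TO1)]
  aa3[is.na(aa3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  emit <- function(rec, name, resname, chain, resnum, icode, x, y, z, element) {
    serial <<- serial + 1L
    writeLines(sprintf(
      "%-6s%5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      rec, serial, name, resname, chain, resnum,
      ifelse(icode == "", " ", icode), x, y, z, element), con)
  }
  if (!is.null(structure$atoms) && nrow(structure$atoms) > 0) {
    at <- structure$atoms
    ri <- match(at$key, res$key)
    for (r in seq_len(nrow(at)))
      emit("ATOM", if (nchar(at$atom[r]) < 4) paste0(" ", at$atom[r]) else at$atom[r],
           aa3[ri[r]], res$chain[ri[r]], res$resnum[ri[r]], res$icode[ri[r]],
           at$x[r], at$y[r], at$z[r], at$element[r])
  } else {
    for (r in seq_len(nrow(res)))
      emit("ATOM", " CA", aa3[r], res$chain[r], res$resnum[r], res$icode[r],
           structure$coords[r, 1], structure$coords[r, 2],
           structure$coords[r, 3], "C")
  }
  if (!is.null(structure$ion_sites)) {
    ions <- structure$ion_sites
    for (r in seq_len(nrow(ions)))
      emit("HETATM", paste0(substr(ions$element[r], 1, 2), " "),
           substr(ions$element[r], 1, 3), "Z", 900L + r, "",
           ions$x[r], ions$y[r], ions$z[r], ions$element[r])
  }
  writeLines("END", con)
  invisible(path)
}
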