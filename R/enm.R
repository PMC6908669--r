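## Anisotropic elastic network model: Hessian construction, eigendecomposition,
## per-residue RMSF from modes, and normalized cross-correlation maps.
##
## The ANM places a bead at each C-alpha and a Hookean spring of stiffness
## gamma between beads within a distance cutoff; the 3N x 3N Hessian's
## low-frequency modes describe the collective dynamics. Correlation maps and
## PRS are normalized, so gamma cancels and only the cutoff matters.

#' Build the anisotropic network model Hessian
#'
#' Off-diagonal 3x3 superblock for a contact pair (i, j):
#' `-gamma * (r_ij %o% r_ij) / |r_ij|^2`; diagonal superblocks are minus the
#' sum of the row's off-diagonal superblocks, which enforces translation
#' invariance.
#'
#' @param structure a [calpha_structure()] (or an N x 3 coordinate matrix)
#' @param cutoff contact cutoff, Angstrom (default 15, the conventional
#'   C-alpha ANM choice)
#' @param gamma uniform spring constant (arbitrary units; default 1)
#' @return object of class `anm_hessian` with fields matrix, cutoff, gamma,
#'   n_residues, connected
#' @export
build_anm_hessian <- function(structure, cutoff = 15, gamma = 1) {
  xyz <- if (is.matrix(structure)) structure else structure$coords
  n <- nrow(xyz)
  stopifnot(n >= 2, cutoff > 0, gamma > 0)
  d <- as.matrix(stats::dist(xyz))
  contact <- d <= cutoff & upper.tri(d)
  H <- matrix(0, 3 * n, 3 * n)
  idx <- which(contact, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    rij <- xyz[j, ] - xyz[i, ]
    blk <- -gamma * tcrossprod(rij) / sum(rij^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  adj <- d <= cutoff
  comp <- connected_components(adj)
  if (max(comp) > 1)
    warning("network disconnected under cutoff ", cutoff, " A (",
            max(comp), " components): expect ", 6 * max(comp), " zero modes")
  structure(list(matrix = H, cutoff = cutoff, gamma = gamma,
                 n_residues = n, n_components = max(comp)),
            class = "anm_hessian")
}

## label connected components of a logical adjacency matrix (BFS)
#' @keywords internal
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Construct a ModeSet
#'
#' @param kind "ANM" (eigenvalues ascending, stiffness units) or "PCA"
#'   (variances descending, Angstrom^2)
#' @param values eigenvalues / variances
#' @param vectors 3N x m column-orthonormal matrix
#' @param n_residues N
#' @param rigid logical vector flagging rigid-body (zero) modes; PCA mode sets
#'   have none
#' @export
mode_set <- function(kind, values, vectors, n_residues,
                     rigid = rep(FALSE, length(values))) {
  kind <- match.arg(kind, c("ANM", "PCA"))
  stopifnot(length(values) == ncol(vectors),
            nrow(vectors) == 3 * n_residues,
            length(rigid) == length(values))
  structure(list(kind = kind, values = values, vectors = vectors,
                 n_residues = n_residues, rigid = rigid),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes over %d residues, %d rigid\n",
              x$kind, length(x$values), x$n_residues, sum(x$rigid)))
  invisible(x)
}

## deterministic eigenvector sign: first component of magnitude > tol positive
fix_mode_signs <- function(vectors, tol = 1e-8) {
  for (k in seq_len(ncol(vectors))) {
    v <- vectors[, k]
    nz <- which(abs(v) > tol * max(abs(v)))
    if (length(nz) && v[nz[1]] < 0) vectors[, k] <- -v
  }
  vectors
}

#' Eigendecompose an ANM Hessian into a ModeSet
#'
#' Modes with eigenvalue below `zero_tol_rel * max(eigenvalue)` are flagged as
#' rigid-body modes and excluded from all downstream sums. A connected 3-D
#' network yields exactly 6; more indicates disconnection (a warning is raised
#' and recorded in the `disconnected` attribute).
#'
#' @param h an `anm_hessian`
#' @param zero_tol_rel relative magnitude threshold for zero modes (default 1e-8)
#' @return a [mode_set()] of kind "ANM", eigenvalues ascending
#' @export
decompose_hessian <- function(h, zero_tol_rel = 1e-8) {
  stopifnot(inherits(h, "anm_hessian"))
  e <- eigen(h$matrix, symmetric = TRUE)
  ord <- order(e$values)        # ascending
  values <- e$values[ord]
  vectors <- fix_mode_signs(e$vectors[, ord, drop = FALSE])
  lam_max <- max(values)
  rigid <- values < zero_tol_rel * lam_max
  values[rigid] <- pmax(values[rigid], 0)  # clip eigensolver noise
  ms <- mode_set("ANM", values, vectors, h$n_residues, rigid = rigid)
  if (sum(rigid) > 6) {
    warning("more than 6 rigid-body modes (", sum(rigid),
            "): network is disconnected")
    attr(ms, "disconnected") <- TRUE
  }
  ms
}

## mode weights for fluctuation sums: 1/lambda for ANM, variance for PCA
mode_weights <- function(modes, keep) {
  if (modes$kind == "ANM") 1 / modes$values[keep] else modes$values[keep]
}

## indices of the k leading non-rigid modes (slowest for ANM, largest-variance
## for PCA; both orderings put them first among non-rigid modes)
select_modes <- function(modes, k) {
  nonrigid <- which(!modes$rigid)
  if (!length(nonrigid)) stop("no non-rigid modes available")
  if (identical(k, "all")) return(nonrigid)
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (k > length(nonrigid)) {
    warning("requested ", k, " modes but only ", length(nonrigid),
            " non-rigid modes available; truncating")
    k <- length(nonrigid)
  }
  if (modes$kind == "ANM") nonrigid[seq_len(k)]
  else nonrigid[order(modes$values[nonrigid], decreasing = TRUE)[seq_len(k)]]
}

#' Per-residue RMSF from a mode set
#'
#' `RMSF_i = sqrt( sum_k w_k * |u_{k,i}|^2 )` over the selected non-rigid
#' modes, with `w_k = 1/lambda_k` for ANM (global scale arbitrary) or the mode
#' variance for PCA (Angstrom).
#'
#' @param modes a [mode_set()]
#' @param k number of modes, or "all" (default) for every non-rigid mode
#' @param squared return mean-square fluctuations instead of RMSF
#' @return numeric vector of length N
#' @export
rmsf_from_modes <- function(modes, k = "all", squared = FALSE) {
  keep <- select_modes(modes, k)
  w <- mode_weights(modes, keep)
  U2 <- modes$vectors[, keep, drop = FALSE]^2
  res_idx <- rep(seq_len(modes$n_residues), each = 3)
  per_res <- rowsum(U2, res_idx)            # N x k, |u_{k,i}|^2
  msf <- as.numeric(per_res %*% w)
  if (squared) msf else sqrt(msf)
}

#' Normalized cross-correlation map from the slowest modes
#'
#' Raw covariance `c_ij = sum_k w_k * (u_{k,i} . u_{k,j})` (3-vector dot per
#' residue block), normalized by the mean-square fluctuations:
#' `C_ij = c_ij / sqrt(c_ii c_jj)`, so entries lie in \[-1, 1\] and the
#' diagonal is 1. Residues with zero self-covariance give NA rows, flagged in
#' the `undefined` attribute.
#'
#' @param modes a [mode_set()]
#' @param k number of modes averaged (default 10, the ten slowest modes)
#' @return object of class `correlation_map`: list(matrix, k_modes)
#' @export
cross_correlation_map <- function(modes, k = 10) {
  keep <- select_modes(modes, k)
  w <- mode_weights(modes, keep)
  n <- modes$n_residues
  C <- matrix(0, n, n)
  for (m in seq_along(keep)) {
    M <- matrix(modes$vectors[, keep[m]], ncol = 3, byrow = TRUE)  # N x 3
    C <- C + w[m] * tcrossprod(M)
  }
  dg <- diag(C)
  if (all(dg == 0)) stop("degenerate input: all-zero covariance")
  undef <- dg <= 0
  s <- sqrt(ifelse(undef, NA_real_, dg))
  Cn <- C / outer(s, s)
  diag(Cn)[!undef] <- 1
  out <- structure(list(matrix = Cn, k_modes = length(keep)),
                   class = "correlation_map")
  attr(out, "undefined") <- which(undef)
  out
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation_map: %d x %d from %d modes\n",
              nrow(x$matrix), ncol(x$matrix), x$k_modes))
  invisible(x)
}
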