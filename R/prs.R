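## Perturbation response scanning (PRS).
##
## Linear response: under an external force f applied at residue i, the
## displacement of the network is d = G f, with G the pseudo-inverse of the
## ANM Hessian over non-rigid modes. Element (i, j) of the PRS map records the
## mean squared displacement of residue j under isotropically averaged unit
## forces at residue i, normalized by the self-response so the diagonal is 1.
## Row means (minus diagonal) are "effectiveness" (effectors: residues whose
## perturbation moves the whole structure); column means are "sensitivity"
## (sensors: residues that respond to perturbations anywhere).

## pseudo-inverse over non-rigid modes
hessian_pseudoinverse <- function(h, zero_tol_rel = 1e-8) {
  ms <- if (inherits(h, "mode_set")) h else
    suppressWarnings(decompose_hessian(h, zero_tol_rel))
  keep <- which(!ms$rigid)
  if (!length(keep)) stop("network has no non-rigid modes")
  V <- ms$vectors[, keep, drop = FALSE]
  V %*% (t(V) / ms$values[keep])
}

prs_finalize <- function(p, keys = NULL) {
  dg <- diag(p)
  degenerate <- which(dg <= 0)
  if (length(degenerate))
    warning("degenerate self-response for ", length(degenerate),
            " residue(s); excluded from profiles")
  P <- p / ifelse(dg > 0, dg, NA_real_)   # row-normalize by self-response
  diag(P)[dg > 0] <- 1
  dimnames(P) <- NULL
  prof <- prs_profiles_matrix(P)
  out <- structure(list(matrix = P,
                        effectiveness = prof$effectiveness,
                        sensitivity = prof$sensitivity,
                        residue_keys = keys),
                   class = "prs_map")
  attr(out, "degenerate") <- degenerate
  out
}

prs_profiles_matrix <- function(P) {
  n <- nrow(P)
  offdiag <- P
  diag(offdiag) <- NA
  list(effectiveness = rowMeans(offdiag, na.rm = TRUE),
       sensitivity = colMeans(offdiag, na.rm = TRUE))
}

#' Closed-form PRS map
#'
#' With G the Hessian pseudo-inverse over non-rigid modes, the raw response of
#' residue j to an isotropically averaged unit force at residue i is
#' `p_ij = (1/3) * sum(G[block j, block i]^2)` (all 9 squared elements of the
#' 3x3 block). The returned matrix is row-normalized: `P_ij = p_ij / p_ii`.
#'
#' @param h an `anm_hessian` or a [mode_set()]
#' @param keys optional residue keys carried into the result
#' @return object of class `prs_map`: matrix (row = perturbed residue,
#'   column = responder), effectiveness and sensitivity profiles
#' @export
prs_map_closed_form <- function(h, keys = NULL) {
  G <- hessian_pseudoinverse(h)
  n <- nrow(G) / 3
  S <- G^2
  idx <- rep(seq_len(n), each = 3)
  S1 <- rowsum(S, idx)                 # n x 3n: sum over block rows (j)
  B <- t(rowsum(t(S1), idx))           # n x n: B[j, i] = block sum
  p <- t(B) / 3                        # p[i, j]
  prs_finalize(p, keys)
}

#' Monte-Carlo PRS map (stochastic oracle)
#'
#' For each residue i, `n_forces` unit force vectors are drawn uniformly on
#' the sphere (seeded), the displacement response is computed through the
#' Hessian pseudo-inverse, and squared displacement magnitudes are averaged
#' per responding residue before the same row normalization as the closed
#' form. Converges to [prs_map_closed_form()] as `n_forces` grows; kept as an
#' independently-coded oracle, not the production path.
#'
#' @param h an `anm_hessian` or a [mode_set()]
#' @param n_forces number of random unit forces per residue
#' @param seed RNG seed (recorded in the result)
#' @param keys optional residue keys
#' @return a `prs_map` with fields n_forces and seed set
#' @export
prs_map_monte_carlo <- function(h, n_forces = 1000, seed = 1, keys = NULL) {
  stopifnot(n_forces >= 1)
  G <- hessian_pseudoinverse(h)
  n <- nrow(G) / 3
  set.seed(seed)
  idx <- rep(seq_len(n), each = 3)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    F <- matrix(stats::rnorm(3 * n_forces), nrow = 3)
    F <- F / rep(sqrt(colSums(F^2)), each = 3)       # unit vectors
    D <- G[, (3 * i - 2):(3 * i)] %*% F              # 3n x n_forces
    p[i, ] <- rowMeans(rowsum(D^2, idx))
  }
  out <- prs_finalize(p, keys)
  out$n_forces <- n_forces
  out$seed <- seed
  out
}

#' @export
print.prs_map <- function(x, ...) {
  cat(sprintf("prs_map: %d x %d%s\n", nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$n_forces))
                sprintf(" (Monte Carlo, %d forces, seed %d)", x$n_forces, x$seed)
              else " (closed form)"))
  invisible(x)
}

#' Effectiveness and sensitivity profiles of a PRS map
#'
#' Row means (effectiveness, the average effect of perturbing each residue)
#' and column means (sensitivity, the average response of each residue),
#' excluding the diagonal.
#'
#' @param map a `prs_map`
#' @return list(effectiveness, sensitivity), each a numeric vector of length N
#'   (named by residue keys when available)
#' @export
prs_profiles <- function(map) {
  stopifnot(inherits(map, "prs_map"))
  prof <- prs_profiles_matrix(map$matrix)
  if (!is.null(map$residue_keys)) {
    names(prof$effectiveness) <- map$residue_keys
    names(prof$sensitivity) <- map$residue_keys
  }
  prof
}

#' Rank PRS hotspots: top effectors and sensors
#'
#' Residues in the top `top_fraction` of each profile. Ties at the cutoff are
#' broken by residue order (the earlier residue is kept). A residue may appear
#' in both sets.
#'
#' @param profiles list(effectiveness, sensitivity) from [prs_profiles()]
#' @param top_fraction fraction of residues reported (default 0.10)
#' @return list(effectors, sensors): integer residue indices (named when the
#'   profiles are named)
#' @export
rank_hotspots <- function(profiles, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  pick <- function(prof) {
    n <- length(prof)
    n_top <- max(1L, min(n, as.integer(round(top_fraction * n))))
    if (top_fraction == 1) n_top <- n
    ord <- order(-prof, seq_len(n))     # stable: ties broken by residue order
    idx <- sort(ord[seq_len(n_top)])
    if (!is.null(names(prof))) stats::setNames(idx, names(prof)[idx]) else idx
  }
  list(effectors = pick(profiles$effectiveness),
       sensors = pick(profiles$sensitivity))
}

#' Write a PRS map and its profiles
#'
#' Writes the square-matrix file plus a TSV of
#' (residue, effectiveness, sensitivity, effector_flag, sensor_flag).
#'
#' @param map a `prs_map`
#' @param matrix_path,profile_path output paths
#' @param top_fraction hotspot fraction for the flags
#' @export
write_prs_map <- function(map, matrix_path, profile_path, top_fraction = 0.10) {
  write_square_matrix(map$matrix, matrix_path)
  prof <- prs_profiles(map)
  hot <- rank_hotspots(prof, top_fraction)
  n <- nrow(map$matrix)
  keys <- if (!is.null(map$residue_keys)) map$residue_keys else
    as.character(seq_len(n))
  df <- data.frame(residue = keys,
                   effectiveness = prof$effectiveness,
                   sensitivity = prof$sensitivity,
                   effector_flag = as.integer(seq_len(n) %in% hot$effectors),
                   sensor_flag = as.integer(seq_len(n) %in% hot$sensors))
  write_tsv_file(df, profile_path)
}
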