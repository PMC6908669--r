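## Conformational-ensemble analysis: rigid-body superposition (Kabsch),
## principal component modes of the coordinate covariance, and ensemble RMSF.
## This is the trajectory-like route; ensembles arrive as multi-MODEL PDB or
## from the synthetic generator.

#' Construct an Ensemble
#'
#' @param frames list of N x 3 coordinate matrices, Angstrom
#' @param reference a [calpha_structure()] with N residues
#' @param aligned has the ensemble been superposed onto the reference?
#' @export
ensemble <- function(frames, reference, aligned = FALSE) {
  n <- n_residues(reference)
  ok <- vapply(frames, function(f)
    is.matrix(f) && nrow(f) == n && ncol(f) == 3 && all(is.finite(f)),
    logical(1))
  if (!all(ok)) stop("every frame must be a finite ", n, " x 3 matrix")
  structure(list(frames = frames, reference = reference, aligned = aligned),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frames x %d residues (%saligned)\n",
              length(x$frames), n_residues(x$reference),
              if (x$aligned) "" else "not "))
  invisible(x)
}

## optimal rotation of P onto Q (both centered) without reflection; returns
## list(R, degenerate)
kabsch_rotation <- function(P0, Q0) {
  C <- crossprod(P0, Q0)
  s <- svd(C)
  degenerate <- s$d[2] < 1e-10 * max(s$d[1], .Machine$double.eps)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, degenerate = degenerate)
}

#' Least-squares superposition of every frame onto the reference
#'
#' Optimal rotation + translation (Kabsch, no reflection), all residues with
#' unit weights. Degenerate (collinear) frames fall back to translation-only
#' with a warning. Per-frame RMSD after fitting is reported in the `rmsd`
#' attribute.
#'
#' @param e an [ensemble()]
#' @return the aligned ensemble
#' @export
superpose_ensemble <- function(e) {
  stopifnot(inherits(e, "ensemble"))
  if (length(e$frames) < 2) stop("superposition needs at least 2 frames")
  ref <- e$reference$coords
  refc <- colMeans(ref)
  ref0 <- sweep(ref, 2, refc)
  rmsd <- numeric(length(e$frames))
  frames <- vector("list", length(e$frames))
  for (f in seq_along(e$frames)) {
    P <- e$frames[[f]]
    pc <- colMeans(P)
    P0 <- sweep(P, 2, pc)
    k <- kabsch_rotation(P0, ref0)
    if (k$degenerate) {
      warning("frame ", f, " is degenerate (collinear); translation-only fit")
      fit <- sweep(P0, 2, refc, "+")
    } else {
      fit <- sweep(P0 %*% k$R, 2, refc, "+")
    }
    rmsd[f] <- sqrt(mean(rowSums((fit - ref)^2)))
    frames[[f]] <- fit
  }
  out <- ensemble(frames, e$reference, aligned = TRUE)
  attr(out, "rmsd") <- rmsd
  out
}

ensemble_coord_matrix <- function(e) {
  do.call(rbind, lapply(e$frames, function(f) as.numeric(t(f))))  # F x 3N
}

#' Principal component modes of an aligned ensemble
#'
#' Top-k eigenpairs of the 3N x 3N coordinate covariance about the ensemble
#' mean (sample covariance, divisor F - 1). Variances descending.
#'
#' @param e an aligned [ensemble()]
#' @param k number of modes, or "all"
#' @return a [mode_set()] of kind "PCA"
#' @export
pca_modes <- function(e, k = "all") {
  stopifnot(inherits(e, "ensemble"))
  if (!e$aligned) stop("pca_modes requires an aligned ensemble; superpose first")
  X <- ensemble_coord_matrix(e)
  nf <- nrow(X)
  if (!identical(k, "all") && nf <= k)
    stop("need more frames than requested modes")
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nf - 1)
  eg <- eigen(C, symmetric = TRUE)    # descending
  m <- if (identical(k, "all")) ncol(C) else as.integer(k)
  values <- pmax(eg$values[seq_len(m)], 0)
  vectors <- fix_mode_signs(eg$vectors[, seq_len(m), drop = FALSE])
  mode_set("PCA", values, vectors, n_residues(e$reference))
}

#' Per-residue RMSF from an aligned ensemble
#'
#' `RMSF_i = sqrt( sum over frames |r_i - <r_i>|^2 / (F - 1) )`, Angstrom.
#' The sample (F - 1) divisor matches the PCA covariance so the mode-route
#' identity holds exactly.
#'
#' @param e an aligned [ensemble()]
#' @return numeric vector of length N
#' @export
rmsf_from_ensemble <- function(e) {
  stopifnot(inherits(e, "ensemble"))
  if (!e$aligned) stop("rmsf_from_ensemble requires an aligned ensemble")
  if (length(e$frames) < 2) {
    warning("single frame: RMSF is identically zero")
    return(numeric(n_residues(e$reference)))
  }
  X <- ensemble_coord_matrix(e)
  v <- apply(X, 2, stats::var)               # per-coordinate, divisor F-1
  unname(sqrt(rowsum(v, rep(seq_len(n_residues(e$reference)), each = 3))[, 1]))
}

#' Average several correlation maps
#'
#' Entry-wise mean of the normalized maps (e.g. one per trajectory/ensemble).
#' @param maps list of `correlation_map` objects of equal size
#' @return a `correlation_map` (k_modes from the first map)
#' @export
average_correlation_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  M <- Reduce(`+`, lapply(maps, `[[`, "matrix")) / length(maps)
  structure(list(matrix = M, k_modes = maps[[1]]$k_modes),
            class = "correlation_map")
}

#' Write an ensemble as multi-MODEL PDB
#' @param e an [ensemble()]
#' @param path output path
#' @export
write_ensemble_pdb <- function(e, path) {
  res <- e$reference$residues
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(e$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- e$frames[[f]]
    aa3 <- names(AA3TO1)[match(res$aa, AA3TO1)]
    aa3[is.na(aa3)] <- "UNK"
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(res)), aa3, res$chain, res$resnum,
      ifelse(res$icode == "", " ", res$icode),
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an ensemble from multi-MODEL PDB
#'
#' All MODELs must contain the same residues; the first MODEL becomes the
#' reference structure.
#' @param path multi-MODEL PDB file
#' @return an (unaligned) [ensemble()]
#' @export
read_ensemble_pdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) stop("no MODEL records: not a multi-MODEL PDB")
  stopifnot(length(starts) == length(ends))
  blocks <- Map(function(s, e) lines[(s + 1):(e - 1)], starts, ends)
  ref <- read_calpha_structure(blocks[[1]], keep_atoms = FALSE)
  frames <- lapply(blocks, function(b) {
    st <- read_calpha_structure(b, keep_atoms = FALSE)
    if (!identical(st$residues$key, ref$residues$key))
      stop("MODELs disagree on residue content")
    unname(st$coords)
  })
  ensemble(frames, ref, aligned = FALSE)
}
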