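## Worm-like-chain force-spectroscopy analysis: WLC evaluation, unfolding
## event detection on force-extension curves, per-segment contour-length
## fitting with fixed persistence length, pooled contour-length-increment
## histograms, and the geometric disulfide-constrained maximum-extension
## bound.

KT_ROOM <- 4.114  # pN nm at 298 K

#' Worm-like-chain interpolation formula
#'
#' `F(x) = (kT/p) * ( 1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc )`, the standard
#' Marko-Siggia interpolation; strictly increasing in x and divergent as
#' x -> Lc.
#'
#' @param x extension, nm (0 <= x < Lc)
#' @param p persistence length, nm (the analysis uses 0.4 nm throughout)
#' @param Lc contour length, nm
#' @param kT thermal energy, pN nm (default 4.114, i.e. 298 K)
#' @return force, pN
#' @export
wlc_force <- function(x, p = 0.4, Lc, kT = KT_ROOM) {
  stopifnot(p > 0, Lc > 0, kT > 0)
  if (any(x < 0) || any(x >= Lc)) stop("extension must satisfy 0 <= x < Lc")
  t <- x / Lc
  (kT / p) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

## inverse of wlc_force in x for a given force (used by the generator)
wlc_extension_at_force <- function(force, p, Lc, kT = KT_ROOM) {
  vapply(force, function(f) {
    stats::uniroot(function(x) wlc_force(x, p, Lc, kT) - f,
                   lower = 0, upper = Lc * (1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
}

#' Construct a ForceCurve
#'
#' @param extension strictly increasing grid, nm
#' @param force pN
#' @param temperature K (metadata)
#' @param metadata free-form list (source, seed, ground truth)
#' @export
force_curve <- function(extension, force, temperature = 298,
                        metadata = list()) {
  stopifnot(length(extension) == length(force),
            all(is.finite(extension)), all(is.finite(force)))
  if (any(diff(extension) <= 0)) stop("extension grid must be strictly increasing")
  structure(list(extension = extension, force = force,
                 temperature = temperature, metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve: %d points, extension %.2f-%.2f nm\n",
              length(x$extension), min(x$extension), max(x$extension)))
  invisible(x)
}

#' Read/write two-column force-extension files
#'
#' Whitespace- or comma-delimited numeric columns (extension nm, force pN);
#' lines starting with '#' are comments.
#' @param path file path
#' @return a [force_curve()]
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  if (anyNA(m)) stop("non-numeric data in force curve file: ", path)
  force_curve(m[, 1], m[, 2], metadata = list(source = path))
}

#' @rdname read_force_curve
#' @param curve a [force_curve()]
#' @export
write_force_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# extension_nm force_pN", con)
  writeLines(paste(fmt_num(curve$extension), fmt_num(curve$force)), con)
  invisible(path)
}

## Savitzky-Golay smoothing: local quadratic fit over an odd window.
## Edges use the shortened symmetric window.
#' @keywords internal
savgol_smooth <- function(y, window = 11) {
  window <- as.integer(window)
  if (window %% 2 == 0) window <- window + 1L
  h <- (window - 1L) %/% 2L
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    if (hh < 1) { out[i] <- y[i]; next }
    t <- (-hh):hh
    yy <- y[(i - hh):(i + hh)]
    if (hh < 2) { out[i] <- mean(yy); next }
    X <- cbind(1, t, t^2)
    out[i] <- stats::lm.fit(X, yy)$coefficients[1]
  }
  out
}

#' Detect unfolding events on a force-extension curve
#'
#' The force trace is smoothed with a local quadratic (Savitzky-Golay) filter;
#' a candidate event is a local maximum of the smoothed force followed within
#' the window by a drop of at least `drop_threshold`. The nonspecific-adhesion
#' region before the first zero-force crossing is excluded. Returns the events
#' and the rising segment (index range) preceding each.
#'
#' @param curve a [force_curve()]
#' @param drop_threshold minimum force drop, pN (default 20)
#' @param window smoothing / look-ahead window, points (default 11, odd)
#' @param min_peak_force peaks below this force are ignored, pN (default 10)
#' @return data.frame with columns peak_index, peak_extension, rupture_force,
#'   segment_start, segment_end (indices into the curve); zero rows when no
#'   events are found
#' @export
detect_unfolding_events <- function(curve, drop_threshold = 20, window = 11,
                                    min_peak_force = 10) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$force)
  if (n < 20) stop("need at least 20 samples")
  fs <- savgol_smooth(curve$force, window)
  h <- max(1L, (as.integer(window) - 1L) %/% 2L)

  ## exclude adhesion region: start after the last non-positive smoothed force
  ## that precedes the first sustained positive stretch
  start <- 1L
  neg <- which(fs[seq_len(max(1L, n %/% 2L))] <= 0)
  if (length(neg) && neg[1] <= 3L) {
    pos_after <- which(fs > 0 & seq_len(n) > neg[1])
    start <- if (length(pos_after)) pos_after[1] else n
  }

  peaks <- integer()
  i <- start + h
  while (i <= n - 4L * h) {    # a drop needs a full verification window
    lo <- max(start, i - h); hi <- min(n, i + h)
    if (fs[i] >= max(fs[lo:hi]) && fs[i] >= min_peak_force) {
      ## level-based drop test: the smoothed force level past the transition
      ## (median, robust to noise) must sit drop_threshold below the peak
      post <- fs[(i + 2L * h):(i + 4L * h)]
      if (fs[i] - stats::median(post) >= drop_threshold) {
        ## two-stage localization: the steepest smoothed descent finds the
        ## transition to within a couple of points; the steepest RAW
        ## single-step drop nearby pins the discontinuity itself
        win <- max(start, i - h):min(n - 1L, i + 3L * h)
        ds <- fs[win + 1L] - fs[win]
        j0 <- win[which.min(ds)]
        w2 <- max(start, j0 - 2L):min(n - 1L, j0 + 2L)
        dr <- curve$force[w2 + 1L] - curve$force[w2]
        pk <- w2[which.min(dr)]
        peaks <- c(peaks, pk)
        ## resume well past the smoothing transition of the drop, else its
        ## decay tail fakes a second event
        i <- pk + 4L * h + 2L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(peaks)) {
    return(data.frame(peak_index = integer(), peak_extension = numeric(),
                      rupture_force = numeric(), segment_start = integer(),
                      segment_end = integer()))
  }
  seg_start <- c(start, utils::head(peaks, -1) + h)
  seg_start <- pmin(seg_start, peaks - 1L)
  data.frame(peak_index = peaks,
             peak_extension = curve$extension[peaks],
             rupture_force = curve$force[peaks],
             segment_start = seg_start,
             segment_end = peaks)
}

## 1-D least squares in Lc (only free parameter)
wlc_ls_fit <- function(x, f, p, kT) {
  xmax <- max(x)
  sse <- function(Lc) sum((wlc_force(x, p, Lc, kT) - f)^2)
  stats::optimize(sse, interval = c(xmax * (1 + 1e-6), xmax * 50))
}

#' Fit per-segment WLC contour lengths
#'
#' For each detected event segment, the contour length Lc is the single free
#' parameter of a least-squares WLC fit (persistence length fixed) to points
#' with positive force below `fit_ceiling * rupture_force` (near-rupture
#' points are excluded because the interpolation formula is least accurate
#' there). Successive differences give the contour-length increments delta_Lc.
#'
#' @param curve a [force_curve()]
#' @param events data.frame from [detect_unfolding_events()]
#' @param p persistence length, nm, held fixed (default 0.4)
#' @param fit_ceiling fraction of the rupture force above which points are
#'   excluded from the fit (default 0.9)
#' @param kT thermal energy, pN nm
#' @return data.frame of unfolding events: peak_extension, rupture_force,
#'   fitted_Lc, delta_Lc (NA for the first event), fit_rss, n_points
#' @export
fit_segment_contour_lengths <- function(curve, events, p = 0.4,
                                        fit_ceiling = 0.9, kT = KT_ROOM) {
  stopifnot(inherits(curve, "force_curve"), p > 0,
            fit_ceiling > 0, fit_ceiling <= 1)
  rows <- list()
  for (s in seq_len(nrow(events))) {
    idx <- events$segment_start[s]:events$segment_end[s]
    x <- curve$extension[idx]
    f <- curve$force[idx]
    if (length(x) < 5) {
      warning("segment ", s, " has fewer than 5 usable points; dropped")
      next
    }
    ## stage 1: fit all segment points, then drop gross outliers (points past
    ## the rupture discontinuity caught inside the segment window)
    fit1 <- wlc_ls_fit(x, f, p, kT)
    resid <- f - wlc_force(pmin(x, fit1$minimum * (1 - 1e-9)), p,
                           fit1$minimum, kT)
    sc <- stats::mad(resid)
    keep <- if (sc > 0) abs(resid) <= 4 * sc else rep(TRUE, length(x))
    if (sum(keep) >= 5 && any(!keep)) fit1 <- wlc_ls_fit(x[keep], f[keep], p, kT)
    ## stage 2: apply the near-rupture ceiling through the MODEL force (the
    ## raw peak force is a single noisy point): keep extensions where the
    ## fitted WLC force stays below fit_ceiling * model rupture force
    Lc1 <- fit1$minimum
    f_rupt <- wlc_force(min(max(x), Lc1 * (1 - 1e-9)), p, Lc1, kT)
    x_cut <- wlc_extension_at_force(fit_ceiling * f_rupt, p, Lc1, kT)
    keep <- keep & x <= x_cut
    opt <- if (sum(keep) >= 5) wlc_ls_fit(x[keep], f[keep], p, kT) else fit1
    rows[[length(rows) + 1L]] <- data.frame(
      peak_extension = events$peak_extension[s],
      rupture_force = events$rupture_force[s],
      fitted_Lc = opt$minimum,
      fit_rss = opt$objective,
      n_points = sum(keep))
  }
  if (!length(rows)) {
    return(data.frame(peak_extension = numeric(), rupture_force = numeric(),
                      fitted_Lc = numeric(), delta_Lc = numeric(),
                      fit_rss = numeric(), n_points = integer()))
  }
  out <- do.call(rbind, rows)
  out$delta_Lc <- c(NA_real_, diff(out$fitted_Lc))
  out[, c("peak_extension", "rupture_force", "fitted_Lc", "delta_Lc",
          "fit_rss", "n_points")]
}

#' Pooled contour-length-increment histogram
#'
#' delta_Lc values from all curves are pooled and binned on a fixed grid whose
#' bin CENTERS sit at integer multiples of `bin_width` (origin -width/2), so
#' increments clustered near, e.g., 20 nm fall into the bin centered on 20 nm.
#' Empty bins are retained.
#'
#' @param event_tables list of event data.frames from
#'   [fit_segment_contour_lengths()]
#' @param bin_width nm (default 5)
#' @return data.frame(center, count)
#' @export
delta_lc_histogram <- function(event_tables, bin_width = 5) {
  dl <- unlist(lapply(event_tables, function(ev) ev$delta_Lc))
  dl <- dl[!is.na(dl)]
  if (!length(dl)) return(data.frame(center = numeric(), count = integer()))
  lo <- floor(min(dl) / bin_width) * bin_width
  hi <- ceiling(max(dl) / bin_width) * bin_width
  breaks <- seq(lo - bin_width / 2, hi + bin_width / 2, by = bin_width)
  counts <- as.integer(table(cut(dl, breaks, right = FALSE)))
  data.frame(center = utils::head(breaks, -1) + bin_width / 2, count = counts)
}

#' Disulfide-constrained maximum-extension bound
#'
#' Intact disulfide bridges lock the enclosed sequence intervals: backbone
#' links inside the union of bridged intervals cannot extend, and each maximal
#' bridged region contributes a fixed `bridge_span` once. The bound is
#' `DL_max = extensible_links * residue_rise + sum(bridge_span) - initial N-C distance`,
#' with extensible links = (N - 1) minus links inside the interval union.
#'
#' @param structure a [calpha_structure()] (N-C distance from the first/last
#'   C-alpha, converted Angstrom -> nm)
#' @param bridges data.frame with residue_a, residue_b keys (as from
#'   [detect_disulfides()]), or NULL for none
#' @param residue_rise extended-backbone rise per link, nm (default 0.365)
#' @param bridge_span through-bridge span per bridged region, nm (default 0.6)
#' @return DL_max, nm
#' @export
max_extension_bound <- function(structure, bridges = NULL,
                                residue_rise = 0.365, bridge_span = 0.6) {
  stopifnot(residue_rise > 0)
  n <- n_residues(structure)
  keys <- structure$residues$key
  intervals <- NULL
  if (!is.null(bridges) && nrow(bridges) > 0) {
    a <- match(bridges$residue_a, keys)
    b <- match(bridges$residue_b, keys)
    if (anyNA(a) || anyNA(b))
      stop("bridge endpoints not found in structure residues")
    intervals <- cbind(pmin(a, b), pmax(a, b))
  }
  locked_links <- 0L
  n_regions <- 0L
  if (!is.null(intervals)) {
    ord <- order(intervals[, 1], intervals[, 2])
    intervals <- intervals[ord, , drop = FALSE]
    cur <- intervals[1, ]
    merged <- list()
    for (r in seq_len(nrow(intervals))[-1]) {
      iv <- intervals[r, ]
      if (iv[1] <= cur[2]) cur[2] <- max(cur[2], iv[2])
      else { merged[[length(merged) + 1L]] <- cur; cur <- iv }
    }
    merged[[length(merged) + 1L]] <- cur
    locked_links <- sum(vapply(merged, function(iv) iv[2] - iv[1], numeric(1)))
    n_regions <- length(merged)
  }
  links <- (n - 1L) - locked_links
  initial_nc_nm <- sqrt(sum((structure$coords[n, ] - structure$coords[1, ])^2)) / 10
  links * residue_rise + n_regions * bridge_span - initial_nc_nm
}
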