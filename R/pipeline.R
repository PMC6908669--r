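## Configuration-driven orchestration of the three analysis surfaces:
## structure -> ENM -> RMSF / correlations / PRS / annotations;
## curves -> events -> contour-length increments -> histogram;
## MSA -> entropy / distance matrices / cladogram.
## Every run echoes its config, writes deterministic numeric outputs
## (9 significant digits) and a manifest with content hashes.

#' Default run configuration
#'
#' A nested list holding every tunable parameter of the pipeline with the
#' package defaults. Unknown keys are rejected by [validate_config()]; a
#' fully-defaulted config is valid.
#'
#' @return nested list
#' @export
default_config <- function() {
  list(
    seed = 1,
    enm = list(cutoff = 15, gamma = 1, zero_tol_rel = 1e-8, k_modes = 10),
    annotations = list(sg_cutoff = 2.3, ion_radius = 3.5, interface_radius = 4.0,
                       ion_elements = c("ZN", "CA")),
    prs = list(top_fraction = 0.10),
    wlc = list(p = 0.4, kT = 4.114, drop_threshold = 20, window = 11,
               fit_ceiling = 0.9, bin_width = 5,
               residue_rise = 0.365, bridge_span = 0.6),
    sequences = list(entropy_gap_policy = "ignore",
                     hamming_gap_policy = "symbol",
                     normalize = FALSE,
                     reference_offset = 1)
  )
}

#' Validate a run configuration against the defaults
#'
#' Missing keys are filled in from [default_config()]; unknown keys raise an
#' error.
#' @param config partial config list
#' @return completed config
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  merge_lvl <- function(cfg, def, path = "") {
    unknown <- setdiff(names(cfg), names(def))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (nm in names(def)) {
      if (is.list(def[[nm]])) {
        cfg[[nm]] <- merge_lvl(if (is.null(cfg[[nm]])) list() else cfg[[nm]],
                               def[[nm]], paste0(path, nm, "$"))
      } else if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
    }
    cfg
  }
  merge_lvl(config, defaults)
}

echo_config <- function(config, outdir) {
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_manifest <- function(outdir) {
  files <- setdiff(list.files(outdir), "manifest.tsv")
  md5 <- tools::md5sum(file.path(outdir, files))
  df <- data.frame(file = files, md5 = unname(md5))
  utils::write.table(df, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Structure pipeline: ENM dynamics, PRS and structural annotations
#'
#' From a C-alpha structure, writes the per-residue RMSF profile, the
#' slow-mode cross-correlation matrix, the PRS map with
#' effectiveness/sensitivity profiles and hotspot flags, detected disulfide
#' bridges, and (when ion sites / a partner are present) ion-contact and
#' interface residue sets.
#'
#' @param structure a [calpha_structure()] or a PDB path
#' @param outdir output directory (created)
#' @param config config list, completed via [validate_config()]
#' @param partner optional partner [calpha_structure()] for interface
#'   annotation
#' @return invisibly, a list of the computed objects; files + manifest in
#'   `outdir`
#' @export
run_structure_pipeline <- function(structure, outdir, config = list(),
                                   partner = NULL) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(structure)) structure <- read_calpha_structure(structure)
  echo_config(config, outdir)
  keys <- structure$residues$key

  h <- build_anm_hessian(structure, cutoff = config$enm$cutoff,
                         gamma = config$enm$gamma)
  modes <- decompose_hessian(h, config$enm$zero_tol_rel)
  rmsf <- rmsf_from_modes(modes, k = "all")
  write_tsv_file(data.frame(residue = keys, rmsf = rmsf),
                 file.path(outdir, "rmsf.tsv"))
  cmap <- cross_correlation_map(modes, k = config$enm$k_modes)
  write_square_matrix(cmap$matrix, file.path(outdir, "correlation.mat"),
                      k_modes = cmap$k_modes)
  prs <- prs_map_closed_form(h, keys = keys)
  write_prs_map(prs, file.path(outdir, "prs.mat"),
                file.path(outdir, "prs_profiles.tsv"),
                top_fraction = config$prs$top_fraction)

  bridges <- tryCatch(
    detect_disulfides(structure, config$annotations$sg_cutoff),
    error = function(e) NULL)
  if (!is.null(bridges))
    write_tsv_file(bridges, file.path(outdir, "disulfides.tsv"))
  if (!is.null(structure$ion_sites)) {
    for (el in unique(structure$ion_sites$element)) {
      ks <- ion_contact_residues(structure, el, config$annotations$ion_radius)
      write_residue_set(structure, ks,
                        file.path(outdir, sprintf("ion_contacts_%s.tsv", el)))
    }
  }
  if (!is.null(partner)) {
    ks <- interface_residues(structure, partner,
                             config$annotations$interface_radius)
    write_residue_set(structure, ks, file.path(outdir, "interface.tsv"))
  }
  write_manifest(outdir)
  invisible(list(hessian = h, modes = modes, rmsf = rmsf,
                 correlation = cmap, prs = prs, bridges = bridges))
}

#' Curves pipeline: unfolding events and contour-length increments
#'
#' Processes force-extension curves (paths or [force_curve()] objects):
#' detects unfolding events, fits per-segment contour lengths at fixed
#' persistence length, and pools increments into a histogram.
#'
#' @param curves list of [force_curve()] objects or file paths
#' @param outdir output directory
#' @param config config list
#' @return invisibly, list(events = per-curve event tables, histogram)
#' @export
run_curves_pipeline <- function(curves, outdir, config = list()) {
  config <- validate_config(config)
  if (!length(curves)) stop("no input curves")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  echo_config(config, outdir)
  wlc <- config$wlc
  tables <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (is.character(cv)) cv <- read_force_curve(cv)
    ev <- detect_unfolding_events(cv, drop_threshold = wlc$drop_threshold,
                                  window = wlc$window)
    fit <- fit_segment_contour_lengths(cv, ev, p = wlc$p,
                                       fit_ceiling = wlc$fit_ceiling,
                                       kT = wlc$kT)
    tables[[i]] <- fit
    write_tsv_file(fit, file.path(outdir, sprintf("events_%03d.tsv", i)))
  }
  hist <- delta_lc_histogram(tables, bin_width = wlc$bin_width)
  if (!nrow(hist)) warning("no unfolding events in any curve: empty histogram")
  write_tsv_file(hist, file.path(outdir, "delta_lc_histogram.tsv"))
  write_manifest(outdir)
  invisible(list(events = tables, histogram = hist))
}

#' Sequence pipeline: conservation, distances and cladogram
#'
#' From an aligned FASTA (or [msa()]), writes the per-column entropy profile,
#' the full Hamming distance matrix (TSV + PHYLIP), the UPGMA cladogram
#' (Newick) and, for each named structural region, a region-restricted
#' distance matrix.
#'
#' @param alignment an [msa()] or aligned-FASTA path
#' @param outdir output directory
#' @param config config list
#' @param regions optional named list of alignment-column vectors (e.g. from
#'   [map_structure_to_alignment()])
#' @return invisibly, list(entropy, distances, tree, regions)
#' @export
run_sequence_pipeline <- function(alignment, outdir, config = list(),
                                  regions = NULL) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(alignment)) alignment <- read_msa_fasta(alignment)
  echo_config(config, outdir)
  sq <- config$sequences

  ent <- column_entropy_profile(alignment, gap_policy = sq$entropy_gap_policy)
  write_tsv_file(data.frame(column = seq_along(ent), entropy_bits = ent),
                 file.path(outdir, "entropy.tsv"))
  D <- hamming_distance_matrix(alignment, normalize = sq$normalize,
                               gap_policy = sq$hamming_gap_policy)
  write_distance_matrix(D, tsv_path = file.path(outdir, "distances.tsv"),
                        phylip_path = file.path(outdir, "distances.phylip"))
  tree <- upgma_tree(D)
  write_newick(tree, file.path(outdir, "cladogram.nwk"))

  region_mats <- list()
  if (!is.null(regions)) {
    for (nm in names(regions)) {
      rd <- tryCatch(
        region_distance_submatrix(alignment, regions[[nm]],
                                  normalize = sq$normalize,
                                  gap_policy = sq$hamming_gap_policy),
        error = function(e) {
          warning("region '", nm, "' failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(rd)) next
      region_mats[[nm]] <- rd
      write_distance_matrix(rd,
        tsv_path = file.path(outdir, sprintf("distances_region_%s.tsv", nm)))
    }
  }
  write_manifest(outdir)
  invisible(list(entropy = ent, distances = D, tree = tree,
                 regions = region_mats))
}
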