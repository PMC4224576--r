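#' Run the full image-processing pipeline on one frame
#'
#' For each leaflet: rasterise and smooth the DPPC, DUPC and cholesterol
#' markers, derive the Lo/Ld mask from the DUPC-DPPC difference, detect the
#' interface, label domains, and measure Ld fraction, interface length,
#' domain count/radius and the cholesterol Ld partition. Across leaflets:
#' the phase match map and mismatch fraction, and (optionally) interpolated
#' leaflet surfaces, the thickness field and per-phase thickness statistics.
#' Proteins present in the frame are classified against the mask of their
#' own leaflet (assigned by the side of the midplane their centre of mass
#' lies on).
#'
#' @param frame a [cg_frame()]; wrapped internally.
#' @param sigma_lipid lipid kernel width in Angstrom; `NULL` (default)
#'   derives it per leaflet with [lipid_kernel_width()] from the leaflet's
#'   own lipid count and box area.
#' @param sigma_canny Canny smoothing width in Angstrom (default 2.0).
#' @param sigma_protein protein footprint width in Angstrom (default 20).
#' @param classify_threshold protein phase-majority threshold (default 0.8).
#' @param min_area domain area filter in squared Angstrom (default 100).
#' @param clean_min_area when non-`NULL`, apply [clean_mask()] with this
#'   area threshold to each leaflet mask before edge detection and domain
#'   labelling (island removal; default `NULL`, masks untouched).
#' @param thickness compute leaflet surfaces and thickness statistics
#'   (default `FALSE`; the sparse solve is the most expensive stage).
#' @param keep_fields keep the masks, edge maps, match map and fields on the
#'   result (default `FALSE`, metrics only).
#' @return list of class `frame_analysis`: `per_leaflet` (data.frame with
#'   one row per leaflet: `time`, `leaflet`, `ld_fraction`,
#'   `interface_length`, `n_domains`, `mean_radius`, `chol_ld_fraction`),
#'   `bilayer` (one row: `time`, `mismatch_fraction`, and thickness columns
#'   when computed), `proteins` (per-protein records), and optionally the
#'   intermediate fields.
#' @export
analyze_frame <- function(frame, sigma_lipid = NULL, sigma_canny = 2.0,
                          sigma_protein = 20, classify_threshold = 0.8,
                          min_area = 100, clean_min_area = NULL,
                          thickness = FALSE, keep_fields = FALSE) {
  frame <- wrap_frame(frame)
  grid <- pixel_grid(frame$box[1], frame$box[2])
  assignment <- assign_leaflets(frame)

  masks <- list(); edges <- list(); dens <- list(); surf <- list()
  rows <- list()
  for (leaflet in c("upper", "lower")) {
    dppc <- species_density(frame, "DPPC", assignment, leaflet, grid, sigma_lipid)
    dupc <- species_density(frame, "DUPC", assignment, leaflet, grid,
                            sigma = dppc$sigma)
    chol <- species_density(frame, "CHOL", assignment, leaflet, grid,
                            sigma = dppc$sigma)
    mask <- phase_mask(dupc, dppc)
    if (!is.null(clean_min_area)) mask <- clean_mask(mask, clean_min_area)
    edge <- detect_interface(mask, smoothing_sigma = sigma_canny)
    doms <- label_domains(mask)
    mr <- tryCatch(mean_domain_radius(doms, min_area = min_area),
                   error = function(e) NA_real_)
    chol_ld <- if (density_integral(chol) > 1e-9)
      species_partition(chol, mask) else NA_real_
    rows[[leaflet]] <- data.frame(
      time = frame$time, leaflet = leaflet, ld_fraction = ld_fraction(mask),
      interface_length = interface_length(edge),
      n_domains = sum(doms$phase == "Ld" & doms$area >= min_area),
      mean_radius = mr, chol_ld_fraction = chol_ld)
    masks[[leaflet]] <- mask
    edges[[leaflet]] <- edge
    dens[[leaflet]] <- list(DPPC = dppc, DUPC = dupc, CHOL = chol)
  }

  match <- leaflet_match(masks$upper, masks$lower)
  bilayer <- data.frame(time = frame$time,
                        mismatch_fraction = unname(match$fractions["mismatch"]))

  thick <- NULL; tstats <- NULL
  if (thickness) {
    po4 <- rbind(select_markers(frame, "DPPC"), select_markers(frame, "DUPC"))
    for (leaflet in c("upper", "lower"))
      surf[[leaflet]] <- leaflet_surface(
        leaflet_markers(po4, assignment, leaflet), grid, leaflet)
    thick <- thickness_field(surf$upper, surf$lower)
    tstats <- phase_thickness_stats(thick, match)
    st <- tstats$stats
    getm <- function(cat) if (cat %in% st$category) st$mean[st$category == cat] else NA_real_
    bilayer$mean_thickness <- tstats$global_mean
    bilayer$thickness_both_Lo <- getm("both_Lo")
    bilayer$thickness_both_Ld <- getm("both_Ld")
    bilayer$thickness_mismatch <- getm("mismatch")
  }

  prot <- select_markers(frame, "PROTEIN")
  proteins <- NULL
  if (nrow(prot) > 0L) {
    prot$leaflet <- ifelse(prot$z >= assignment$midplane_z, "upper", "lower")
    prot$protein_id <- seq_len(nrow(prot))
    proteins <- do.call(rbind, lapply(c("upper", "lower"), function(lf) {
      p <- prot[prot$leaflet == lf, , drop = FALSE]
      protein_records(p, masks[[lf]], sigma = sigma_protein,
                      threshold = classify_threshold)
    }))
  }

  out <- list(per_leaflet = do.call(rbind, rows), bilayer = bilayer,
              proteins = proteins, match_fractions = match$fractions,
              thickness_stats = tstats)
  if (keep_fields) {
    out$masks <- masks; out$edges <- edges; out$densities <- dens
    out$match <- match; out$surfaces <- surf; out$thickness_field <- thick
  }
  structure(out, class = "frame_analysis")
}

#' Run the pipeline over a sequence of frames
#'
#' @param frames list of [cg_frame()]s (e.g. from [read_gro_frames()] or a
#'   generator).
#' @param ... forwarded to [analyze_frame()].
#' @return list of class `trajectory_analysis` with row-bound `per_leaflet`,
#'   `bilayer` and `proteins` tables. Any stage failure is rethrown naming
#'   the frame index.
#' @export
analyze_frames <- function(frames, ...) {
  res <- lapply(seq_along(frames), function(i) {
    tryCatch(analyze_frame(frames[[i]], ...),
             error = function(e) stop("frame ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  structure(list(
    per_leaflet = do.call(rbind, lapply(res, `[[`, "per_leaflet")),
    bilayer = do.call(rbind, lapply(res, `[[`, "bilayer")),
    proteins = do.call(rbind, lapply(res, `[[`, "proteins"))),
    class = "trajectory_analysis")
}

#' Inter-leaflet mismatch of randomly mixed bilayers over several seeds
#'
#' Generates randomly mixed bilayer frames and measures the fraction of the
#' box where the two leaflets' Lo/Ld masks disagree — the expected starting
#' point of a phase-separation trajectory, before any demixing. Two
#' statistically independent leaflets thresholded at their own means
#' disagree on about half of the area.
#'
#' Only the stages the measurement needs are run (DPPC/DUPC densities,
#' masks, match map), so many seeds are cheap.
#'
#' @param seeds integer vector of generator seeds, one frame per seed.
#' @param composition a [composition_spec()] (default: 3000 lipids per
#'   leaflet at 5:3:2).
#' @param box lateral box in Angstrom (default 400 x 400).
#' @param sigma lipid kernel width; `NULL` derives it from the leaflet
#'   lipid count and box area.
#' @return numeric vector of per-seed mismatch fractions.
#' @export
mixed_mismatch_fractions <- function(seeds, composition = composition_spec(3000),
                                     box = c(400, 400), sigma = NULL) {
  vapply(seeds, function(s) {
    frame <- wrap_frame(random_mixed_frame(composition, box = box, seed = s)$frame)
    grid <- pixel_grid(frame$box[1], frame$box[2])
    assignment <- assign_leaflets(frame)
    masks <- lapply(c(upper = "upper", lower = "lower"), function(lf) {
      dppc <- species_density(frame, "DPPC", assignment, lf, grid, sigma)
      dupc <- species_density(frame, "DUPC", assignment, lf, grid,
                              sigma = dppc$sigma)
      phase_mask(dupc, dppc)
    })
    unname(leaflet_match(masks$upper, masks$lower)$fractions["mismatch"])
  }, numeric(1))
}

#' Export a field's matrix as a plain-text table
#'
#' @param field any field object with `values` (density, mask, edge map,
#'   surface, thickness) or a bare matrix.
#' @param path output file; tab-separated, rows index x.
#' @return `path`, invisibly.
#' @export
write_field_matrix <- function(field, path) {
  m <- if (is.matrix(field)) field else field$values
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
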