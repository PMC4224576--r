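#' Gaussian footprint of a protein centre of mass
#'
#' A unit-integral periodic Gaussian of width `sigma` (default 20 Angstrom,
#' half the ~40 Angstrom contact distance between two protein centres of
#' mass) centred at the protein's lateral centre of mass. Mass wrapping
#' around the box is handled exactly, so a footprint at a box corner spreads
#' into all four quadrants and still integrates to one.
#'
#' @param com length-2 numeric `(x, y)` in Angstrom, wrapped into the box.
#' @param grid a [pixel_grid()].
#' @param sigma Gaussian width (standard deviation) in Angstrom.
#' @return a `density_field` with unit mass.
#' @export
protein_footprint <- function(com, grid, sigma = 20) {
  stopifnot(inherits(grid, "pixel_grid"), length(com) == 2L)
  if (any(com < 0) || com[1] >= grid$Lx || com[2] >= grid$Ly)
    stop("protein centre of mass must be wrapped into [0, L)")
  if (sigma <= 0) stop("kernel width must be positive")
  if (sigma > min(grid$Lx, grid$Ly) / 2)
    stop("kernel wider than half the box")
  wrapped_at <- function(n, px, L, c0) {
    xc <- (seq_len(n) - 0.5) * px
    K <- ceiling(6 * sigma / L) + 1L
    g <- numeric(n)
    for (k in -K:K) g <- g + exp(-((xc - c0 + k * L)^2) / (2 * sigma^2))
    g
  }
  v <- outer(wrapped_at(grid$nx, grid$px, grid$Lx, com[1]),
             wrapped_at(grid$ny, grid$py, grid$Ly, com[2]))
  v <- v / sum(v)
  structure(list(values = v / (grid$px * grid$py), grid = grid, sigma = sigma,
                 species = "PROTEIN", leaflet = NA_character_,
                 time = NA_real_), class = "density_field")
}

#' Classify a protein as Lo, Ld or interfacial from its footprint
#'
#' The Ld fraction under the protein is the footprint-weighted average of the
#' phase mask, `f_Ld = sum(footprint * mask) / sum(footprint)`; `f_Lo` is its
#' complement. A protein belongs to a phase when that phase holds strictly
#' more than `threshold` (default 80%) of its footprint; otherwise it is
#' interfacial. Exactly 80% is interfacial (strict inequality). Proteins are
#' classified against the mask of their own leaflet.
#'
#' @param footprint a [protein_footprint()].
#' @param mask a [phase_mask()] on the same grid.
#' @param threshold phase-majority threshold (default 0.8).
#' @return list with `f_Lo`, `f_Ld` (summing to 1) and `label` in
#'   `c("Lo", "Ld", "interfacial")`.
#' @export
classify_protein <- function(footprint, mask, threshold = 0.8) {
  stop_unless_same_grid(footprint$grid, mask$grid)
  w <- footprint$values
  f_ld <- sum(w * (mask$values == 1L)) / sum(w)
  f_lo <- 1 - f_ld
  label <- if (f_lo > threshold) "Lo" else if (f_ld > threshold) "Ld" else
    "interfacial"
  list(f_Lo = f_lo, f_Ld = f_ld, label = label)
}

#' Per-frame protein phase records for one leaflet
#'
#' @param coms data.frame with `protein_id`, `x`, `y` (wrapped Angstrom).
#' @param mask the leaflet's [phase_mask()].
#' @param sigma footprint width in Angstrom.
#' @param threshold phase-majority threshold.
#' @return data.frame `time`, `leaflet`, `protein_id`, `x`, `y`, `f_Lo`,
#'   `f_Ld`, `label`.
#' @export
protein_records <- function(coms, mask, sigma = 20, threshold = 0.8) {
  if (nrow(coms) == 0L)
    return(data.frame(time = numeric(), leaflet = character(),
                      protein_id = integer(), x = numeric(), y = numeric(),
                      f_Lo = numeric(), f_Ld = numeric(), label = character()))
  res <- lapply(seq_len(nrow(coms)), function(i) {
    fp <- protein_footprint(c(coms$x[i], coms$y[i]), mask$grid, sigma)
    cl <- classify_protein(fp, mask, threshold)
    data.frame(time = mask$time, leaflet = mask$leaflet,
               protein_id = coms$protein_id[i], x = coms$x[i], y = coms$y[i],
               f_Lo = cl$f_Lo, f_Ld = cl$f_Ld, label = cl$label)
  })
  do.call(rbind, res)
}

#' Protein phase-localization counts over time
#'
#' Collapses per-protein records into per-frame, per-leaflet counts of Lo,
#' Ld and interfacial proteins. The protein id set must be identical in
#' every frame of a leaflet; a missing protein is an error naming the frame
#' time and id. Counts always sum to the number of proteins in the leaflet.
#'
#' @param records data.frame as produced by [protein_records()] over several
#'   frames (columns `time`, `leaflet`, `protein_id`, `label`).
#' @return data.frame `time`, `leaflet`, `n_Lo`, `n_Ld`, `n_interfacial`,
#'   `n_total`, time-sorted within leaflet.
#' @export
localization_timeseries <- function(records) {
  stopifnot(all(c("time", "leaflet", "protein_id", "label") %in% names(records)))
  out <- list()
  for (lf in unique(records$leaflet)) {
    r <- records[records$leaflet == lf, , drop = FALSE]
    ids <- sort(unique(r$protein_id))
    for (tm in sort(unique(r$time))) {
      rt <- r[r$time == tm, , drop = FALSE]
      missing <- setdiff(ids, rt$protein_id)
      if (length(missing))
        stop(sprintf("protein id %d missing from %s leaflet at t = %g",
                     missing[1], lf, tm))
      if (anyDuplicated(rt$protein_id))
        stop(sprintf("duplicate protein id in %s leaflet at t = %g", lf, tm))
      out[[length(out) + 1L]] <- data.frame(
        time = tm, leaflet = lf,
        n_Lo = sum(rt$label == "Lo"), n_Ld = sum(rt$label == "Ld"),
        n_interfacial = sum(rt$label == "interfacial"), n_total = nrow(rt))
    }
  }
  do.call(rbind, out)
}
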