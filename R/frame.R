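#' Construct a coarse-grained bilayer frame
#'
#' A frame is one time point of a coarse-grained simulation: a table of beads
#' (name, residue name, residue id, x/y/z position in Angstrom) together with
#' the periodic box dimensions and the frame time.
#'
#' All coordinates in this package are in Angstrom; GRO files (which store
#' nanometres) are converted on read and write.
#'
#' @param beads data.frame with columns `bead`, `resname`, `resid`, `x`, `y`,
#'   `z` (Angstrom).
#' @param box numeric length-3 vector `(Lx, Ly, Lz)` in Angstrom, all > 0.
#' @param time frame time in ns.
#' @return An object of class `cg_frame`.
#' @export
cg_frame <- function(beads, box, time = 0) {
  stopifnot(is.data.frame(beads),
            all(c("bead", "resname", "resid", "x", "y", "z") %in% names(beads)))
  box <- as.numeric(box)
  if (length(box) == 2L) box <- c(box, 0)  # lateral-only callers
  if (length(box) != 3L || any(!is.finite(box)) || any(box[1:2] <= 0))
    stop("box must be three positive lengths (Lx, Ly, Lz) in Angstrom")
  structure(list(beads = beads, box = box, time = as.numeric(time)),
            class = "cg_frame")
}

#' @export
#' @method print cg_frame
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame> %d beads, %d molecules, box %.1f x %.1f x %.1f A, t = %g ns\n",
              nrow(x$beads), length(unique(x$beads$resid)),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Wrap all bead coordinates into the primary periodic box
#'
#' Applies the minimum positive remainder so every coordinate component lies
#' in `[0, L)` for its box edge. Idempotent; displacements are integer
#' multiples of the box edges.
#'
#' @param frame a [cg_frame()].
#' @return The frame with wrapped coordinates.
#' @export
wrap_frame <- function(frame) {
  stopifnot(inherits(frame, "cg_frame"))
  b <- frame$beads
  if (any(!is.finite(b$x)) || any(!is.finite(b$y)) || any(!is.finite(b$z)))
    stop("non-finite coordinate in frame")
  b$x <- b$x %% frame$box[1]
  b$y <- b$y %% frame$box[2]
  if (frame$box[3] > 0) b$z <- b$z %% frame$box[3]
  frame$beads <- b
  frame
}

#' Select per-molecule marker points for one species
#'
#' Phospholipids are represented by their phosphate (`PO4`) bead, cholesterol
#' by its hydroxyl (`ROH`) bead, and proteins by the equal-weight centre of
#' mass of all their beads (computed with minimum-image unwrapping relative to
#' the first bead of each molecule, then wrapped back into the box).
#'
#' @param frame a [cg_frame()].
#' @param species one of `"DPPC"`, `"DUPC"`, `"CHOL"`, `"PROTEIN"`.
#' @param protein_resnames residue names treated as protein.
#' @return data.frame with columns `resid`, `x`, `y`, `z` (one row per
#'   molecule of the species).
#' @export
select_markers <- function(frame, species, protein_resnames = "PROT") {
  stopifnot(inherits(frame, "cg_frame"))
  species <- match.arg(species, c("DPPC", "DUPC", "CHOL", "PROTEIN"))
  b <- frame$beads
  if (species == "PROTEIN") {
    pb <- b[b$resname %in% protein_resnames, , drop = FALSE]
    if (nrow(pb) == 0L)
      return(data.frame(resid = integer(), x = numeric(), y = numeric(),
                        z = numeric()))
    com_one <- function(d) {
      # minimum-image unwrap about the first bead before averaging
      ref <- c(d$x[1], d$y[1], d$z[1])
      L <- frame$box
      ux <- d$x - L[1] * round((d$x - ref[1]) / L[1])
      uy <- d$y - L[2] * round((d$y - ref[2]) / L[2])
      uz <- if (L[3] > 0) d$z - L[3] * round((d$z - ref[3]) / L[3]) else d$z
      c(mean(ux), mean(uy), mean(uz))
    }
    coms <- do.call(rbind, lapply(split(pb, pb$resid), com_one))
    resid <- as.integer(names(split(pb, pb$resid)))
    out <- data.frame(resid = resid, x = coms[, 1] %% frame$box[1],
                      y = coms[, 2] %% frame$box[2], z = coms[, 3])
    return(out[order(out$resid), , drop = FALSE])
  }
  marker <- if (species == "CHOL") "ROH" else "PO4"
  sel <- b[b$resname == species & b$bead == marker, , drop = FALSE]
  if (anyDuplicated(sel$resid))
    stop("multiple '", marker, "' markers found for one ", species, " molecule")
  data.frame(resid = sel$resid, x = sel$x, y = sel$y, z = sel$z)
}

#' Assign lipid molecules to leaflets by a flat midplane
#'
#' The midplane is the mean z of all phospholipid phosphate markers; every
#' lipid (phospholipid by its PO4 bead, cholesterol by its ROH bead) is
#' assigned to the upper or lower leaflet by the side of the midplane its
#' marker lies on. A marker exactly on the midplane is assigned upper with a
#' warning. Frames where more than 5% of markers lie within 5 Angstrom of the
#' midplane (suggesting undulation or an unwrapped bilayer) trigger a warning.
#'
#' The flat-midplane rule is this package's choice; it is appropriate for
#' bilayers that do not undulate significantly.
#'
#' @param frame a wrapped [cg_frame()].
#' @param protein_resnames residue names excluded as protein.
#' @return list of class `leaflet_assignment` with `mapping` (data.frame
#'   `resid`, `resname`, `leaflet`) and `midplane_z`.
#' @export
assign_leaflets <- function(frame, protein_resnames = "PROT") {
  stopifnot(inherits(frame, "cg_frame"))
  b <- frame$beads
  po4 <- b[b$bead == "PO4" & !(b$resname %in% protein_resnames), , drop = FALSE]
  roh <- b[b$bead == "ROH" & !(b$resname %in% protein_resnames), , drop = FALSE]
  if (nrow(po4) + nrow(roh) < 2L)
    stop("frame must contain at least two phosphate/hydroxyl markers")
  if (nrow(po4) == 0L) stop("no phosphate (PO4) markers found")
  midplane <- mean(po4$z)
  mk <- rbind(po4[, c("resid", "resname", "z")], roh[, c("resid", "resname", "z")])
  near <- abs(mk$z - midplane) < 5
  if (mean(near) > 0.05)
    warning(sprintf(
      "%.1f%% of leaflet markers lie within 5 A of the midplane; %s",
      100 * mean(near),
      "the flat-midplane leaflet assignment may be unreliable"))
  on_plane <- mk$z == midplane
  if (any(on_plane))
    warning(sum(on_plane), " marker(s) exactly on the midplane assigned to the upper leaflet")
  leaflet <- ifelse(mk$z >= midplane, "upper", "lower")
  structure(list(
    mapping = data.frame(resid = mk$resid, resname = mk$resname,
                         leaflet = leaflet),
    midplane_z = midplane
  ), class = "leaflet_assignment")
}

#' Restrict markers to one leaflet
#'
#' @param markers data.frame from [select_markers()].
#' @param assignment a [assign_leaflets()] result.
#' @param leaflet `"upper"` or `"lower"`.
#' @return the subset of `markers` whose molecules belong to `leaflet`.
#' @export
leaflet_markers <- function(markers, assignment, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  stopifnot(inherits(assignment, "leaflet_assignment"))
  keep <- assignment$mapping$resid[assignment$mapping$leaflet == leaflet]
  markers[markers$resid %in% keep, , drop = FALSE]
}
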