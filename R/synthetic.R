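#' Lipid composition of a synthetic leaflet
#'
#' Scales the reference 5:3:2 DPPC:DUPC:cholesterol mixture (751:450:299 per
#' 1500 lipids) to the requested leaflet size with largest-remainder
#' rounding, so the ratio is preserved within integer rounding and the
#' counts sum exactly to `n_per_leaflet`.
#'
#' @param n_per_leaflet lipids per leaflet (default 3000).
#' @param ratio reference counts per species.
#' @return object of class `composition_spec`: named integer `counts`
#'   (per leaflet) and `n_per_leaflet`.
#' @export
composition_spec <- function(n_per_leaflet = 3000,
                             ratio = c(DPPC = 751, DUPC = 450, CHOL = 299)) {
  stopifnot(n_per_leaflet > 0, all(ratio >= 0), sum(ratio) > 0)
  q <- ratio / sum(ratio) * n_per_leaflet
  counts <- floor(q)
  short <- n_per_leaflet - sum(counts)
  if (short > 0) {
    add <- order(q - counts, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1
  }
  structure(list(counts = stats::setNames(as.integer(counts), names(ratio)),
                 n_per_leaflet = as.integer(n_per_leaflet)),
            class = "composition_spec")
}

#' Fraction of phospholipids that are DPPC
#' @param composition a [composition_spec()].
#' @return DPPC / (DPPC + DUPC).
#' @export
dppc_phospholipid_fraction <- function(composition) {
  ct <- composition$counts
  unname(ct["DPPC"] / (ct["DPPC"] + ct["DUPC"]))
}

#' Total coarse-grained bead count of a solvated bilayer system
#'
#' Exact integer bookkeeping: lipid counts times beads per molecule (MARTINI
#' v2.1 mapping: 12 beads per DPPC or DUPC, 8 per cholesterol) plus
#' single-bead solvent (water and ion) counts.
#'
#' @param lipid_counts named counts, e.g. `c(DPPC = 3004, DUPC = 1800,
#'   CHOL = 1196)` for the 6000-lipid system.
#' @param solvent_counts named or unnamed single-bead solvent counts.
#' @param beads_per_molecule beads per lipid molecule by species.
#' @return integer total bead count.
#' @export
count_system_beads <- function(lipid_counts, solvent_counts = c(),
                               beads_per_molecule = c(DPPC = 12, DUPC = 12,
                                                      CHOL = 8)) {
  if (length(lipid_counts) && is.null(names(lipid_counts)))
    stop("lipid_counts must be named by species")
  unknown <- setdiff(names(lipid_counts), names(beads_per_molecule))
  if (length(unknown))
    stop("no beads-per-molecule entry for: ", paste(unknown, collapse = ", "))
  lip <- sum(lipid_counts * beads_per_molecule[names(lipid_counts)])
  as.integer(lip + sum(solvent_counts))
}

#' Blue-noise lateral positions in a periodic box
#'
#' Dart-throwing (random sequential adsorption) with a minimum pairwise
#' minimum-image distance, emulating liquid in-plane disorder without the
#' moire artefacts a lattice would produce on a 1 Angstrom pixel grid.
#' Deterministic under `set.seed()`.
#'
#' @param n points to place.
#' @param Lx,Ly box edges in Angstrom.
#' @param min_dist minimum pairwise distance (default 5 Angstrom).
#' @return data.frame `x`, `y`.
#' @export
blue_noise_points <- function(n, Lx, Ly, min_dist = 5) {
  cover <- n * pi * (min_dist / 2)^2 / (Lx * Ly)
  if (cover > 0.52)
    stop(sprintf("infeasible density: %d points at min_dist %.1f cover %.0f%% of the box",
                 n, min_dist, 100 * cover))
  p <- poisson_disk_cpp(as.integer(n), Lx, Ly, min_dist, 2000)
  data.frame(x = p[, 1], y = p[, 2])
}

# ---- internal assembly helpers ------------------------------------------

lipid_beads <- function(pts, species, z) {
  data.frame(bead = ifelse(species == "CHOL", "ROH", "PO4"),
             resname = species, resid = seq_along(species),
             x = pts$x, y = pts$y, z = z)
}

# species by signed distance into the Ld region: DUPC inside, DPPC/CHOL at
# the reference Lo ratio outside, a 50/50 coin inside the thin mixing band
assign_species_by_region <- function(d, mixing_band, lo_ratio = c(DPPC = 751, CHOL = 299)) {
  n <- length(d)
  species <- character(n)
  p_dppc <- lo_ratio[["DPPC"]] / sum(lo_ratio)
  lo_draw <- function(m) ifelse(stats::runif(m) < p_dppc, "DPPC", "CHOL")
  inside <- d > mixing_band / 2
  outside <- d < -mixing_band / 2
  band <- !inside & !outside
  species[inside] <- "DUPC"
  species[outside] <- lo_draw(sum(outside))
  if (any(band)) {
    coin <- stats::runif(sum(band)) < 0.5
    sp <- character(sum(band))
    sp[coin] <- "DUPC"
    sp[!coin] <- lo_draw(sum(!coin))
    species[band] <- sp
  }
  species
}

min_image_dist <- function(x1, y1, x2, y2, Lx, Ly) {
  dx <- abs(x1 - x2); dy <- abs(y1 - y2)
  dx <- pmin(dx, Lx - dx); dy <- pmin(dy, Ly - dy)
  sqrt(dx^2 + dy^2)
}

# signed lateral distance into the Ld region (> 0 inside) for geometric
# ground truths; approximate Euclidean for the sinusoidal stripe (exact for
# a straight stripe)
truth_signed_distance <- function(truth, x, y, leaflet = "upper") {
  if (truth$kind == "stripe") {
    x0 <- if (leaflet == "lower") truth$x0 + truth$lower_offset else truth$x0
    xl <- x0 + truth$amplitude * sin(2 * pi * y / truth$wavelength)
    xi <- (x - xl) %% truth$box[1]
    ifelse(xi <= truth$stripe_width,
           pmin(xi, truth$stripe_width - xi),
           -pmin(xi - truth$stripe_width, truth$box[1] - xi))
  } else if (truth$kind == "circles") {
    d <- rep(-Inf, length(x))
    for (k in seq_len(nrow(truth$circles))) {
      dk <- truth$circles$radius[k] -
        min_image_dist(x, y, truth$circles$x[k], truth$circles$y[k],
                       truth$box[1], truth$box[2])
      d <- pmax(d, dk)
    }
    d
  } else {
    stop("ground truth of kind '", truth$kind, "' has no phase geometry")
  }
}

build_two_leaflet_frame <- function(pts_u, sp_u, d_u, pts_l, sp_l, d_l,
                                    box, d_lo, d_ld, z_jitter, time) {
  Lz <- d_lo + 60
  th_u <- ifelse(d_u > 0, d_ld, d_lo)
  th_l <- ifelse(d_l > 0, d_ld, d_lo)
  n_u <- nrow(pts_u)
  bu <- lipid_beads(pts_u, sp_u, Lz / 2 + th_u / 2 + stats::rnorm(n_u, 0, z_jitter))
  bl <- lipid_beads(pts_l, sp_l, Lz / 2 - th_l / 2 + stats::rnorm(nrow(pts_l), 0, z_jitter))
  bl$resid <- bl$resid + n_u
  cg_frame(rbind(bu, bl), c(box[1], box[2], Lz), time = time)
}

lipid_truth_df <- function(frame, d_u, d_l, sp_u, sp_l) {
  n_u <- length(sp_u)
  data.frame(resid = seq_len(n_u + length(sp_l)),
             leaflet = rep(c("upper", "lower"), c(n_u, length(sp_l))),
             species = c(sp_u, sp_l),
             phase = ifelse(c(d_u, d_l) > 0, "Ld", "Lo"))
}

# ---- generators ---------------------------------------------------------

#' Randomly mixed synthetic bilayer frame
#'
#' Two leaflets of blue-noise lipid positions with species assigned by a
#' random permutation that realises the composition counts exactly; no
#' lateral phase structure. Leaflet z positions sit at plus/minus half the
#' mixed-phase bilayer thickness (default 41 Angstrom) with Gaussian jitter.
#'
#' @param composition a [composition_spec()].
#' @param box lateral box `(Lx, Ly)` in Angstrom (default 400 x 400).
#' @param seed RNG seed (`set.seed`); `NULL` leaves the RNG state alone.
#' @param d0 mixed-phase leaflet separation in Angstrom.
#' @param z_jitter marker z jitter s.d. in Angstrom.
#' @param min_dist blue-noise minimum distance in Angstrom.
#' @return list with `frame` (a [cg_frame()]) and `truth` (class
#'   `bilayer_truth`, kind `"mixed"`: per-lipid leaflet and species labels;
#'   no phase geometry).
#' @export
random_mixed_frame <- function(composition, box = c(400, 400), seed = NULL,
                               d0 = 41, z_jitter = 1, min_dist = 5) {
  stopifnot(inherits(composition, "composition_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- composition$n_per_leaflet
  species_pool <- rep(names(composition$counts), composition$counts)
  make_leaflet <- function() {
    pts <- blue_noise_points(n, box[1], box[2], min_dist)
    list(pts = pts, sp = sample(species_pool))
  }
  u <- make_leaflet(); l <- make_leaflet()
  Lz <- d0 + 60
  bu <- lipid_beads(u$pts, u$sp, Lz / 2 + d0 / 2 + stats::rnorm(n, 0, z_jitter))
  bl <- lipid_beads(l$pts, l$sp, Lz / 2 - d0 / 2 + stats::rnorm(n, 0, z_jitter))
  bl$resid <- bl$resid + n
  frame <- cg_frame(rbind(bu, bl), c(box, Lz), time = 0)
  truth <- structure(list(
    kind = "mixed", box = box, d0 = d0,
    lipids = data.frame(resid = seq_len(2L * n),
                        leaflet = rep(c("upper", "lower"), each = n),
                        species = c(u$sp, l$sp), phase = NA_character_)),
    class = "bilayer_truth")
  list(frame = frame, truth = truth)
}

#' Phase-separated synthetic frame with one Ld stripe
#'
#' A DUPC-rich Ld stripe (optionally with a sinusoidally perturbed boundary)
#' in a DPPC/cholesterol Lo sea, with a thin mixing band at the interfaces
#' and phase-dependent leaflet separations (ordered thicker than
#' disordered). The true interface length is twice the arc length of the
#' perturbed boundary, computed by quadrature.
#'
#' @param composition a [composition_spec()] (sets the per-leaflet lipid
#'   count and the Lo-region DPPC:CHOL ratio; regional species assignment
#'   means global counts follow the stripe area, not the nominal counts).
#' @param box lateral box `(Lx, Ly)` in Angstrom.
#' @param stripe_width Ld stripe width in Angstrom, in `(0, Lx)`.
#' @param roughness_amplitude sinusoidal boundary amplitude in Angstrom.
#' @param roughness_wavelength boundary wavelength (default `Ly`).
#' @param seed RNG seed.
#' @param d_lo,d_ld Lo/Ld leaflet separations in Angstrom (defaults 45/36).
#' @param mixing_band width of the 50/50 compositional band at interfaces.
#' @param lower_offset lateral x shift of the lower leaflet's stripe,
#'   planting a known mismatch fraction.
#' @param z_jitter,min_dist as in [random_mixed_frame()].
#' @param time frame time in ns.
#' @return list with `frame` and `truth` (kind `"stripe"`: geometry, true
#'   interface length per leaflet, Ld area fraction, mismatch fraction,
#'   leaflet separations, per-lipid phase labels).
#' @export
striped_frame <- function(composition, box = c(400, 400), stripe_width = 120,
                          roughness_amplitude = 0, roughness_wavelength = NULL,
                          seed = NULL, d_lo = 45, d_ld = 36, mixing_band = 3,
                          lower_offset = 0, z_jitter = 1, min_dist = 5,
                          time = 0) {
  stopifnot(inherits(composition, "composition_spec"))
  if (stripe_width <= 0 || stripe_width >= box[1])
    stop("stripe_width must lie strictly between 0 and Lx")
  if (roughness_amplitude < 0 || roughness_amplitude > stripe_width / 2)
    stop("roughness amplitude exceeds the stripe half-width")
  if (is.null(roughness_wavelength)) roughness_wavelength <- box[2]
  if (!is.null(seed)) set.seed(seed)
  n <- composition$n_per_leaflet
  geom <- structure(list(kind = "stripe", box = box,
                         x0 = (box[1] - stripe_width) / 2,
                         stripe_width = stripe_width,
                         amplitude = roughness_amplitude,
                         wavelength = roughness_wavelength,
                         lower_offset = lower_offset),
                    class = "bilayer_truth")
  make_leaflet <- function(leaflet) {
    pts <- blue_noise_points(n, box[1], box[2], min_dist)
    d <- truth_signed_distance(geom, pts$x, pts$y, leaflet)
    list(pts = pts, d = d, sp = assign_species_by_region(d, mixing_band))
  }
  u <- make_leaflet("upper"); l <- make_leaflet("lower")
  frame <- build_two_leaflet_frame(u$pts, u$sp, u$d, l$pts, l$sp, l$d,
                                   box, d_lo, d_ld, z_jitter, time)
  a <- roughness_amplitude; lam <- roughness_wavelength
  arc <- if (a == 0) box[2] else
    stats::integrate(function(y) sqrt(1 + (2 * pi * a / lam)^2 *
                                        cos(2 * pi * y / lam)^2),
                     0, box[2], subdivisions = 500L)$value
  truth <- geom
  truth$interface_length <- 2 * arc
  truth$ld_area_fraction <- stripe_width / box[1]
  truth$mismatch_fraction <- 2 * min(abs(lower_offset), stripe_width) / box[1]
  truth$d_lo <- d_lo; truth$d_ld <- d_ld
  truth$lipids <- lipid_truth_df(frame, u$d, l$d, u$sp, l$sp)
  list(frame = frame, truth = truth)
}

#' Synthetic frame with circular Ld domains in an Lo sea
#'
#' @param composition a [composition_spec()].
#' @param box lateral box in Angstrom.
#' @param radii domain radii in Angstrom.
#' @param centers optional data.frame `x`, `y` of domain centres; checked
#'   for periodic non-overlap with at least 3 Angstrom gaps. `NULL` places
#'   them by rejection sampling.
#' @param seed,d_lo,d_ld,mixing_band,z_jitter,min_dist,time as in
#'   [striped_frame()].
#' @return list with `frame` and `truth` (kind `"circles"`: centres, true
#'   radii, true interface length `2*pi*sum(r)`, per-lipid phase labels).
#' @export
circular_domain_frame <- function(composition, box = c(400, 400), radii = 50,
                                  centers = NULL, seed = NULL, d_lo = 45,
                                  d_ld = 36, mixing_band = 3, z_jitter = 1,
                                  min_dist = 5, time = 0) {
  stopifnot(inherits(composition, "composition_spec"), all(radii > 0))
  if (!is.null(seed)) set.seed(seed)
  radii <- as.numeric(radii)
  if (any(2 * radii + 3 > min(box)))
    stop("a domain of radius ", max(radii), " cannot fit the box with a 3 A gap")
  if (is.null(centers)) {
    ord <- order(radii, decreasing = TRUE)
    cx <- numeric(0); cy <- numeric(0); cr <- numeric(0)
    for (r in radii[ord]) {
      placed <- FALSE
      for (att in seq_len(20000L)) {
        x <- stats::runif(1, 0, box[1]); y <- stats::runif(1, 0, box[2])
        if (length(cx) == 0 ||
              all(min_image_dist(x, y, cx, cy, box[1], box[2]) >= cr + r + 3)) {
          cx <- c(cx, x); cy <- c(cy, y); cr <- c(cr, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place non-overlapping domains; reduce radii")
    }
    centers <- data.frame(x = cx, y = cy)
    radii <- cr
  } else {
    centers <- as.data.frame(centers)
    stopifnot(nrow(centers) == length(radii))
    if (nrow(centers) > 1) {
      for (i in seq_len(nrow(centers) - 1)) {
        j <- (i + 1):nrow(centers)
        dd <- min_image_dist(centers$x[i], centers$y[i], centers$x[j],
                             centers$y[j], box[1], box[2])
        if (any(dd < radii[i] + radii[j] + 3))
          stop("supplied domain centres overlap (3 A periodic gap required)")
      }
    }
  }
  geom <- structure(list(kind = "circles", box = box,
                         circles = data.frame(x = centers$x, y = centers$y,
                                              radius = radii)),
                    class = "bilayer_truth")
  n <- composition$n_per_leaflet
  make_leaflet <- function(leaflet) {
    pts <- blue_noise_points(n, box[1], box[2], min_dist)
    d <- truth_signed_distance(geom, pts$x, pts$y, leaflet)
    list(pts = pts, d = d, sp = assign_species_by_region(d, mixing_band))
  }
  u <- make_leaflet("upper"); l <- make_leaflet("lower")
  frame <- build_two_leaflet_frame(u$pts, u$sp, u$d, l$pts, l$sp, l$d,
                                   box, d_lo, d_ld, z_jitter, time)
  truth <- geom
  truth$radii <- radii
  truth$interface_length <- 2 * pi * sum(radii)
  truth$ld_area_fraction <- sum(pi * radii^2) / (box[1] * box[2])
  truth$d_lo <- d_lo; truth$d_ld <- d_ld
  truth$lipids <- lipid_truth_df(frame, u$d, l$d, u$sp, l$sp)
  list(frame = frame, truth = truth)
}

#' Synthetic coarsening time series with a prescribed growth exponent
#'
#' Emits frames whose characteristic Ld domain radius grows as
#' `r(t) = r_end * (t / t_end)^alpha` while the total Ld area stays fixed,
#' so the domain count shrinks as `n(t) = round(A_Ld / (pi r(t)^2))` and the
#' true interface length `2 pi n(t) r(t)` decreases as the mean radius
#' grows. Domains are placed on a randomly jittered lattice (guaranteed
#' non-overlap); per-domain radii carry small multiplicative noise so frames
#' are independently noisy.
#'
#' @param composition a [composition_spec()].
#' @param box lateral box in Angstrom.
#' @param alpha growth exponent (> 0).
#' @param n_frames number of frames.
#' @param t_end final time in microseconds; frame i sits at `t_end * i /
#'   n_frames`.
#' @param seed RNG seed.
#' @param ld_area_fraction total Ld area fraction (default 0.2).
#' @param r_end characteristic radius at `t_end` (default `min(box)/8`).
#' @param radius_noise s.d. of multiplicative log-normal radius noise.
#' @param ... forwarded to [circular_domain_frame()] (`d_lo`, `d_ld`, ...).
#' @return list with `frames` (list of [cg_frame()]), `truths` (list of
#'   per-frame truths) and `truth_series` (data.frame `time_us`,
#'   `char_length`, `interface_length`, `mean_radius`, `n_domains`).
#' @export
coarsening_series <- function(composition, box = c(400, 400), alpha = 0.5,
                              n_frames = 10, t_end = 5, seed = NULL,
                              ld_area_fraction = 0.2, r_end = NULL,
                              radius_noise = 0.02, ...) {
  stopifnot(alpha > 0, n_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(r_end)) r_end <- min(box) / 8
  A_ld <- ld_area_fraction * box[1] * box[2]
  times <- t_end * seq_len(n_frames) / n_frames
  frames <- list(); truths <- list(); rows <- list()
  for (i in seq_len(n_frames)) {
    r_i <- r_end * (times[i] / t_end)^alpha
    n_i <- max(2L, as.integer(round(A_ld / (pi * r_i^2))))
    radii <- r_i * exp(stats::rnorm(n_i, 0, radius_noise))
    k <- ceiling(sqrt(n_i))
    cellx <- box[1] / k; celly <- box[2] / k
    if (min(cellx, celly) < 2 * max(radii) + 3.2)
      stop("coarsening domains too large for non-overlapping placement")
    cells <- sample(k * k, n_i)
    ci <- (cells - 1) %% k; cj <- (cells - 1) %/% k
    jx <- pmax(0, cellx / 2 - radii - 1.6)
    jy <- pmax(0, celly / 2 - radii - 1.6)
    centers <- data.frame(
      x = (ci + 0.5) * cellx + stats::runif(n_i, -1, 1) * jx,
      y = (cj + 0.5) * celly + stats::runif(n_i, -1, 1) * jy)
    centers$x <- centers$x %% box[1]
    centers$y <- centers$y %% box[2]
    fr <- circular_domain_frame(composition, box, radii = radii,
                                centers = centers, seed = NULL,
                                time = times[i] * 1000, ...)
    frames[[i]] <- fr$frame
    truths[[i]] <- fr$truth
    rows[[i]] <- data.frame(time_us = times[i], char_length = r_i,
                            interface_length = fr$truth$interface_length,
                            mean_radius = mean(radii), n_domains = n_i)
  }
  list(frames = frames, truths = truths,
       truth_series = do.call(rbind, rows))
}

#' Add protein centres of mass with planted phase labels
#'
#' Adds single-bead protein markers (residue name `PROT`) to a synthetic
#' frame. `placement` is either `"hexagonal"` (a staggered lattice ignoring
#' phase truth) or a named count vector such as
#' `c(Lo = 3, Ld = 1, interface = 6)`; phase placements require a truth with
#' phase geometry (stripe or circles) and put Lo/Ld proteins at least
#' `clearance` from any interface (default 4 footprint widths, where the
#' footprint classifier is saturated) and interfacial proteins within
#' `interface_window` of one (default half a footprint width).
#'
#' @param frame a generator [cg_frame()].
#' @param truth the matching `bilayer_truth`.
#' @param n_per_leaflet proteins per leaflet for hexagonal placement
#'   (ignored when `placement` is a count vector).
#' @param placement `"hexagonal"` or named counts over
#'   `c("Lo", "Ld", "interface")`.
#' @param sigma footprint width the labels are planted for (Angstrom).
#' @param clearance minimum interface distance for a planted phase label.
#' @param interface_window maximum interface distance for a planted
#'   interfacial label.
#' @param min_sep minimum protein-protein distance in Angstrom.
#' @param seed RNG seed.
#' @return list with `frame` (proteins appended) and `truth` (gains a
#'   `proteins` data.frame: `protein_id`, `leaflet`, `x`, `y`, `label`).
#' @export
place_proteins <- function(frame, truth, n_per_leaflet = 10,
                           placement = "hexagonal", sigma = 20,
                           clearance = 4 * sigma,
                           interface_window = 0.5 * sigma, min_sep = 30,
                           seed = NULL) {
  stopifnot(inherits(frame, "cg_frame"), inherits(truth, "bilayer_truth"))
  if (!is.null(seed)) set.seed(seed)
  box <- frame$box
  hex_points <- function(n) {
    s <- sqrt(2 * box[1] * box[2] / (sqrt(3) * n))
    pts <- expand.grid(i = 0:ceiling(box[1] / s), j = 0:ceiling(box[2] / (s * sqrt(3) / 2)))
    x <- (pts$i + ifelse(pts$j %% 2 == 1, 0.5, 0)) * s
    y <- pts$j * s * sqrt(3) / 2
    keep <- x < box[1] & y < box[2]
    data.frame(x = x[keep][seq_len(n)], y = y[keep][seq_len(n)])
  }
  sample_label <- function(label, leaflet, placed) {
    for (att in seq_len(20000L)) {
      x <- stats::runif(1, 0, box[1]); y <- stats::runif(1, 0, box[2])
      d <- truth_signed_distance(truth, x, y, leaflet)
      ok <- switch(label,
                   Lo = d <= -clearance,
                   Ld = d >= clearance,
                   interface = abs(d) <= interface_window,
                   stop("unknown placement label '", label, "'"))
      if (ok && (nrow(placed) == 0 ||
                   all(min_image_dist(x, y, placed$x, placed$y,
                                      box[1], box[2]) >= min_sep)))
        return(c(x, y))
    }
    stop("requested '", label, "' placement impossible in this frame's geometry")
  }
  records <- list()
  next_resid <- max(frame$beads$resid) + 1L
  next_id <- 1L
  beads <- list()
  for (leaflet in c("upper", "lower")) {
    zl <- if (leaflet == "upper") max(frame$beads$z) + 5 else min(frame$beads$z) - 5
    if (identical(placement, "hexagonal")) {
      pts <- hex_points(n_per_leaflet)
      labels <- rep(NA_character_, n_per_leaflet)
    } else {
      counts <- placement
      if (is.null(names(counts))) stop("placement counts must be named")
      pts <- data.frame(x = numeric(0), y = numeric(0))
      labels <- character(0)
      for (lab in names(counts)) {
        for (m in seq_len(counts[[lab]])) {
          p <- sample_label(lab, leaflet, pts)
          pts <- rbind(pts, data.frame(x = p[1], y = p[2]))
          labels <- c(labels, if (lab == "interface") "interfacial" else lab)
        }
      }
    }
    nP <- nrow(pts)
    ids <- next_id:(next_id + nP - 1L)
    beads[[leaflet]] <- data.frame(bead = "BB", resname = "PROT",
                                   resid = next_resid:(next_resid + nP - 1L),
                                   x = pts$x, y = pts$y, z = zl)
    records[[leaflet]] <- data.frame(protein_id = ids, leaflet = leaflet,
                                     x = pts$x, y = pts$y, label = labels)
    next_resid <- next_resid + nP
    next_id <- next_id + nP
  }
  frame$beads <- rbind(frame$beads, beads$upper, beads$lower)
  truth$proteins <- rbind(records$upper, records$lower)
  list(frame = frame, truth = truth)
}
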