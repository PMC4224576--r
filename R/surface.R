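#' Continuous leaflet surface from sparse phosphate markers
#'
#' Builds a per-pixel height field z(x, y) for one leaflet from its scattered
#' phosphate marker coordinates. Markers are binned to their pixels (averaged
#' when a pixel holds more than one) and the empty pixels are filled by
#' periodic biharmonic (thin-plate) spline inpainting: the discrete surface
#' minimises the integrated squared Laplacian subject to the marker-pixel
#' values, solved as a sparse symmetric positive-definite system. The
#' interpolant passes exactly through the marker pixels, reproduces planes
#' away from the periodic seam, and is natively periodic (no tiling step is
#' needed and no artificial edge appears at the box boundary).
#'
#' Cholesterol hydroxyl beads are excluded by construction: the surface is
#' defined by phosphate markers only.
#'
#' @param markers data.frame with wrapped `x`, `y` and `z` (Angstrom); at
#'   least 16 markers.
#' @param grid a [pixel_grid()].
#' @param leaflet metadata tag.
#' @return object of class `surface_field`: `values` (z in Angstrom, finite
#'   everywhere), `grid`, `leaflet`, `interpolation`.
#' @export
leaflet_surface <- function(markers, grid, leaflet = NA_character_) {
  stopifnot(inherits(grid, "pixel_grid"))
  n <- nrow(markers)
  if (is.null(n) || n < 16L)
    stop("at least 16 markers are required to build a leaflet surface")
  if (any(markers$x < 0 | markers$x >= grid$Lx |
            markers$y < 0 | markers$y >= grid$Ly))
    stop("markers must be wrapped into [0, L)")

  nx <- grid$nx; ny <- grid$ny; N <- nx * ny
  ix <- pmin(nx - 1L, as.integer(floor(markers$x / grid$px)))
  iy <- pmin(ny - 1L, as.integer(floor(markers$y / grid$py)))
  lin <- ix + nx * iy + 1L
  zbar <- tapply(markers$z, lin, mean)
  fixed <- as.integer(names(zbar))
  zfix <- as.numeric(zbar)

  if (length(fixed) == N) {
    vals <- matrix(NA_real_, nx, ny)
    vals[fixed] <- zfix
  } else {
    A <- periodic_bilaplacian(nx, ny)
    free <- setdiff(seq_len(N), fixed)
    rhs <- -A[free, fixed, drop = FALSE] %*% zfix
    zfree <- Matrix::solve(A[free, free], rhs)
    vals <- matrix(NA_real_, nx, ny)
    vals[fixed] <- zfix
    vals[free] <- as.numeric(zfree)
  }
  structure(list(values = vals, grid = grid, leaflet = leaflet,
                 interpolation = "periodic biharmonic spline"),
            class = "surface_field")
}

# sparse periodic 5-point Laplacian L and its Gram matrix L'L (13-point
# bilaplacian); cached per grid size within a session
periodic_bilaplacian <- local({
  cache <- new.env(parent = emptyenv())
  function(nx, ny) {
    key <- paste(nx, ny, sep = "x")
    if (!is.null(cache[[key]])) return(cache[[key]])
    N <- nx * ny
    idx <- matrix(seq_len(N), nx, ny)
    up <- as.vector(idx[c(2:nx, 1), ])
    down <- as.vector(idx[c(nx, 1:(nx - 1)), ])
    right <- as.vector(idx[, c(2:ny, 1)])
    left <- as.vector(idx[, c(ny, 1:(ny - 1))])
    i <- rep(seq_len(N), 5L)
    j <- c(seq_len(N), up, down, right, left)
    x <- c(rep(-4, N), rep(1, 4L * N))
    L <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N, N))
    A <- Matrix::crossprod(L)
    cache[[key]] <- A
    A
  }
})

#' Bilayer thickness field from two leaflet surfaces
#'
#' Per-pixel difference upper minus lower, measured phosphate-to-phosphate.
#' Non-positive values are unphysical for a bilayer; they are counted and
#' carried on the result (and excluded from [phase_thickness_stats()]).
#'
#' @param upper,lower [leaflet_surface()]s on the same grid.
#' @return object of class `thickness_field`: `values` (Angstrom), `grid`,
#'   `n_unphysical`.
#' @export
thickness_field <- function(upper, lower) {
  stopifnot(inherits(upper, "surface_field"), inherits(lower, "surface_field"))
  stop_unless_same_grid(upper$grid, lower$grid)
  v <- upper$values - lower$values
  structure(list(values = v, grid = upper$grid,
                 n_unphysical = sum(v <= 0)), class = "thickness_field")
}

#' @export
#' @method print thickness_field
print.thickness_field <- function(x, ...) {
  cat(sprintf("<thickness_field> %dx%d px, mean %.2f A, %d unphysical pixel(s)\n",
              x$grid$nx, x$grid$ny, mean(x$values), x$n_unphysical))
  invisible(x)
}

#' Per-phase thickness statistics keyed by the leaflet match map
#'
#' Thickness mean, standard deviation and a fixed-width histogram are
#' computed over the pixels of each match category (both-Lo, both-Ld,
#' mismatch) and globally. Unphysical pixels (thickness <= 0) are excluded
#' throughout; category fractions are computed over the included pixels so
#' the decomposition identity holds exactly:
#' global mean = sum(category fraction x category mean).
#' An empty category is absent from the output, not reported as zero.
#'
#' @param thickness a [thickness_field()].
#' @param match a [leaflet_match()] map on the same grid.
#' @param bin_width histogram bin width in Angstrom (default 0.5).
#' @return list of class `thickness_stats`: `stats` (data.frame `category`,
#'   `n_pixels`, `fraction`, `mean`, `sd`), `histograms` (named list of
#'   data.frames `mid`, `count`), `global_mean`, `n_excluded`.
#' @export
phase_thickness_stats <- function(thickness, match, bin_width = 0.5) {
  stop_unless_same_grid(thickness$grid, match$grid)
  valid <- thickness$values > 0
  t_ok <- thickness$values[valid]
  cat_ok <- match$values[valid]
  if (length(t_ok) == 0L) stop("no physical thickness values to summarise")
  breaks <- seq(floor(min(t_ok) / bin_width) * bin_width,
                ceiling(max(t_ok) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  cats <- c(both_Lo = 0L, both_Ld = 1L, mismatch = 2L)
  rows <- list(); hists <- list()
  for (nm in names(cats)) {
    tv <- t_ok[cat_ok == cats[[nm]]]
    if (length(tv) == 0L) next
    h <- hist(tv, breaks = breaks, plot = FALSE)
    hists[[nm]] <- data.frame(mid = h$mids, count = h$counts)
    rows[[nm]] <- data.frame(category = nm, n_pixels = length(tv),
                             fraction = length(tv) / length(t_ok),
                             mean = mean(tv), sd = stats::sd(tv))
  }
  hg <- hist(t_ok, breaks = breaks, plot = FALSE)
  hists[["global"]] <- data.frame(mid = hg$mids, count = hg$counts)
  rows[["global"]] <- data.frame(category = "global", n_pixels = length(t_ok),
                                 fraction = 1, mean = mean(t_ok),
                                 sd = stats::sd(t_ok))
  structure(list(stats = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 histograms = hists, global_mean = mean(t_ok),
                 n_excluded = sum(!valid)),
            class = "thickness_stats")
}
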