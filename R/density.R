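#' Unit-pixel grid over the lateral box
#'
#' Pixels are nominally 1 x 1 Angstrom: the grid has `round(Lx) x round(Ly)`
#' pixels, so for a fluctuating box the actual pixel edge is `Lx/round(Lx)`
#' (within half a percent of 1 Angstrom for the boxes considered here).
#' Pixel `(i, j)` (0-based) covers the half-open cell
#' `[i*px, (i+1)*px) x [j*py, (j+1)*py)`.
#'
#' @param Lx,Ly lateral box edges in Angstrom.
#' @return object of class `pixel_grid` with fields `nx`, `ny`, `Lx`, `Ly`,
#'   `px`, `py`.
#' @export
pixel_grid <- function(Lx, Ly = Lx) {
  stopifnot(Lx > 0, Ly > 0)
  nx <- max(1L, as.integer(round(Lx)))
  ny <- max(1L, as.integer(round(Ly)))
  structure(list(nx = nx, ny = ny, Lx = Lx, Ly = Ly,
                 px = Lx / nx, py = Ly / ny), class = "pixel_grid")
}

same_grid <- function(a, b) {
  isTRUE(a$nx == b$nx) && isTRUE(a$ny == b$ny) &&
    isTRUE(all.equal(a$Lx, b$Lx)) && isTRUE(all.equal(a$Ly, b$Ly))
}

stop_unless_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("fields are not defined on the same pixel grid")
  invisible(TRUE)
}

#' Rasterize lateral marker positions onto the pixel grid
#'
#' Each point increments the count of the pixel whose half-open cell contains
#' it; two markers sharing a pixel give a count of 2 (counts are not clamped
#' to unity, so no marker is silently merged). The grid total always equals
#' the number of points.
#'
#' @param points data.frame or matrix with x/y (Angstrom), already wrapped
#'   into `[0, L)`.
#' @param grid a [pixel_grid()].
#' @return integer matrix `nx x ny` (rows index x, columns y) of counts.
#' @export
rasterize <- function(points, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  x <- if (is.data.frame(points)) points$x else points[, 1]
  y <- if (is.data.frame(points)) points$y else points[, 2]
  if (length(x) == 0L) return(matrix(0L, grid$nx, grid$ny))
  if (any(x < 0 | x >= grid$Lx | y < 0 | y >= grid$Ly))
    stop("points must be wrapped into [0, L) before rasterization")
  ix <- pmin(grid$nx - 1L, as.integer(floor(x / grid$px)))
  iy <- pmin(grid$ny - 1L, as.integer(floor(y / grid$py)))
  counts <- tabulate(ix + grid$nx * iy + 1L, nbins = grid$nx * grid$ny)
  matrix(as.integer(counts), grid$nx, grid$ny)
}

#' Lipid Gaussian width from the equal-area-per-lipid assumption
#'
#' Assuming every lipid occupies the same share of the leaflet, each lipid's
#' footprint is a circle of area `box_area / n`; the kernel width (standard
#' deviation) is that circle's radius, `sqrt(box_area / (n * pi))`. For 3000
#' lipids in a 400 Angstrom square leaflet this gives 4.1 Angstrom.
#'
#' @param n_lipids_per_leaflet lipid count in one leaflet.
#' @param box_area lateral box area in squared Angstrom.
#' @return kernel width in Angstrom.
#' @export
lipid_kernel_width <- function(n_lipids_per_leaflet, box_area) {
  if (n_lipids_per_leaflet <= 0 || box_area <= 0)
    stop("lipid count and box area must be positive")
  sqrt(box_area / (n_lipids_per_leaflet * pi))
}

# 1D periodic (wrapped) Gaussian sampled at pixel offsets 0..n-1, image sum
# truncated at |k| <= K where K covers 6 sigma.
wrapped_gaussian_1d <- function(n, sigma_px) {
  d <- 0:(n - 1)
  K <- ceiling(6 * sigma_px / n) + 1L
  g <- numeric(n)
  for (k in -K:K) g <- g + exp(-((d + k * n)^2) / (2 * sigma_px^2))
  g
}

# periodic 2D Gaussian kernel with unit sum, origin at element [1, 1]
periodic_gaussian_kernel <- function(grid, sigma) {
  if (sigma <= 0) stop("kernel width must be positive")
  if (sigma > min(grid$Lx, grid$Ly) / 2)
    stop("kernel wider than half the box: phases would be indistinguishable")
  k <- outer(wrapped_gaussian_1d(grid$nx, sigma / grid$px),
             wrapped_gaussian_1d(grid$ny, sigma / grid$py))
  k / sum(k)
}

# circular (periodic) convolution via FFT; kernel origin at [1, 1]
periodic_convolve <- function(values, kernel) {
  Re(stats::fft(stats::fft(values) * stats::fft(kernel), inverse = TRUE)) /
    length(values)
}

#' Smoothed species density field by periodic Gaussian convolution
#'
#' Convolves a rasterized indicator/count grid with a unit-integral periodic
#' Gaussian, giving each marker point a smooth spatial extent. The
#' convolution wraps around the box (the simulation cell is periodic), so
#' density leaving one edge reappears at the opposite edge and the field
#' integral equals the number of contributing points.
#'
#' The kernel width is interpreted as the standard deviation of the Gaussian.
#'
#' @param indicator count matrix from [rasterize()].
#' @param grid the [pixel_grid()] the counts live on.
#' @param sigma Gaussian width (standard deviation) in Angstrom; must be at
#'   least one pixel and less than half the box.
#' @param species,leaflet,time metadata carried on the field.
#' @return object of class `density_field`: `values` (per-pixel density in
#'   points per squared Angstrom), `grid`, `sigma`, `species`, `leaflet`,
#'   `time`.
#' @export
gaussian_density <- function(indicator, grid, sigma,
                             species = NA_character_,
                             leaflet = NA_character_, time = NA_real_) {
  stopifnot(inherits(grid, "pixel_grid"),
            nrow(indicator) == grid$nx, ncol(indicator) == grid$ny)
  if (sigma < max(grid$px, grid$py))
    stop("kernel width must be at least one pixel")
  kern <- periodic_gaussian_kernel(grid, sigma)
  vals <- periodic_convolve(indicator, kern)
  vals <- pmax(vals, 0)  # clip FFT round-off
  structure(list(values = vals / (grid$px * grid$py), grid = grid,
                 sigma = sigma, species = species, leaflet = leaflet,
                 time = time),
            class = "density_field")
}

#' @export
#' @method print density_field
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %s/%s %dx%d px, sigma %.2f A, integral %.2f\n",
              x$species, x$leaflet, x$grid$nx, x$grid$ny, x$sigma,
              density_integral(x)))
  invisible(x)
}

#' Integral of a density field over the box
#'
#' Equals the number of contributing marker points (mass conservation of the
#' periodic convolution).
#'
#' @param field a [gaussian_density()] result.
#' @return total mass (points).
#' @export
density_integral <- function(field) {
  sum(field$values) * field$grid$px * field$grid$py
}

#' Rasterize and smooth one species of one leaflet in one call
#'
#' @param frame a wrapped [cg_frame()].
#' @param species species passed to [select_markers()].
#' @param assignment a [assign_leaflets()] result.
#' @param leaflet `"upper"` or `"lower"`.
#' @param grid a [pixel_grid()]; defaults to the frame's box.
#' @param sigma kernel width in Angstrom; `NULL` derives it with
#'   [lipid_kernel_width()] from the leaflet's total lipid count.
#' @return a `density_field`.
#' @export
species_density <- function(frame, species, assignment, leaflet,
                            grid = NULL, sigma = NULL) {
  if (is.null(grid)) grid <- pixel_grid(frame$box[1], frame$box[2])
  if (is.null(sigma)) {
    n_leaflet <- sum(assignment$mapping$leaflet == leaflet)
    sigma <- lipid_kernel_width(n_leaflet, grid$Lx * grid$Ly)
  }
  mk <- leaflet_markers(select_markers(frame, species), assignment, leaflet)
  gaussian_density(rasterize(mk, grid), grid, sigma, species = species,
                   leaflet = leaflet, time = frame$time)
}
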