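# constructors for hand-built fields used across test files

make_grid <- function(L) pixel_grid(L, L)

make_mask <- function(values, grid, leaflet = "upper", time = 0) {
  structure(list(values = values, grid = grid, leaflet = leaflet,
                 time = time, threshold_used = NA_real_),
            class = "phase_mask")
}

make_density <- function(values, grid, species = "CHOL", leaflet = "upper") {
  structure(list(values = values, grid = grid, sigma = NA_real_,
                 species = species, leaflet = leaflet, time = 0),
            class = "density_field")
}

# composition at the physical areal density (~53 A^2 per lipid) for a box
comp_for_box <- function(L) composition_spec(round(L^2 / 53))

# binary mask of a filled circle (pixel centres inside), periodic distance
circle_mask <- function(grid, cx, cy, r) {
  xs <- (seq_len(grid$nx) - 0.5) * grid$px
  ys <- (seq_len(grid$ny) - 0.5) * grid$py
  dx <- abs(outer(xs, rep(1, grid$ny)) - cx)
  dy <- abs(outer(rep(1, grid$nx), ys) - cy)
  dx <- pmin(dx, grid$Lx - dx)
  dy <- pmin(dy, grid$Ly - dy)
  make_mask(matrix(as.integer(dx^2 + dy^2 < r^2), grid$nx, grid$ny), grid)
}

# binary mask of a vertical Ld stripe covering x in [x0, x0 + w) (wrapped)
stripe_mask <- function(grid, x0, w) {
  xs <- (seq_len(grid$nx) - 0.5) * grid$px
  inside <- ((xs - x0) %% grid$Lx) < w
  make_mask(matrix(as.integer(inside), grid$nx, grid$ny, byrow = FALSE), grid)
}

# rasterize a synthetic truth's phase geometry into a noise-free mask
truth_mask <- function(truth, grid, leaflet = "upper") {
  xs <- rep((seq_len(grid$nx) - 0.5) * grid$px, times = grid$ny)
  ys <- rep((seq_len(grid$ny) - 0.5) * grid$py, each = grid$nx)
  d <- bilayerphase:::truth_signed_distance(truth, xs, ys, leaflet)
  make_mask(matrix(as.integer(d > 0), grid$nx, grid$ny), grid, leaflet)
}
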