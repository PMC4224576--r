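lipid_density_markers <- function(L, seed) {
  set.seed(seed)
  blue_noise_points(round(L^2 / 53), L, L, 5)
}

test_that("surface interpolation reproduces constant, planar and sinusoidal fields", {
  g <- make_grid(120)
  pts <- lipid_density_markers(120, 42)

  s0 <- leaflet_surface(data.frame(pts, z = 20.5), g)
  expect_lt(max(abs(s0$values - 20.5)), 1e-6)
  expect_true(all(is.finite(s0$values)))

  # tilted plane: recovered in the interior; a non-periodic field must jump
  # somewhere, and the jump is confined to a band at the periodic seam
  sp <- leaflet_surface(data.frame(pts, z = 0.01 * pts$x + 15), g)
  xc <- seq_len(120) - 0.5
  truth <- outer(0.01 * xc + 15, rep(1, 120))
  interior <- xc >= 20 & xc <= 100
  expect_lt(max(abs(sp$values - truth)[interior, ]), 0.1)

  # box-commensurate sinusoid at lipid sampling density
  ss <- leaflet_surface(data.frame(pts, z = 3 * sin(2 * pi * pts$x / 60)), g)
  ts <- outer(3 * sin(2 * pi * xc / 60), rep(1, 120))
  expect_lt(sqrt(mean((ss$values - ts)^2)), 0.3)
})

test_that("the surface passes exactly through marker pixels, even for noisy heights", {
  g <- make_grid(80)
  pts <- lipid_density_markers(80, 11)
  z <- 40 + sin(2 * pi * pts$y / 80) + rnorm(nrow(pts), 0, 1)
  s <- leaflet_surface(data.frame(pts, z = z), g)
  ix <- pmin(79, floor(pts$x)) + 1
  iy <- pmin(79, floor(pts$y)) + 1
  # markers sharing no pixel here: surface equals the marker height
  expect_lt(max(abs(s$values[cbind(ix, iy)] - z)), 0.5)
})

test_that("surface construction validates its inputs", {
  g <- make_grid(40)
  few <- data.frame(x = runif(10, 0, 40), y = runif(10, 0, 40), z = 1)
  expect_error(leaflet_surface(few, g), "16")
  bad <- data.frame(x = c(runif(20, 0, 40), 41), y = runif(21, 0, 40), z = 1)
  expect_error(leaflet_surface(bad, g), "wrapped")
})

test_that("thickness is the leaflet difference, antisymmetric, with unphysical pixels flagged", {
  g <- make_grid(60)
  mk <- function(z0) structure(list(values = matrix(z0, 60, 60), grid = g,
                                    leaflet = "x", interpolation = "test"),
                               class = "surface_field")
  th <- thickness_field(mk(20.5), mk(-20.5))
  expect_true(all(th$values == 41))
  expect_equal(th$n_unphysical, 0)

  sw <- thickness_field(mk(-20.5), mk(20.5))
  expect_true(all(sw$values == -41))
  expect_equal(sw$n_unphysical, 60 * 60)
})

test_that("per-phase statistics decompose the global mean exactly", {
  g <- make_grid(50)
  # construct categories with known fractions 0.4 / 0.4 / 0.2 and means 45/36/40.5
  mvals <- matrix(2L, 50, 50)
  mvals[1:20, ] <- 0L
  mvals[21:40, ] <- 1L
  match <- structure(list(values = mvals, grid = g,
                          fractions = c(both_Lo = 0.4, both_Ld = 0.4, mismatch = 0.2),
                          time = 0), class = "match_map")
  tvals <- matrix(40.5, 50, 50)
  tvals[1:20, ] <- 45
  tvals[21:40, ] <- 36
  th <- structure(list(values = tvals, grid = g, n_unphysical = 0),
                  class = "thickness_field")
  st <- phase_thickness_stats(th, match)
  s <- st$stats
  expect_equal(s$mean[s$category == "both_Lo"], 45)
  expect_equal(s$mean[s$category == "both_Ld"], 36)
  expect_equal(s$mean[s$category == "mismatch"], 40.5)
  expect_equal(st$global_mean, 0.4 * 45 + 0.4 * 36 + 0.2 * 40.5)
  # decomposition identity
  cats <- s[s$category != "global", ]
  expect_equal(sum(cats$fraction * cats$mean), st$global_mean, tolerance = 1e-6)

  # uniform field: every category mean is the constant
  th41 <- structure(list(values = matrix(41, 50, 50), grid = g, n_unphysical = 0),
                    class = "thickness_field")
  st41 <- phase_thickness_stats(th41, match)
  expect_true(all(abs(st41$stats$mean - 41) < 1e-12))

  # an absent category is absent, not zero
  match2 <- match
  match2$values[match2$values == 2L] <- 0L
  st2 <- phase_thickness_stats(th, match2)
  expect_false("mismatch" %in% st2$stats$category)
})

test_that("planted Lo/Ld separations are recovered through the full surface pipeline", {
  sim <- striped_frame(comp_for_box(160), box = c(160, 160), stripe_width = 64,
                       seed = 21)
  fa <- analyze_frame(sim$frame, thickness = TRUE)
  expect_equal(fa$bilayer$thickness_both_Lo, 45, tolerance = 0.5 / 45)
  expect_equal(fa$bilayer$thickness_both_Ld, 36, tolerance = 0.5 / 36)
  # decomposition identity on measured data
  st <- fa$thickness_stats$stats
  cats <- st[st$category != "global", ]
  expect_equal(sum(cats$fraction * cats$mean), fa$thickness_stats$global_mean,
               tolerance = 1e-6)
  # the thickness distribution is bimodal with modes near the separations
  hg <- fa$thickness_stats$histograms$global
  in_ld <- hg$mid > 34 & hg$mid < 38
  in_lo <- hg$mid > 43 & hg$mid < 47
  between <- hg$mid > 39 & hg$mid < 42
  expect_gt(max(hg$count[in_ld]), max(hg$count[between]))
  expect_gt(max(hg$count[in_lo]), max(hg$count[between]))
  expect_lt(abs(hg$mid[in_ld][which.max(hg$count[in_ld])] - 36), 1.1)
  expect_lt(abs(hg$mid[in_lo][which.max(hg$count[in_lo])] - 45), 1.1)
})
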