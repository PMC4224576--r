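test_that("composition scaling preserves the 5:3:2 mixture with exact totals", {
  cs <- composition_spec(3000)
  expect_equal(cs$counts, c(DPPC = 1502L, DUPC = 900L, CHOL = 598L))
  expect_equal(sum(cs$counts), 3000L)
  expect_equal(composition_spec(1500)$counts, c(DPPC = 751L, DUPC = 450L, CHOL = 299L))
  # largest-remainder rounding keeps totals exact for awkward sizes
  for (n in c(100, 1234, 2999)) expect_equal(sum(composition_spec(n)$counts), n)
  expect_equal(dppc_phospholipid_fraction(composition_spec(1500)), 751 / 1201)
})

test_that("system bead bookkeeping is exact and linear", {
  expect_identical(count_system_beads(c(DPPC = 3004, DUPC = 1800, CHOL = 1196),
                                      c(W = 65984, NA. = 2016, CL = 2016)),
                   137232L)
  expect_identical(count_system_beads(c(DPPC = 0, DUPC = 0, CHOL = 0), c(W = 10)), 10L)
  expect_identical(count_system_beads(c(DPPC = 2 * 3004, DUPC = 2 * 1800,
                                        CHOL = 2 * 1196),
                                      2 * c(65984, 2016, 2016)),
                   2L * 137232L)
  expect_error(count_system_beads(c(POPC = 10)), "POPC")
})

test_that("generators are deterministic under a seed and decorrelated across seeds", {
  cs <- comp_for_box(80)
  a <- random_mixed_frame(cs, box = c(80, 80), seed = 3)
  b <- random_mixed_frame(cs, box = c(80, 80), seed = 3)
  expect_identical(a$frame$beads, b$frame$beads)
  expect_identical(a$truth$lipids, b$truth$lipids)
  c_ <- random_mixed_frame(cs, box = c(80, 80), seed = 4)
  expect_gt(max(abs(a$frame$beads$x - c_$frame$beads$x)), 1)

  s1 <- striped_frame(cs, box = c(80, 80), stripe_width = 30, seed = 5)
  s2 <- striped_frame(cs, box = c(80, 80), stripe_width = 30, seed = 5)
  expect_identical(s1$frame$beads, s2$frame$beads)
})

test_that("blue-noise placement honours the minimum distance and detects infeasibility", {
  set.seed(8)
  pts <- blue_noise_points(100, 100, 100, min_dist = 5)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  # interior minimum-image check via the periodic helper
  dmin <- min(vapply(seq_len(99), function(i)
    min(bilayerphase:::min_image_dist(pts$x[i], pts$y[i],
                                      pts$x[(i + 1):100], pts$y[(i + 1):100],
                                      100, 100)), numeric(1)))
  expect_gte(dmin, 5)
  expect_error(blue_noise_points(2000, 100, 100, min_dist = 5), "nfeasible")
})

test_that("striped ground truth records geometry, interface length and mismatch", {
  cs <- comp_for_box(100)
  s <- striped_frame(cs, box = c(100, 100), stripe_width = 30, seed = 2)
  expect_equal(s$truth$interface_length, 200)
  expect_equal(s$truth$ld_area_fraction, 0.3)
  expect_equal(s$truth$mismatch_fraction, 0)

  # sinusoidal boundary: arc length from quadrature exceeds the straight one
  a <- 5; lam <- 50
  sr <- striped_frame(cs, box = c(100, 100), stripe_width = 30,
                      roughness_amplitude = a, roughness_wavelength = lam,
                      seed = 2)
  analytic <- 2 * integrate(function(y) sqrt(1 + (2 * pi * a / lam)^2 *
                                               cos(2 * pi * y / lam)^2),
                            0, 100)$value
  expect_equal(sr$truth$interface_length, analytic, tolerance = 1e-6)
  expect_gt(sr$truth$interface_length, 200)

  # planted mismatch by shifting the lower leaflet's stripe
  so <- striped_frame(cs, box = c(100, 100), stripe_width = 30,
                      lower_offset = 10, seed = 2)
  expect_equal(so$truth$mismatch_fraction, 0.2)

  expect_error(striped_frame(cs, box = c(100, 100), stripe_width = 120),
               "stripe_width")
  expect_error(striped_frame(cs, box = c(100, 100), stripe_width = 30,
                             roughness_amplitude = 20), "amplitude")
})

test_that("circular-domain truth is consistent and overlap is rejected", {
  cs <- comp_for_box(200)
  ci <- circular_domain_frame(cs, box = c(200, 200), radii = c(30, 50), seed = 4)
  expect_equal(ci$truth$interface_length, 2 * pi * 80)
  expect_equal(sort(ci$truth$radii), c(30, 50))
  expect_equal(ci$truth$ld_area_fraction, pi * (30^2 + 50^2) / 200^2)

  expect_error(circular_domain_frame(cs, box = c(200, 200), radii = c(40, 40),
                                     centers = data.frame(x = c(50, 100), y = c(50, 50))),
               "overlap")

  # a circle centred on the box corner is still a single domain
  cc <- circular_domain_frame(cs, box = c(200, 200), radii = 40,
                              centers = data.frame(x = 0.1, y = 0.1))
  g <- pixel_grid(200, 200)
  doms <- label_domains(truth_mask(cc$truth, g))
  expect_equal(sum(doms$phase == "Ld"), 1L)
  expect_equal(doms$equivalent_radius[doms$phase == "Ld"], 40, tolerance = 1 / 40)
})

test_that("coarsening series grow as prescribed with interface and radius anti-correlated", {
  cs <- composition_spec(400)
  co <- coarsening_series(cs, box = c(150, 150), alpha = 0.5, n_frames = 8,
                          t_end = 4, seed = 6)
  expect_length(co$frames, 8L)
  ts <- co$truth_series
  expect_true(all(diff(ts$char_length) > 0))
  expect_equal(fit_power_law(list(times = ts$time_us, values = ts$char_length))$alpha,
               0.5, tolerance = 1e-6)
  expect_lt(cor(ts$mean_radius, ts$interface_length, method = "spearman"), 0)
  # noisy truth radii still recover the exponent
  f <- fit_power_law(list(times = ts$time_us, values = ts$mean_radius))
  expect_equal(f$alpha, 0.5, tolerance = 0.05 / 0.5)
})

test_that("protein placement plants labels, reproduces under seeds, and fails loudly", {
  cs <- composition_spec(3000)
  s <- striped_frame(cs, box = c(400, 400), stripe_width = 200, seed = 9)
  hex <- place_proteins(s$frame, s$truth, n_per_leaflet = 10,
                        placement = "hexagonal", seed = 10)
  expect_equal(nrow(hex$truth$proteins), 20L)
  expect_equal(sum(hex$frame$beads$resname == "PROT"), 20L)

  p1 <- place_proteins(s$frame, s$truth, placement = c(Lo = 2, interface = 2), seed = 11)
  p2 <- place_proteins(s$frame, s$truth, placement = c(Lo = 2, interface = 2), seed = 11)
  expect_identical(p1$truth$proteins, p2$truth$proteins)

  # Ld placement at 4 sigma clearance is impossible in a narrow stripe
  narrow <- striped_frame(comp_for_box(200), box = c(200, 200),
                          stripe_width = 40, seed = 12)
  expect_error(place_proteins(narrow$frame, narrow$truth,
                              placement = c(Ld = 1), seed = 13),
               "impossible")
  # and phase placement needs phase geometry
  mixed <- random_mixed_frame(comp_for_box(100), box = c(100, 100), seed = 14)
  expect_error(place_proteins(mixed$frame, mixed$truth, placement = c(Lo = 1)),
               "geometry")
})

test_that("generator frames survive GRO round-trips with leaflet labels intact", {
  s <- striped_frame(comp_for_box(90), box = c(90, 90), stripe_width = 30, seed = 1)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro_frames(s$frame, path)
  back <- read_gro_frames(path)[[1]]
  la <- assign_leaflets(wrap_frame(back))
  merged <- merge(la$mapping, s$truth$lipids, by = "resid")
  expect_identical(merged$leaflet.x, merged$leaflet.y)
})
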