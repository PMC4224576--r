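test_that("mean-threshold masking is strict, per-leaflet, and cholesterol-blind", {
  g <- make_grid(40)
  const <- make_density(matrix(0.01, 40, 40), g, "DUPC")
  # identical constant fields: difference is 0 everywhere, strict > fails
  m <- phase_mask(const, make_density(matrix(0.01, 40, 40), g, "DPPC"))
  expect_true(all(m$values == 0L))
  expect_equal(ld_fraction(m), 0)
  expect_equal(m$threshold_used, 0)

  # half-box step fields: the mask is exactly the DUPC half
  step <- matrix(0, 40, 40); step[1:20, ] <- 0.02
  m2 <- phase_mask(make_density(step, g, "DUPC"),
                   make_density(0.02 - step, g, "DPPC"))
  expect_equal(m2$values[, 1], rep(c(1L, 0L), each = 20))
  expect_equal(ld_fraction(m2), 0.5)

  # swapping the species inverts the mask exactly
  m3 <- phase_mask(make_density(0.02 - step, g, "DUPC"),
                   make_density(step, g, "DPPC"))
  expect_equal(m3$values, 1L - m2$values)

  expect_error(phase_mask(const, make_density(matrix(0.01, 30, 30), make_grid(30), "DPPC")),
               "grid")
})

test_that("masks are unchanged by cholesterol content of the frame", {
  sim <- striped_frame(comp_for_box(100), box = c(100, 100), stripe_width = 40,
                       seed = 8)
  fr <- wrap_frame(sim$frame)
  la <- assign_leaflets(fr)
  g <- pixel_grid(100, 100)
  mask_of <- function(frame, assignment) {
    dppc <- species_density(frame, "DPPC", assignment, "upper", g, 4.1)
    dupc <- species_density(frame, "DUPC", assignment, "upper", g, 4.1)
    phase_mask(dupc, dppc)
  }
  m1 <- mask_of(fr, la)
  no_chol <- fr
  no_chol$beads <- fr$beads[fr$beads$resname != "CHOL", , drop = FALSE]
  m2 <- mask_of(no_chol, assign_leaflets(no_chol))
  expect_identical(m1$values, m2$values)
})

test_that("the periodic Canny detector finds one-pixel chains and no border artefacts", {
  g <- make_grid(400)
  expect_equal(sum(detect_interface(make_mask(matrix(0L, 400, 400), g))$values), 0)

  m <- stripe_mask(g, 140, 120)
  e <- detect_interface(m)
  expect_equal(sum(e$values), 800)
  expect_equal(max(bilayerphase:::label_components_cpp(e$values, 8L, TRUE)), 2L)
  # every edge pixel lies within 2 pixels of a mask transition
  trans <- abs(m$values - bilayerphase:::shift_mat(m$values, 1L, 0L)) +
    abs(m$values - bilayerphase:::shift_mat(m$values, 0L, 1L))
  near <- trans > 0
  for (d in list(c(1,0), c(-1,0), c(0,1), c(0,-1), c(2,0), c(-2,0), c(0,2), c(0,-2)))
    near <- near | bilayerphase:::shift_mat(trans, d[1], d[2]) > 0
  expect_true(all(near[e$values == 1L]))

  # stripe straddling the periodic seam: same result, chains continuous
  ms <- stripe_mask(g, 340, 120)
  es <- detect_interface(ms)
  expect_equal(sum(es$values), 800)
  expect_equal(max(bilayerphase:::label_components_cpp(es$values, 8L, TRUE)), 2L)
})

test_that("interface length estimators behave as documented on known geometry", {
  g <- make_grid(400)
  empty <- detect_interface(make_mask(matrix(0L, 400, 400), g))
  expect_equal(interface_length(empty), 0)

  e <- detect_interface(stripe_mask(g, 140, 120))
  expect_equal(interface_length(e), 800, tolerance = 0.02)          # chain
  expect_equal(interface_length(e, "pixel"), 800, tolerance = 0.02) # pixel

  ec <- detect_interface(circle_mask(g, 200, 200, 50))
  expect_equal(interface_length(ec), 2 * pi * 50, tolerance = 0.10)
  # the bare pixel count is biased low on curved interfaces
  expect_lt(interface_length(ec, "pixel"), interface_length(ec))

  # 45-degree stripe: chain estimator exact, pixel estimator short by sqrt(2)
  xy <- expand.grid(i = seq_len(400) - 0.5, j = seq_len(400) - 0.5)
  diag_mask <- make_mask(matrix(as.integer(((xy$i + xy$j) %% 400) < 160), 400, 400), g)
  ed <- detect_interface(diag_mask)
  expect_equal(interface_length(ed), 2 * 400 * sqrt(2), tolerance = 0.02)
  expect_equal(interface_length(ed, "pixel"), 800, tolerance = 0.02)
})

test_that("domain labelling merges across periodic seams and uses 8-connectivity", {
  g <- make_grid(200)
  d <- label_domains(circle_mask(g, 100, 100, 50))
  ld <- d[d$phase == "Ld", ]
  expect_equal(nrow(ld), 1L)
  expect_equal(ld$equivalent_radius, 50, tolerance = 1 / 50)
  expect_equal(ld$centroid_x, 100, tolerance = 0.5)
  # Lo sea is one wrapped component
  expect_equal(nrow(d[d$phase == "Lo", ]), 1L)
  expect_equal(sum(d$area[d$phase == "Ld"]) + sum(d$area[d$phase == "Lo"]),
               200 * 200)

  # domain straddling the x seam is one domain with a periodic-aware centroid
  ds <- label_domains(circle_mask(g, 2, 100, 30))
  lds <- ds[ds$phase == "Ld", ]
  expect_equal(nrow(lds), 1L)
  expect_equal(lds$equivalent_radius, 30, tolerance = 1 / 30)
  expect_lt(min(abs(c(lds$centroid_x - 2, lds$centroid_x - 202,
                      lds$centroid_x + 198))), 0.5)

  # four squares meeting at corners form a single 8-connected domain
  v <- matrix(0L, 60, 60)
  v[11:20, 11:20] <- 1L; v[21:30, 21:30] <- 1L
  v[11:20, 21:30] <- 0L  # keep the checkerboard: only two filled here
  v[31:40, 11:20] <- 0L
  chk <- make_mask(v, make_grid(60))
  expect_equal(nrow(label_domains(chk)[label_domains(chk)$phase == "Ld", ]), 1L)
})

test_that("periodic labelling agrees with a reference labeller away from the seams", {
  set.seed(2)
  v <- matrix(as.integer(runif(80 * 80) < 0.35), 80, 80)
  # embed in a background frame so periodicity cannot matter
  pad <- matrix(0L, 100, 100)
  pad[11:90, 11:90] <- v
  ours <- bilayerphase:::label_components_cpp(pad, 4L, TRUE)
  ref <- EBImage::bwlabel(pad)  # EBImage: 4-connected components, non-periodic
  # same partition: counts and one-to-one label correspondence
  expect_equal(max(ours), max(ref))
  expect_equal(length(unique(paste(ours[pad == 1L], ref[pad == 1L]))), max(ref))
})

test_that("mean domain radius filters small islands and averages the rest", {
  g <- make_grid(200)
  v <- circle_mask(g, 60, 100, 30)$values | circle_mask(g, 150, 100, 50)$values
  m <- make_mask(v * 1L, g)
  d <- label_domains(m)
  expect_equal(mean_domain_radius(d), 40, tolerance = 1 / 40)

  # five single-pixel specks do not change the answer
  v2 <- m$values
  v2[cbind(c(2, 5, 8, 11, 197), c(2, 190, 3, 180, 5))] <- 1L
  d2 <- label_domains(make_mask(v2, g))
  expect_equal(mean_domain_radius(d2), mean_domain_radius(d))

  expect_error(mean_domain_radius(d, min_area = 1e6), "no domain")
})

test_that("match maps classify pixel pairs and their fractions sum to one", {
  g <- make_grid(50)
  a <- stripe_mask(g, 10, 20)
  expect_equal(unname(leaflet_match(a, a)$fractions["mismatch"]), 0)
  b <- make_mask(1L - a$values, g, leaflet = "lower")
  expect_equal(unname(leaflet_match(a, b)$fractions["mismatch"]), 1)

  # independent random masks at Ld fraction ~1/2 mismatch on ~2p(1-p) of pixels
  set.seed(6)
  mm <- replicate(10, {
    u <- make_mask(matrix(as.integer(runif(2500) < 0.5), 50, 50), g)
    l <- make_mask(matrix(as.integer(runif(2500) < 0.5), 50, 50), g)
    mt <- leaflet_match(u, l)
    expect_equal(sum(mt$fractions), 1, tolerance = 1e-9)
    unname(mt$fractions["mismatch"])
  })
  expect_equal(mean(mm), 0.5, tolerance = 0.05)
})

test_that("species partition is density-weighted mask coverage", {
  g <- make_grid(100)
  mask <- stripe_mask(g, 0, 50)
  uni <- make_density(matrix(0.01, 100, 100), g)
  expect_equal(species_partition(uni, mask), 0.5, tolerance = 1e-3)

  conc <- gaussian_density(rasterize(data.frame(x = 75, y = 50), g), g, 4)
  expect_lt(species_partition(conc, mask), 0.01)  # deep in the Lo half

  expect_error(species_partition(make_density(matrix(0, 100, 100), g), mask),
               "zero")
})

test_that("area opening removes islands below the threshold and nothing else", {
  g <- make_grid(200)
  base <- circle_mask(g, 100, 100, 40)
  v <- base$values
  v[cbind(c(5, 10, 190), c(5, 180, 20))] <- 1L     # 1-px Ld specks
  v[95:96, 95:96] <- 0L                            # 4-px Lo hole inside the domain
  cleaned <- clean_mask(make_mask(v, g), min_area = 100)
  expect_identical(cleaned$values, base$values)
})
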