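test_that("scene builder validates specs and handles the empty compartment", {
  expect_error(compartment_spec(cluster_concentration = -1),
               "cluster_concentration")
  expect_error(compartment_spec(n_membrane_puncta = -5), "n_membrane_puncta")
  expect_error(compartment_spec(radii = c(100, -1, 100)), "radii")
  sc <- build_scene(list(compartment_spec(radii = c(150, 150, 150))), seed = 1)
  expect_equal(nrow(sc$points), 0)
  expect_true(sc$meshes[[1]]$watertight)
  expect_equal(sc$meshes[[1]]$euler, 2)
})

test_that("membrane puncta lie on the shell and scenes are deterministic", {
  cs <- compartment_spec(centroid = c(500, 400, 300),
                         radii = c(150, 150, 150), n_membrane_puncta = 200)
  sc1 <- build_scene(list(cs), seed = 42)
  sc2 <- build_scene(list(cs), seed = 42)
  expect_identical(sc1$points, sc2$points)
  r <- sqrt(rowSums(sweep(as.matrix(sc1$points[, c("x", "y", "z")]),
                          2, c(500, 400, 300))^2))
  expect_true(all(abs(r - 150) < 1e-9))
  # different seed, different draw
  sc3 <- build_scene(list(cs), seed = 43)
  expect_false(identical(sc1$points, sc3$points))
  # clustered membrane puncta stay on an ellipsoid shell
  cs2 <- compartment_spec(radii = c(200, 150, 150), n_membrane_puncta = 100,
                          n_clusters = 5, cluster_concentration = 40)
  sc4 <- build_scene(list(cs2), seed = 1)
  p <- as.matrix(sc4$points[, c("x", "y", "z")])
  expect_true(all(abs(sqrt(rowSums(sweep(p, 2, c(200, 150, 150), "/")^2)) - 1)
                  < 1e-9))
})

test_that("interior puncta are strictly inside the shell", {
  cs <- compartment_spec(radii = c(150, 120, 100), n_interior_puncta = 300)
  sc <- build_scene(list(cs), seed = 3)
  p <- as.matrix(sc$points[, c("x", "y", "z")])
  expect_true(all(sqrt(rowSums(sweep(p, 2, c(150, 120, 100), "/")^2)) < 1))
})

test_that("distortion transforms points per the closed form", {
  # identity
  d0 <- distortion_spec(global_factor = 1)
  p <- rbind(c(100, 200, 300), c(-50, 0, 10))
  expect_equal(apply_distortion(p, d0)$points, p)
  g <- list(dims = c(4, 4, 4), voxel = c(100, 100, 100))
  expect_true(all(apply_distortion(p, d0, grid = g)$field$ux == 0))
  # pure global scale
  d10 <- distortion_spec(global_factor = 10)
  expect_equal(apply_distortion(p, d10)$points, p * 10)
  # one radial bump, evaluated by hand: point 300 nm from the centre with
  # amplitude -0.1 and falloff 300 moves inward by 0.1*exp(-1/2)*300
  dl <- distortion_spec(1, local_centers = c(0, 0, 0),
                        local_amplitude = -0.1, local_falloff = 300)
  got <- apply_distortion(matrix(c(300, 0, 0), 1), dl)$points
  expect_equal(got[1, 1], 300 - 0.1 * exp(-0.5) * 300, tolerance = 1e-12)
  expect_equal(got[1, 2:3], c(0, 0))
  # sampled field equals the analytic formula at grid points
  gf <- apply_distortion(p, dl, grid = list(dims = c(6, 6, 6),
                                            voxel = c(150, 150, 150)))$field
  ctrs <- exmkit:::grid_centers(list(dims = c(6, 6, 6),
                                     voxel = c(150, 150, 150)))
  ana <- local_displacement(dl, ctrs)
  expect_equal(as.vector(gf$ux), ana[, 1])
  expect_equal(as.vector(gf$uz), ana[, 3])
  # fold-over guard
  expect_error(distortion_spec(1, c(0, 0, 0), -1.2, 100), "amplitude")
  expect_warning(distortion_spec(1, c(0, 0, 0), -0.6, 100), "invertib")
})

test_that("ground-truth displacement reproduces the pre-to-post offsets", {
  cs <- compartment_spec(radii = c(150, 150, 150), n_membrane_puncta = 50)
  d <- distortion_spec(4, local_centers = c(100, 100, 100),
                       local_amplitude = -0.2, local_falloff = 500)
  sc <- build_scene(list(cs), distortion = d, seed = 5)
  pre <- as.matrix(sc$points[, c("x", "y", "z")])
  expect_equal(pre + true_displacement(sc, pre, total = TRUE), sc$post_points)
})

test_that("renderer conserves intensity and peaks at the nearest voxel", {
  psf <- psf_model(75, 200)
  g <- list(dims = c(40, 40, 24), voxel = c(25, 25, 50))
  v <- render_volume(matrix(c(512, 488, 600), 1), psf, g, noise = list())
  expect_equal(sum(v$data), 1, tolerance = 0.01)
  pk <- arrayInd(which.max(v$data), dim(v$data))
  expect_equal(as.vector(pk), c(21, 20, 12))  # nearest voxel to the source
  # two sources 10 FWHM apart give two local maxima
  fw <- psf_fwhm(psf)[["lateral"]]
  v2 <- render_volume(rbind(c(210, 505, 610), c(210 + 10 * fw, 505, 610)),
                      psf, list(dims = c(100, 40, 24), voxel = c(25, 25, 50)),
                      noise = list())
  lm <- exmkit:::local_max3(v2$data) & v2$data > 0.2 * max(v2$data)
  expect_equal(sum(lm), 2)
  expect_error(render_volume(matrix(c(-100, 0, 0), 1), psf, g), "outside")
  expect_error(render_volume(matrix(c(1, 1, 1), 1), psf,
                             list(dims = c(8, 8, 8), voxel = c(0, 10, 10))),
               "voxel")
})

test_that("renders are deterministic given the seed, noise follows it", {
  psf <- psf_model(75, 200)
  g <- list(dims = c(24, 24, 12), voxel = c(40, 40, 80))
  pts <- matrix(c(480, 480, 480), 1)
  n <- list(gain = 1000, sd = 0.001)
  a <- render_volume(pts, psf, g, noise = n, seed = 7)
  b <- render_volume(pts, psf, g, noise = n, seed = 7)
  c <- render_volume(pts, psf, g, noise = n, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("rendered point source has the closed-form FWHM", {
  psf <- psf_model(75, 150)
  v <- render_volume(matrix(c(600, 600, 300), 1), psf,
                     list(dims = c(60, 60, 30), voxel = c(20, 20, 20)),
                     noise = list())
  sp <- detect_spots(v, scale = 2 * sqrt(2 * log(2)) * 75)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$width_nm, 2 * sqrt(2 * log(2)) * 75, tolerance = 0.02)
})

test_that("TEM renderer produces measurable annuli with a truth table", {
  # single cage, no jitter: ellipse-fit width within one pixel of 28
  s1 <- nanocage_field_spec(1, 28, 0)
  r1 <- render_tem_nanocages(s1, dims = c(160, 160), pixel_size = 0.5,
                             seed = 1, ellipticity_sd = 0)
  m1 <- measure_tem_widths(r1$image, pixel_size = 0.5)
  expect_equal(nrow(m1), 1)
  expect_lt(abs(m1$width - 28), 1)
  # empty field
  r0 <- render_tem_nanocages(nanocage_field_spec(0), dims = c(64, 64))
  expect_equal(sum(r0$image), 0)
  expect_equal(nrow(r0$truth), 0)
  # population truth: sample mean within 3 SE of the population mean
  s138 <- nanocage_field_spec(138, 28.3, 1.6)
  r138 <- render_tem_nanocages(s138, dims = c(512, 512), pixel_size = 4,
                               seed = 99)
  se <- 1.6 / sqrt(138)
  expect_lt(abs(mean(r138$truth$diameter) - 28.3), 3 * se)
  expect_true(all(r138$truth$diameter > 0))
  # determinism
  r138b <- render_tem_nanocages(s138, dims = c(512, 512), pixel_size = 4,
                                seed = 99)
  expect_identical(r138$image, r138b$image)
})

test_that("PSF model enforces the FWHM relation", {
  p <- psf_model(75, 250)
  expect_equal(unname(psf_fwhm(p)), 2 * sqrt(2 * log(2)) * c(75, 250))
  expect_equal(fwhm_to_sigma(psf_fwhm(p)[["lateral"]]), 75)
  expect_error(psf_model(-1, 10), "sigma")
})
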