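test_that("TEM widths follow the (major + minor)/2 rule in both paths", {
  # manual ellipse table pass-through
  m <- measure_tem_widths(data.frame(major = c(30, 200), minor = c(26, 200)))
  expect_equal(m$width, c(28, 200))
  expect_error(measure_tem_widths(data.frame(major = 10, minor = -1)), "> 0")
  # batch rule equals the arithmetic oracle exactly
  set.seed(1)
  maj <- runif(50, 25, 35); mnr <- maj - runif(50, 0, 4)
  mb <- measure_tem_widths(data.frame(major = maj, minor = mnr))
  expect_equal(mb$width, (maj + mnr) / 2)
  # automatic path on a rendered circle of known diameter
  r1 <- render_tem_nanocages(nanocage_field_spec(1, 28, 0),
                             dims = c(160, 160), pixel_size = 0.5, seed = 2,
                             ellipticity_sd = 0)
  a1 <- measure_tem_widths(r1$image, pixel_size = 0.5)
  expect_lt(abs(a1$major - 28), 1)
  expect_lt(abs(a1$minor - 28), 1)
  # flat image: warning and empty result
  expect_warning(e <- measure_tem_widths(matrix(0, 32, 32)), "no components|flat")
  expect_equal(nrow(e), 0)
})

test_that("TEM estimator recovers a cage population mean within 3 SE", {
  spec <- nanocage_field_spec(60, 28.3, 1.6)
  r <- render_tem_nanocages(spec, dims = c(1900, 1900), pixel_size = 0.5,
                            seed = 12)
  m <- measure_tem_widths(r$image, pixel_size = 0.5)
  expect_gt(nrow(m), 45)
  se <- stats::sd(r$truth$diameter) / sqrt(nrow(m))
  expect_lt(abs(mean(m$width) - mean(r$truth$diameter)), 3 * se + 0.3)
})

test_that("spot detection fits point-source widths and separates pairs", {
  expect_equal(nrow(detect_spots(image_volume(array(0, c(24, 24, 8)),
                                              c(40, 40, 40)))), 0)
  psf <- psf_model(75, 160)
  fw <- 2 * sqrt(2 * log(2)) * 75
  v <- render_volume(matrix(c(610, 590, 300), 1), psf,
                     list(dims = c(60, 60, 30), voxel = c(20, 20, 20)),
                     noise = list())
  sp <- detect_spots(v, scale = fw)
  expect_equal(nrow(sp), 1)
  expect_true(sp$accepted)
  expect_equal(sp$width_nm, fw, tolerance = 0.02)
  expect_equal(c(sp$x, sp$y), c(610, 590), tolerance = 10)
  # two sources 5 FWHM apart resolve into two spots at the right centroids
  pts <- rbind(c(400, 600, 300), c(400 + 5 * fw, 600, 300))
  v2 <- render_volume(pts, psf, list(dims = c(90, 60, 30),
                                     voxel = c(20, 20, 20)), noise = list())
  sp2 <- detect_spots(v2, scale = fw)
  expect_equal(nrow(sp2), 2)
  got <- sp2[order(sp2$x), ]
  expect_lt(max(abs(got$x - pts[, 1])), 10)  # half a voxel
  expect_lt(max(abs(got$y - pts[, 2])), 10)
})

test_that("intrinsic EF is the mean accepted width over the reference", {
  s <- data.frame(width_nm = rep(28.3, 5), accepted = TRUE)
  expect_equal(intrinsic_ef(s, 28.3)$intrinsic_ef, 1)
  expect_equal(intrinsic_ef(data.frame(width_nm = c(283, 283)),
                            28.3)$intrinsic_ef, 10)
  # the two paper-scale means: 263.7 nm spots over a 28.3 nm standard
  set.seed(2)
  w <- rnorm(200, 0, 5)
  w <- w - mean(w) + 263.7   # exact sample mean
  ef <- intrinsic_ef(data.frame(width_nm = w), 28.3)
  expect_equal(ef$intrinsic_ef, 263.7 / 28.3, tolerance = 1e-12)
  expect_equal(ef$intrinsic_ef, 9.32, tolerance = 0.001)
  # ratio consistency: scaling widths by k scales the EF by k exactly
  efk <- intrinsic_ef(data.frame(width_nm = 3 * w), 28.3)
  expect_equal(efk$intrinsic_ef, 3 * ef$intrinsic_ef)
  # flagged spots are excluded but counted
  s2 <- data.frame(width_nm = c(100, 999), accepted = c(TRUE, FALSE))
  e2 <- intrinsic_ef(s2, 10)
  expect_equal(e2$intrinsic_ef, 10)
  expect_equal(e2$n_flagged, 1)
  expect_error(intrinsic_ef(data.frame(width_nm = 1, accepted = FALSE), 10),
               "zero accepted")
  expect_warning(intrinsic_ef(s, 28.3, psf_fwhm = 5), "quadrature")
})

test_that("macroscopic EF averages per-dimension expansion ratios", {
  expect_equal(macroscopic_ef(5, 47), 9.4)
  expect_equal(macroscopic_ef(c(3, 7, 11), c(3, 7, 11)), 1)
  expect_equal(macroscopic_ef(c(10, 10), c(40, 44)), 4.2)
  expect_error(macroscopic_ef(c(1, 2), 3), "length")
  expect_error(macroscopic_ef(-1, 3), "> 0")
})

test_that("scale calibration rescales voxels, keeps intensities, records provenance", {
  v <- image_volume(array(runif(8^3), c(8, 8, 8)), c(40, 40, 150))
  same <- calibrate_scale(v, 1)
  expect_equal(same$voxel, v$voxel)
  expect_identical(same$data, v$data)
  cal <- calibrate_scale(v, 10, source = "intrinsic")
  expect_equal(cal$voxel, c(4, 4, 15))
  expect_identical(cal$data, v$data)
  expect_equal(cal$meta$calibration[[1]]$source, "intrinsic")
  expect_equal(cal$meta$calibration[[1]]$ef, 10)
  # invertibility
  back <- calibrate_scale(cal, 1 / 10)
  expect_equal(back$voxel, v$voxel)
  # using the (smaller) intrinsic EF instead of the macroscopic one makes
  # any measured object larger by exactly ef_macro / ef_intrinsic
  obj_vox <- 12
  w_macro <- obj_vox * calibrate_scale(v, 9.4)$voxel[1]
  w_intr <- obj_vox * calibrate_scale(v, 8.9)$voxel[1]
  expect_equal(w_intr / w_macro, 9.4 / 8.9)
})

test_that("bead averaging yields the closed-form PSF FWHM", {
  psf <- psf_model(72.2, 267)
  mk_bead <- function(seed, off = c(0, 0, 0), noise = 2e-6) {
    ctr <- c(32, 32, 28) * c(15, 15, 60) / 2 + off
    render_volume(matrix(ctr, 1), psf,
                  list(dims = c(32, 32, 28), voxel = c(15, 15, 60)),
                  noise = list(sd = noise), seed = seed)
  }
  beads <- lapply(1:10, function(i) mk_bead(i, runif(3, -20, 20)))
  fw <- fwhm_from_beads(beads)
  expect_equal(unname(fw[1]), 2 * sqrt(2 * log(2)) * 72.2, tolerance = 0.03)
  expect_equal(unname(fw[2]), 2 * sqrt(2 * log(2)) * 267, tolerance = 0.03)
  expect_equal(attr(fw, "n_used"), 10)
  # averaging 10 noisy copies fits better than a single one
  fw1 <- fwhm_from_beads(beads[1])
  expect_lt(attr(fw, "fit_rms"), attr(fw1, "fit_rms"))
  # off-centre beads are rejected and counted
  far <- mk_bead(99, c(150, 150, 500))
  fw2 <- fwhm_from_beads(c(beads[1:3], list(far)))
  expect_equal(attr(fw2, "n_rejected"), 1)
  # a bead much larger than the PSF broadens the measurement (flagged)
  expect_false(is.na(attr(fw, "finite_bead")))
})

test_that("effective PSF scales inversely with the expansion factor", {
  expect_equal(effective_psf(170, 10), 17)
  expect_equal(effective_psf(650, 10), 65)
  expect_equal(effective_psf(123.4, 1), 123.4)
  expect_error(effective_psf(-1, 10), "> 0")
})

test_that("full nanocage chain recovers the rendered width ratio", {
  # >= 50 point-like cages rendered at the post-expansion spot width, then
  # detected and divided by the TEM reference
  true_fw <- 263.7
  psf <- psf_model(fwhm_to_sigma(true_fw), 2.2 * fwhm_to_sigma(true_fw))
  pts <- separated_points(55, 900, 9100, 3 * true_fw, seed = 6,
                          zlim = c(700, 1300))
  vol <- render_volume(pts, psf, list(dims = c(250, 250, 50),
                                      voxel = c(40, 40, 40)),
                       noise = list(gain = 3e5, sd = 1e-4), seed = 7)
  sp <- detect_spots(vol, scale = true_fw)
  expect_gte(sum(sp$accepted), 50)
  ef <- intrinsic_ef(sp, 28.3)
  expect_lt(abs(ef$intrinsic_ef - true_fw / 28.3), 3 * ef$sd)
})
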