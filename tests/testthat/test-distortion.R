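make_linear_field <- function(alpha, dims = c(48, 48, 48), voxel = 20,
                              centre = NULL) {
  ctr <- centre %||% (dims * voxel / 2)
  g <- exmkit:::grid_centers(list(dims = dims, voxel = rep(voxel, 3)))
  u <- sweep(g, 2, ctr) * alpha
  distortion_field(array(u[, 1], dims), array(u[, 2], dims),
                   array(u[, 3], dims), voxel = rep(voxel, 3))
}

test_that("pair-differential RMSE closes on zero and constant fields", {
  z <- array(0, c(32, 32, 32))
  fz <- distortion_field(z, z, z, voxel = c(20, 20, 20))
  cur <- rmse_vs_length_scale(fz, c(100, 200, 400), n_pairs = 200, seed = 1)
  expect_equal(cur$rmse_nm, rep(0, 3))
  # a uniform shift is registration residue, not distortion
  fc <- distortion_field(z + 35, z, z, voxel = c(20, 20, 20))
  cc <- rmse_vs_length_scale(fc, c(100, 200, 400), n_pairs = 200, seed = 1)
  expect_equal(cc$rmse_nm, rep(0, 3))
  # but the raw-magnitude variant sees it
  cm <- rmse_vs_length_scale(fc, c(100, 200), n_pairs = 200, seed = 1,
                             method = "magnitude")
  expect_equal(cm$rmse_nm, rep(35, 2))
})

test_that("linear radial field gives percent error equal to its slope", {
  fl <- make_linear_field(0.03)
  cur <- rmse_vs_length_scale(fl, c(100, 200, 400, 800), n_pairs = 400,
                              seed = 2)
  expect_true(all(cur$ok))
  expect_true(all(abs(cur$percent - 3) < 0.3))
  # linearity: scaling the field by k scales RMSE(L) by k
  f2 <- make_linear_field(0.06)
  c2 <- rmse_vs_length_scale(f2, c(100, 200, 400, 800), n_pairs = 400,
                             seed = 2)
  expect_equal(c2$rmse_nm / cur$rmse_nm, rep(2, 4), tolerance = 1e-9)
})

test_that("scales without enough valid pairs are flagged, not fabricated", {
  fl <- make_linear_field(0.03, dims = c(16, 16, 16))
  cur <- rmse_vs_length_scale(fl, c(100, 5000), n_pairs = 150, seed = 1)
  expect_true(cur$ok[1])
  expect_false(cur$ok[2])
  expect_true(is.na(cur$rmse_nm[2]))
  expect_error(rmse_vs_length_scale(fl, c(100, 200), n_pairs = 50), ">= 100")
  expect_error(rmse_vs_length_scale(fl, c(200, 100, 300), n_pairs = 200),
               "increasing")
})

test_that("radial component map projects onto the radial direction", {
  dims <- c(24, 24, 24); voxel <- 20
  ctr <- dims * voxel / 2
  z <- array(0, dims)
  fz <- distortion_field(z, z, z, voxel = rep(voxel, 3))
  expect_true(all(radial_component_map(fz, ctr) == 0))
  # purely tangential field: u = omega x r has zero radial component
  g <- exmkit:::grid_centers(list(dims = dims, voxel = rep(voxel, 3)))
  r <- sweep(g, 2, ctr)
  u <- cbind(-r[, 2], r[, 1], 0)
  ft <- distortion_field(array(u[, 1], dims), array(u[, 2], dims),
                         array(u[, 3], dims), voxel = rep(voxel, 3))
  expect_lt(max(abs(radial_component_map(ft, ctr))), 1e-9)
  expect_error(radial_component_map(fz, c(-100, 0, 0)), "inside")
})

test_that("dense 2D flow matches translations and a phase-correlation oracle", {
  set.seed(5)
  pts <- cbind(runif(40, 12, 84), runif(40, 12, 84))
  f <- blob_image(96, pts)
  expect_error(farneback_flow(f, matrix(1, 96, 96)), "zero variance")
  # self-flow is zero on the mask
  fl0 <- farneback_flow(f, f, pixel_size = c(1, 1))
  expect_lt(mean(sqrt(fl0$u1[fl0$mask]^2 + fl0$u2[fl0$mask]^2)), 0.05)
  # known translation, checked against a phase-correlation oracle
  m <- blob_image(96, sweep(pts, 2, c(3, 0), "+"))
  fl <- farneback_flow(f, m, pixel_size = c(1, 1))
  got <- c(mean(fl$u1[fl$mask]), mean(fl$u2[fl$mask]))
  xc <- Re(stats::fft(stats::fft(m) * Conj(stats::fft(f)), inverse = TRUE))
  pk <- as.vector(arrayInd(which.max(xc), dim(xc))) - 1L
  oracle <- ifelse(pk > 48, pk - 96, pk)  # unwrap circular shift
  expect_equal(oracle, c(3, 0))
  expect_lt(max(abs(got - oracle)), 0.2)
  # nm conversion follows the pixel pitch
  fl2 <- farneback_flow(f, m, pixel_size = c(15, 40))
  expect_equal(mean(fl2$u1[fl2$mask]), 45, tolerance = 0.2 * 15)
})

test_that("2D flow recovers a known radial contraction", {
  set.seed(6)
  pts <- cbind(runif(45, 12, 84), runif(45, 12, 84))
  f <- blob_image(96, pts)
  ctr <- c(48.5, 48.5)
  m <- blob_image(96, sweep(sweep(pts, 2, ctr), 1, 0.95, "*") +
                    rep(1, 45) %o% ctr)
  fl <- farneback_flow(f, m, pixel_size = c(1, 1))
  xi <- matrix(rep(1:96, 96), 96); yi <- t(xi)
  tx <- -0.05 * (xi - ctr[1]); ty <- -0.05 * (yi - ctr[2])
  k <- fl$mask
  cs <- sum(fl$u1[k] * tx[k] + fl$u2[k] * ty[k]) /
    sqrt(sum(fl$u1[k]^2 + fl$u2[k]^2) * sum(tx[k]^2 + ty[k]^2))
  mag <- sqrt(sum(fl$u1[k]^2 + fl$u2[k]^2) / sum(tx[k]^2 + ty[k]^2))
  expect_gt(cs, 0.9)
  expect_gt(mag, 0.8)
  expect_lt(mag, 1.2)
})

test_that("resectioned 3D flow closes on identical volumes and fuses x", {
  set.seed(7)
  pts <- cbind(runif(60, 150, 810), runif(60, 150, 810), runif(60, 150, 810))
  psf <- psf_model(45, 70)
  grid <- list(dims = c(48, 48, 48), voxel = c(20, 20, 20))
  pre <- render_volume(pts, psf, grid, noise = list())
  fld <- resection_flow_3d(pre, pre)
  mg <- field_magnitude(fld)
  expect_lt(max(mg[fld$mask]), 1e-6)
  # pure x-translation: both plane families measure dx, fused equals either
  post <- render_volume(sweep(pts, 2, c(30, 0, 0), "+"), psf, grid,
                        noise = list(), allow_clip = TRUE)
  fl2 <- resection_flow_3d(pre, post)
  expect_equal(median(fl2$ux[fl2$mask]), 30, tolerance = 3)
  expect_lt(abs(median(fl2$uy[fl2$mask])), 2)
  expect_lt(abs(median(fl2$uz[fl2$mask])), 2)
})

test_that("axial shear is recovered in the z component only", {
  set.seed(8)
  pts <- cbind(runif(60, 150, 810), runif(60, 150, 810), runif(60, 150, 810))
  psf <- psf_model(45, 70)
  grid <- list(dims = c(48, 48, 48), voxel = c(20, 20, 20))
  pre <- render_volume(pts, psf, grid, noise = list())
  post <- render_volume(cbind(pts[, 1], pts[, 2], pts[, 3] + 30), psf, grid,
                        noise = list(), allow_clip = TRUE)
  fld <- resection_flow_3d(pre, post)
  m <- fld$mask
  expect_equal(median(fld$uz[m]), 30, tolerance = 30 * 0.2)
  expect_lt(abs(median(fld$ux[m])), 3)
  expect_lt(abs(median(fld$uy[m])), 3)
})

test_that("a 90-degree rotation about x permutes the fused components", {
  set.seed(9)
  pts <- cbind(runif(40, 150, 810), runif(40, 150, 810), runif(40, 150, 810))
  psf <- psf_model(45, 45)
  grid <- list(dims = c(48, 48, 48), voxel = c(20, 20, 20))
  pre <- render_volume(pts, psf, grid, noise = list())
  post <- render_volume(sweep(pts, 2, c(20, 0, 10), "+"), psf, grid,
                        noise = list(), allow_clip = TRUE)
  fld <- resection_flow_3d(pre, post)
  rot <- function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1]  # y->z, z->-y
  pre_r <- image_volume(rot(pre$data), grid$voxel)
  post_r <- image_volume(rot(post$data), grid$voxel)
  fld_r <- resection_flow_3d(pre_r, post_r)
  m <- fld_r$mask & rot(fld$mask)
  expect_equal(fld_r$ux[m], rot(fld$ux)[m], tolerance = 1e-4)
  expect_equal(fld_r$uy[m], rot(fld$uz)[m], tolerance = 1e-4)
  expect_equal(fld_r$uz[m], -rot(fld$uy)[m], tolerance = 1e-4)
})
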