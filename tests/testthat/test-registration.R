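test_that("affine utilities satisfy the similarity algebra", {
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t1 <- affine_similarity(2.5, R, c(10, -20, 5))
  d <- affine_decompose(t1)
  expect_equal(d$scale, 2.5)
  expect_lt(d$orthonormality, 1e-12)
  # inverse and composition
  rt <- affine_compose(affine_invert(t1), t1)
  expect_equal(rt$m, diag(4), tolerance = 1e-12)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(affine_apply(affine_invert(t1), affine_apply(t1, p)), p,
               tolerance = 1e-9)
  expect_error(affine3d(matrix(0, 4, 4)), "row|invert")
})

test_that("closed-form similarity fit recovers a known transform exactly", {
  set.seed(1)
  X <- matrix(runif(60, -100, 100), 20, 3)
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  Y <- sweep(3.2 * X %*% t(R), 2, c(5, 6, 7), "+")
  fit <- exmkit:::fit_similarity(X, Y)
  d <- affine_decompose(fit)
  expect_equal(d$scale, 3.2, tolerance = 1e-9)
  expect_equal(d$rotation, R, tolerance = 1e-9)
  expect_equal(d$translation, c(5, 6, 7), tolerance = 1e-6)
})

test_that("identical volumes register to the identity", {
  pair <- registration_pair(1, c(0, 0, 0), pre_dims = 48, pre_voxel = 40,
                            post_dims = 48, post_voxel = 40, n_points = 50)
  res <- estimate_transform(pair$pre, pair$pre, init_scale = 1,
                            cfg = block_match_config(block = 16, stride = 8,
                                                     search = 4))
  d <- affine_decompose(res$transform)
  expect_equal(d$scale, 1, tolerance = 0.002)
  expect_lt(max(abs(d$translation)), 10)
  expect_lt(res$diagnostics$final_residual_nm, 5)
})

test_that("a scaled and translated render is recovered within 1 percent", {
  pair <- registration_pair(2, c(300, 200, 100), pre_dims = 48,
                            pre_voxel = 40, post_dims = 56, post_voxel = 80,
                            n_points = 60, seed = 21)
  res <- estimate_transform(pair$pre, pair$post, init_scale = 1.9,
                            cfg = block_match_config(block = 16, stride = 8,
                                                     search = 6))
  d <- affine_decompose(res$transform)
  expect_lt(abs(d$scale / 2 - 1), 0.01)
  expect_lt(max(abs(d$translation - c(300, 200, 100))), 40)  # half post voxel
  expect_lt(d$orthonormality, 1e-6)
  # block residual RMS is non-increasing across recorded iterations
  expect_true(all(diff(res$diagnostics$residual_nm) <= 1e-9))
})

test_that("forward and reverse estimates compose to the identity", {
  pair <- registration_pair(2, c(200, 150, 120), pre_dims = 48,
                            pre_voxel = 40, post_dims = 56, post_voxel = 80,
                            n_points = 60, seed = 31)
  cfg <- block_match_config(block = 16, stride = 8, search = 6)
  ab <- estimate_transform(pair$pre, pair$post, init_scale = 2, cfg = cfg)
  ba <- estimate_transform(pair$post, pair$pre, init_scale = 0.5, cfg = cfg)
  comp <- affine_compose(ba$transform, ab$transform)
  d <- affine_decompose(comp)
  expect_equal(d$scale, 1, tolerance = 0.01)
  expect_lt(max(abs(d$translation)), 50)
})

test_that("estimation matches an exhaustive search oracle on a small fixture", {
  # <= 32^3 volumes: brute-force the global NCC over (scale, translation)
  pair <- registration_pair(1.25, c(80, -40, 40), pre_dims = 32,
                            pre_voxel = 40, post_dims = 32, post_voxel = 50,
                            n_points = 40, seed = 41, sigma = c(80, 80))
  cfg <- block_match_config(block = 12, stride = 6, search = 5)
  res <- estimate_transform(pair$pre, pair$post, init_scale = 1.2, cfg = cfg)
  d <- affine_decompose(res$transform)
  scales <- seq(1.15, 1.35, by = 0.025)
  shifts <- seq(-100, 100, by = 25)
  best <- c(-Inf, NA, NA, NA, NA)
  post <- pair$post
  for (s in scales) for (tx in shifts) for (ty in shifts) for (tz in shifts) {
    tr <- affine_similarity(s, diag(3), c(tx, ty, tz))
    mv <- resample_to_reference(pair$pre, tr, post)
    cc <- suppressWarnings(stats::cor(as.vector(mv$data),
                                      as.vector(post$data)))
    if (is.finite(cc) && cc > best[1]) best <- c(cc, s, tx, ty, tz)
  }
  expect_lt(abs(d$scale - best[2]), 0.025)        # scale-grid resolution
  expect_lt(max(abs(d$translation - best[3:5])), 25)  # shift-grid resolution
})

test_that("degenerate input fails with a clear message", {
  flat <- image_volume(array(1, c(32, 32, 32)), c(40, 40, 40))
  expect_error(estimate_transform(flat, flat, init_scale = 1,
                                  cfg = block_match_config(block = 16,
                                                           stride = 8,
                                                           search = 4)),
               "similarity transform")
  expect_error(block_match_config(block = 4), ">= 8")
  expect_error(block_match_config(min_correlation = 1.5), "0, 1")
})

test_that("resampling preserves content through exact transforms", {
  set.seed(2)
  arr <- array(runif(24^3), c(24, 24, 24))
  vol <- image_volume(arr, c(20, 20, 20))
  idt <- affine_similarity(1)
  expect_equal(resample_to_reference(vol, idt, vol)$data, arr,
               tolerance = 1e-12)
  # integer-voxel translation shifts content exactly
  tr <- affine_similarity(1, diag(3), c(40, 0, -20))  # +2 vox x, -1 vox z
  shifted <- resample_to_reference(vol, tr, vol)
  expect_equal(shifted$data[3:24, , 1:23], arr[1:22, , 2:24],
               tolerance = 1e-12)
  expect_true(all(shifted$meta$valid[3:24, , 1:23]))
  # scale x2 then x0.5 roundtrip on a PSF-band-limited render:
  # interior RMS change below 2 percent
  set.seed(3)
  pts <- cbind(runif(20, 60, 420), runif(20, 60, 420), runif(20, 60, 420))
  volsm <- render_volume(pts, psf_model(60, 60),
                         list(dims = c(24, 24, 24), voxel = c(20, 20, 20)),
                         noise = list())
  up <- resample_to_reference(volsm, affine_similarity(2),
                              list(dims = c(48, 48, 48),
                                   voxel = c(20, 20, 20)))
  down <- resample_to_reference(up, affine_similarity(0.5),
                                list(dims = c(24, 24, 24),
                                     voxel = c(20, 20, 20)))
  core <- 5:20
  rel <- sqrt(mean((down$data[core, core, core] -
                      volsm$data[core, core, core])^2)) /
    sqrt(mean(volsm$data[core, core, core]^2))
  expect_lt(rel, 0.02)
})
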