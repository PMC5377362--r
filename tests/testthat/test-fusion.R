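test_that("confidence weights decay monotonically from one", {
  expect_equal(cwa_weight(0, 2), 1)
  expect_equal(cwa_weight(3, 3), exp(-1))
  set.seed(51)
  r <- sort(runif(100, 0, 10))
  w <- cwa_weight(r, 1.7)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(cwa_weight(1, 0), "sigma_sq")
})

test_that("adaptive sigma is the minimum residual plus epsilon", {
  expect_equal(adaptive_sigma_sq(c(4, 9, 1), 0.01), 1.01)
  expect_equal(adaptive_sigma_sq(c(0, 0, 0), 1e-6), 1e-6)
  r <- 2.5
  expect_equal(adaptive_sigma_sq(r, 0.3), r + 0.3)
  # a lone patch always ends with normalized weight exactly 1
  w <- cwa_weight(r, adaptive_sigma_sq(r, 0.3))
  expect_equal(w / w, 1)
  expect_error(adaptive_sigma_sq(numeric(0), 1), "no coverage")
  expect_error(adaptive_sigma_sq(1, 0), "epsilon")
})

# small pipeline fixture shared by the fusion tests
fusion_fixture <- function(seed = 61L, grid = 24L, n_atoms = 64L) {
  ph <- tiny_phantom(grid = grid, seed = seed, blur = 1, noise = 0.05)
  roi <- roi_from_mask(ph$label, margin = 5L)
  norm <- normalize_intensity(ph$mr, mask_from_roi(roi, dim(ph$mr)))
  df <- signed_distance_transform(ph$label)
  pairs <- sample_patch_pairs(norm, df, roi, 5L, stride = 2L)
  dict <- build_dictionary(pairs, n_atoms, seed = 1L)
  list(ph = ph, roi = roi, norm = norm, dict = dict)
}

test_that("a non-overlapping tiling copies each patch prediction verbatim", {
  f <- fusion_fixture()
  seg <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                        fusion_params(5L, stride = 5L)) # stride = patch edge
  # recompute one patch independently and compare the copied block
  u <- 3L
  ctr <- seg$centers[u, ]
  x <- as.vector(f$norm$data[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
                             (ctr[3] - 2):(ctr[3] + 2)])
  pred <- predict_df_patch(llc_code(x, f$dict, coding_params(k = 8L)), f$dict)
  # voxels covered once take the prediction unchanged
  got <- seg$df$data[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
                     (ctr[3] - 2):(ctr[3] + 2)]
  cov <- seg$coverage[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
                      (ctr[3] - 2):(ctr[3] + 2)]
  expect_equal(got[cov == 1L], array(pred, dim = c(5, 5, 5))[cov == 1L],
               tolerance = 1e-12)
})

test_that("fused DF is a convex combination of its contributors and covers the roi", {
  f <- fusion_fixture()
  for (mode in c("cwa", "average")) {
    seg <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                          fusion_params(5L, stride = 2L, mode = mode))
    inroi <- array(FALSE, dim = dim(f$norm$data))
    inroi[f$roi$lower[1]:f$roi$upper[1], f$roi$lower[2]:f$roi$upper[2],
          f$roi$lower[3]:f$roi$upper[3]] <- TRUE
    expect_true(all(seg$coverage[inroi] >= 1L)) # stride <= patch edge covers all
    expect_true(all(seg$coverage[!inroi] == 0L))
    # independent recomputation of every contributing patch prediction:
    # the fused value must lie between the per-voxel contributor extremes
    lo <- array(Inf, dim = dim(f$norm$data))
    hi <- array(-Inf, dim = dim(f$norm$data))
    for (u in seq_len(nrow(seg$centers))) {
      ctr <- seg$centers[u, ]
      ix <- (ctr[1] - 2):(ctr[1] + 2); iy <- (ctr[2] - 2):(ctr[2] + 2)
      iz <- (ctr[3] - 2):(ctr[3] + 2)
      x <- as.vector(f$norm$data[ix, iy, iz])
      pred <- array(predict_df_patch(llc_code(x, f$dict, coding_params(k = 8L)),
                                     f$dict), dim = c(5, 5, 5))
      lo[ix, iy, iz] <- pmin(lo[ix, iy, iz], pred)
      hi[ix, iy, iz] <- pmax(hi[ix, iy, iz], pred)
    }
    cov <- seg$coverage > 0
    expect_true(all(seg$df$data[cov] >= lo[cov] - 1e-9))
    expect_true(all(seg$df$data[cov] <= hi[cov] + 1e-9))
  }
})

test_that("with identical residuals CWA collapses to the plain average", {
  # constant test volume inside the roi: every patch is identical, so all
  # residuals coincide and the confidence weights cancel in the ratio
  f <- fusion_fixture()
  const <- f$norm
  const$data[] <- 0.37
  cwa <- segment_volume(const, f$roi, f$dict, coding_params(k = 8L),
                        fusion_params(5L, stride = 2L, mode = "cwa"))
  avg <- segment_volume(const, f$roi, f$dict, coding_params(k = 8L),
                        fusion_params(5L, stride = 2L, mode = "average"))
  expect_equal(sd(cwa$residuals), 0)
  expect_lt(max(abs(cwa$df$data - avg$df$data)), 1e-10)
})

test_that("CWA approaches the plain average as sigma grows without bound", {
  f <- fusion_fixture()
  big <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                        fusion_params(5L, stride = 2L, mode = "cwa", sigma_sq = 1e12))
  avg <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                        fusion_params(5L, stride = 2L, mode = "average"))
  expect_lt(max(abs(big$df$data - avg$df$data)), 1e-6)
})

test_that("segmentation is deterministic and validates its configuration", {
  f <- fusion_fixture()
  s1 <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                       fusion_params(5L, stride = 2L))
  s2 <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                       fusion_params(5L, stride = 2L))
  expect_identical(s1$df$data, s2$df$data)
  expect_identical(s1$label$data, s2$label$data)
  expect_error(segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                              fusion_params(7L, stride = 2L)),
               "patch_edge")
  expect_error(fusion_params(5L, stride = 6L), "stride")
  expect_error(fusion_params(4L), "odd")
})

test_that("out-of-roi voxels are background and the label tracks the DF sign", {
  f <- fusion_fixture()
  seg <- segment_volume(f$norm, f$roi, f$dict, coding_params(k = 8L),
                        fusion_params(5L, stride = 2L))
  expect_true(all(seg$label$data[seg$coverage == 0L] == 0))
  expect_equal(seg$label$data, array(as.numeric(seg$df$data > 0), dim = dim(seg$df$data)))
})
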