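test_that("LLC reproduces exact and symmetric geometries", {
  set.seed(41)
  A <- matrix(rnorm(10 * 27), 10, 27)
  dict <- manual_dictionary(A)
  # self-representation
  code <- llc_code(A[4, ], dict, coding_params(k = 1L))
  expect_equal(code$neighbor_indices, 4L)
  expect_equal(code$weights, 1)
  expect_equal(code$residual, 0)
  # midpoint of two equidistant atoms, ridge 0
  two <- manual_dictionary(rbind(rep(0, 27), rep(2, 27)))
  mid <- rep(1, 27)
  code <- llc_code(mid, two, coding_params(k = 2L, ridge = 0))
  expect_equal(code$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(code$residual, 0, tolerance = 1e-10)
})

test_that("LLC weights agree with an equality-constrained QP oracle", {
  set.seed(42)
  for (rep in 1:10) {
    A <- matrix(rnorm(20 * 27), 20, 27)
    dict <- manual_dictionary(A)
    x <- rnorm(27)
    code <- llc_code(x, dict, coding_params(k = 6L, ridge = 1e-4))
    w_star <- llc_kkt_oracle(x, A[code$neighbor_indices, ], 1e-4)
    expect_lt(max(abs(code$weights - w_star)), 1e-6)
    expect_lt(abs(sum(code$weights) - 1), 1e-8)
    # stored residual is recomputable from the stored fields
    recon <- as.numeric(crossprod(A[code$neighbor_indices, ], code$weights))
    expect_lt(abs(code$residual - sqrt(sum((x - recon)^2))), 1e-8)
  }
})

test_that("LLC is translation covariant at ridge 0 and may go negative", {
  set.seed(43)
  A <- matrix(rnorm(12 * 27), 12, 27)
  x <- rnorm(27)
  cc <- rnorm(1)
  p0 <- coding_params(k = 5L, ridge = 0)
  w1 <- llc_code(x, manual_dictionary(A), p0)$weights
  w2 <- llc_code(x + cc, manual_dictionary(A + cc), p0)$weights
  expect_equal(w1, w2, tolerance = 1e-6)
  # negativity occurs (x outside local hull); run several draws
  any_negative <- FALSE
  for (s in 1:5) {
    x2 <- rnorm(27, sd = 3)
    any_negative <- any_negative ||
      any(llc_code(x2, manual_dictionary(A), p0)$weights < 0)
  }
  expect_true(any_negative)
})

test_that("LAE finds vertex and hull-boundary optima on the simplex", {
  A <- matrix(rnorm(8 * 27), 8, 27)
  dict <- manual_dictionary(A)
  code <- lae_code(A[3, ], dict, coding_params(k = 4L, method = "lae"))
  expect_equal(code$weights[code$neighbor_indices == 3L], 1, tolerance = 1e-8)
  expect_equal(code$residual, 0, tolerance = 1e-8)
  # x beyond the nearer of two collinear atoms: all weight on that atom
  two <- manual_dictionary(rbind(rep(1, 27), rep(2, 27)))
  out <- lae_code(rep(0, 27), two, coding_params(k = 2L, method = "lae"))
  expect_equal(out$weights, c(1, 0), tolerance = 1e-6)
})

test_that("LAE respects the simplex and matches a grid-search oracle at k = 3", {
  set.seed(44)
  for (rep in 1:5) {
    A <- matrix(rnorm(6 * 12), 6, 12)
    dict <- manual_dictionary(A, patch_edge = 3L)
    x <- rnorm(12)
    code <- lae_code(x, dict, coding_params(k = 3L, method = "lae"))
    expect_true(all(code$weights >= -1e-8))
    expect_lt(abs(sum(code$weights) - 1), 1e-8)
    obj <- lae_objective(x, A[code$neighbor_indices, ], code$weights)
    expect_lte(obj, lae_grid_oracle(x, A[code$neighbor_indices, ]) + 1e-6)
  }
})

test_that("LAE residual is never below LLC residual on the same neighbors", {
  set.seed(45)
  for (rep in 1:8) {
    A <- matrix(rnorm(15 * 27), 15, 27)
    dict <- manual_dictionary(A)
    x <- rnorm(27)
    # ridge-free LLC: the exact equality-constrained optimum, so the
    # simplex-constrained optimum can never beat it
    r_llc <- llc_code(x, dict, coding_params(k = 5L, ridge = 0))$residual
    r_lae <- lae_code(x, dict, coding_params(k = 5L, method = "lae"))$residual
    expect_gte(r_lae, r_llc - 1e-7)
  }
})

test_that("coefficient transfer to DF atoms is exact and linear", {
  set.seed(46)
  Amr <- matrix(rnorm(9 * 27), 9, 27)
  Adf <- matrix(rnorm(9 * 27), 9, 27)
  dict <- manual_dictionary(Amr, Adf)
  c1 <- llc_code(Amr[5, ], dict, coding_params(k = 1L))
  expect_equal(predict_df_patch(c1, dict), Adf[5, ])

  fake <- structure(list(neighbor_indices = c(2L, 7L), weights = c(0.5, 0.5),
                         residual = 0, method = "llc"), class = "coding_result")
  expect_equal(predict_df_patch(fake, dict), colMeans(Adf[c(2, 7), ]))

  w <- rnorm(4); w <- w / sum(w)
  idx <- c(1L, 3L, 8L, 9L)
  g <- structure(list(neighbor_indices = idx, weights = w, residual = 0,
                      method = "llc"), class = "coding_result")
  manual <- vapply(seq_len(27), function(j) sum(w * Adf[idx, j]), 0)
  expect_equal(predict_df_patch(g, dict), manual, tolerance = 1e-12)

  # linearity: predict(a w1 + (1-a) w2) = a predict(w1) + (1-a) predict(w2)
  w2 <- rnorm(4); w2 <- w2 / sum(w2)
  a <- 0.3
  mix <- g; mix$weights <- a * w + (1 - a) * w2
  g2 <- g; g2$weights <- w2
  expect_equal(predict_df_patch(mix, dict),
               a * predict_df_patch(g, dict) + (1 - a) * predict_df_patch(g2, dict),
               tolerance = 1e-12)

  bad <- g; bad$neighbor_indices <- c(1L, 3L, 8L, 99L)
  expect_error(predict_df_patch(bad, dict), "out of range")
})

test_that("both coders return sum-to-one weights across random instances", {
  set.seed(47)
  for (rep in 1:10) {
    A <- matrix(rnorm(20 * 8), 20, 8)
    dict <- manual_dictionary(A, patch_edge = 3L)
    x <- rnorm(8)
    expect_lt(abs(sum(llc_code(x, dict, coding_params(k = 7L))$weights) - 1), 1e-8)
    expect_lt(abs(sum(lae_code(x, dict, coding_params(k = 7L, method = "lae"))$weights) - 1), 1e-8)
  }
})
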