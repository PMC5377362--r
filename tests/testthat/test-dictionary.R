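test_that("patch sampling enumerates the stride grid of valid centers", {
  set.seed(9)
  v <- volume(array(rnorm(9^3), dim = c(9, 9, 9)))
  df <- volume(array(rnorm(9^3), dim = c(9, 9, 9)), label = FALSE)
  roi <- roi_box(c(1, 1, 1), c(9, 9, 9))
  expect_equal(nrow(sample_patch_pairs(v, df, roi, 3L, stride = 1L)$mr), 343L)
  expect_equal(nrow(sample_patch_pairs(v, df, roi, 3L, stride = 3L)$mr), 27L)
  # each mr vector reshapes to the sub-block at its center
  pp <- sample_patch_pairs(v, df, roi, 3L, stride = 1L)
  set.seed(10)
  for (i in sample(nrow(pp$mr), 5L)) {
    c3 <- pp$centers[i, ]
    blk <- v$data[(c3[1] - 1):(c3[1] + 1), (c3[2] - 1):(c3[2] + 1), (c3[3] - 1):(c3[3] + 1)]
    expect_identical(pp$mr[i, ], as.vector(blk))
    blk_df <- df$data[(c3[1] - 1):(c3[1] + 1), (c3[2] - 1):(c3[2] + 1), (c3[3] - 1):(c3[3] + 1)]
    expect_identical(pp$df[i, ], as.vector(blk_df))
  }
  expect_error(sample_patch_pairs(v, df, roi_box(c(1, 1, 1), c(2, 2, 2)), 5L),
               "too small")
})

test_that("degenerate dictionaries reproduce their training pairs", {
  one <- random_pairs(5L, seed = 21L)
  one$mr <- one$mr[rep(1L, 5L), ]
  one$df <- one$df[rep(1L, 5L), ]
  d1 <- build_dictionary(one, 1L, seed = 0L)
  expect_equal(d1$mr_atoms[1, ], one$mr[1, ])
  expect_equal(d1$df_atoms[1, ], one$df[1, ])

  # n_atoms = n distinct well-separated pairs: every atom equals one pair
  sep <- random_pairs(6L, seed = 22L)
  sep$mr <- sep$mr + 50 * matrix(rep(1:6, 27L), 6L, 27L)
  dd <- build_dictionary(sep, 6L, seed = 0L)
  reorder <- apply(dd$mr_atoms, 1L, function(a) which.min(colSums((t(sep$mr) - a)^2)))
  expect_equal(sort(reorder), 1:6)
  expect_equal(dd$mr_atoms, sep$mr[reorder, ], tolerance = 1e-12)
  expect_equal(dd$df_atoms, sep$df[reorder, ], tolerance = 1e-12)
})

test_that("k-means output is a Lloyd fixed point with conserved membership", {
  pairs <- random_pairs(200L, seed = 23L)
  dict <- build_dictionary(pairs, 8L, seed = 5L)
  sizes <- dict$meta$cluster_sizes
  expect_equal(sum(sizes), 200L) # multiset union of clusters = training set
  expect_equal(tabulate(dict$assignment, 8L), sizes)
  # exhaustive independent re-assignment: own center is the nearest
  D <- outer(rowSums(pairs$mr^2), rep(1, 8L)) +
    outer(rep(1, 200L), rowSums(dict$mr_atoms^2)) -
    2 * pairs$mr %*% t(dict$mr_atoms)
  expect_equal(apply(D, 1L, which.min), dict$assignment)
  # each center is the mean of its members, DF atoms likewise
  for (j in 1:8) {
    mem <- dict$assignment == j
    expect_equal(dict$mr_atoms[j, ], colMeans(pairs$mr[mem, , drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(dict$df_atoms[j, ], colMeans(pairs$df[mem, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("dictionary construction is reproducible and beats random grouping", {
  pairs <- random_pairs(150L, seed = 24L)
  d1 <- build_dictionary(pairs, 10L, seed = 9L)
  d2 <- build_dictionary(pairs, 10L, seed = 9L)
  expect_identical(d1$mr_atoms, d2$mr_atoms)
  expect_identical(d1$df_atoms, d2$df_atoms)

  set.seed(31)
  inertia_random <- replicate(5, {
    a <- sample(1:10, 150L, replace = TRUE)
    ctr <- rowsum(pairs$mr, a) / as.integer(table(factor(a, 1:10)))[sort(unique(a))]
    sum((pairs$mr - ctr[match(a, sort(unique(a))), ])^2)
  })
  expect_lt(d1$meta$inertia, min(inertia_random))
  expect_error(build_dictionary(pairs, 151L, seed = 0L), "exceeds")
})

test_that("the converged dictionary is a fixed point of stats::kmeans too", {
  # independent cross-check: Lloyd iteration as implemented by stats::kmeans,
  # started at our converged centers, must leave them unchanged
  pairs <- random_pairs(120L, d = 8L, seed = 25L)
  dict <- build_dictionary(pairs, 6L, seed = 3L)
  km <- suppressWarnings(stats::kmeans(pairs$mr, centers = dict$mr_atoms,
                                       algorithm = "Lloyd", iter.max = 10L))
  expect_equal(unname(km$centers), dict$mr_atoms, tolerance = 1e-10)
  expect_equal(km$tot.withinss, dict$meta$inertia, tolerance = 1e-10)
  expect_equal(unname(km$cluster), dict$assignment)
})

test_that("knn_query matches a brute-force sort with index tie-breaking", {
  set.seed(26)
  A <- matrix(rnorm(50 * 27), 50, 27)
  dict <- manual_dictionary(A)
  x <- rnorm(27)
  d <- sqrt(colSums((t(A) - x)^2))
  expect_equal(knn_query(dict, x, 5L), order(d)[1:5])
  expect_equal(knn_query(dict, x, 50L), order(d))
  expect_equal(knn_query(dict, A[17, ], 1L), 17L)
  # exact ties break toward the lower atom index
  dup <- manual_dictionary(A[c(1, 1, 2, 2), ])
  expect_equal(knn_query(dup, A[2, ], 2L), c(3L, 4L))
  expect_error(knn_query(dict, rnorm(5), 1L), "length")
})

test_that("dictionaries survive serialization", {
  pairs <- random_pairs(40L, seed = 27L)
  dict <- build_dictionary(pairs, 4L, seed = 1L)
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  write_dictionary(dict, tf)
  back <- read_dictionary(tf)
  expect_identical(back$mr_atoms, dict$mr_atoms)
  expect_identical(back$meta$seed, dict$meta$seed)
  expect_error(read_dictionary(tempfile()), "no such")
})
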