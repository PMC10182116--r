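# Semi-automated segmentation workflow: clustering, border densification,
# centroids, breast isolation and fibroglandular segmentation.

test_that("tissue clustering reproduces the threshold oracle on separated modes", {
  d <- c(10, 10, 10)
  fat <- array(0, d); wat <- array(0, d)
  idx <- seq_len(prod(d))
  third <- split(idx, cut(idx, 3, labels = FALSE))
  fat[third[[2]]] <- 10; wat[third[[2]]] <- 1    # fat-dominant region
  fat[third[[3]]] <- 1;  wat[third[[3]]] <- 10   # water-dominant region
  labs <- cluster_tissues(fat, wat, seed = 1)
  oracle <- array(0L, d)
  oracle[third[[2]]] <- 2L
  oracle[third[[3]]] <- 1L
  expect_identical(as.vector(labs), as.vector(oracle))
  # the relabelling makes the output invariant to the k-means seed
  for (s in c(2, 99, 1234)) {
    expect_identical(cluster_tissues(fat, wat, seed = s), labs)
  }
  expect_error(cluster_tissues(array(0, d), array(0, d)), "degenerate")
  expect_error(cluster_tissues(array(1, d), array(1, d)), "degenerate")
})

test_that("border densification fills un-drawn slices and dilates", {
  d <- c(8, 10, 6)
  m <- array(FALSE, d)
  m[c(1, 3, 5, 7), 5, ] <- TRUE              # drawn on every second slice
  delin <- border_delineation(m)
  expect_equal(delin$drawn_slices, c(1, 3, 5, 7))
  b <- densify_border(delin, dilation_radius_voxels = 0)
  # nearest-slice copy reaches all intervening slices
  expect_true(all(apply(b$sheet[1:7, , ], 1, any)))
  expect_identical(b$sheet, b$dilated)
  # radius 0 with all slices drawn is the identity
  m2 <- array(FALSE, d); m2[, 4, ] <- TRUE
  b2 <- densify_border(border_delineation(m2), 0)
  expect_identical(b2$sheet, m2)
  # dilation grows the sheet
  b3 <- densify_border(delin, 2)
  expect_true(all(b3$dilated[b3$sheet]))
  expect_gt(sum(b3$dilated), sum(b3$sheet))
  expect_error(densify_border(border_delineation(array(FALSE, d),
                                                 drawn_slices = 1)), "empty")
})

test_that("densified border stays close to the true interface surface", {
  ph <- make_phantom(small_phantom_spec(seed = 5))
  delin <- make_delineation(ph$truth, every_k_slices = 2, jitter_voxels = 1,
                            seed = 6)
  b <- densify_border(delin, 2)
  h <- breastpdff:::hausdorff_voxels(breastpdff:::mask_coords(b$sheet),
                                     breastpdff:::mask_coords(ph$truth$interface))
  expect_lte(h, 2 + sqrt(2))   # nearest-slice copy (<=1 in FH) + jitter
})

test_that("breast centroids are symmetric and land inside the breasts", {
  ph <- make_phantom(small_phantom_spec(seed = 8))
  delin <- make_delineation(ph$truth, 2, 0, seed = 1)
  cen <- breast_centroids(delin, anterior_offset_voxels = 6)
  d <- dim(ph$truth$labels)
  # mirror symmetry about the RL midline within a voxel
  expect_equal(cen$left[["FH"]], cen$right[["FH"]], tolerance = 1)
  expect_equal(cen$left[["RL"]] - 1, d[3] - cen$right[["RL"]], tolerance = 1)
  inside <- function(cc, mask) {
    mask[matrix(round(unname(cc)), 1)]
  }
  expect_true(inside(cen$left, ph$truth$breast_left))
  expect_true(inside(cen$right, ph$truth$breast_right))
  # single border voxel per side: centroid reproduces its FH/RL coordinates
  m <- array(FALSE, c(8, 8, 8)); m[3, 6, 2] <- TRUE; m[5, 6, 7] <- TRUE
  cen1 <- breast_centroids(border_delineation(m), anterior_offset_voxels = 2)
  expect_equal(unname(cen1$left[c(1, 3)]), c(3, 2))
  expect_equal(unname(cen1$right[c(1, 3)]), c(5, 7))
  # one-sided delineation errors with the side named
  m[5, 6, 7] <- FALSE
  expect_error(breast_centroids(border_delineation(m)), "right")
})

test_that("breast isolation separates thorax and validates centroids", {
  # synthetic foreground: two blobs anterior of a full slab, cut by a
  # coronal-plane border behind both breasts
  d <- c(10, 12, 10)
  labs <- array(0L, d)
  labs[, 9:12, ] <- 1L                        # thorax slab
  labs[3:8, 2:7, 2:4] <- 2L                   # left blob
  labs[3:8, 2:7, 7:9] <- 2L                   # right blob
  border <- array(FALSE, d); border[, 8, ] <- TRUE
  cents <- list(left = c(5, 4, 3), right = c(5, 4, 8))
  iso <- isolate_breasts(labs, border, cents)
  expect_equal(sum(iso$left_breast), sum(labs[, , 1:5] == 2L))
  expect_false(any(iso$left_breast[, 9:12, ]))
  expect_false(any(iso$right_breast[, 9:12, ]))
  expect_false(any(iso$left_breast & iso$right_breast))
  # centroid in air errors
  expect_error(isolate_breasts(labs, border, list(left = c(1, 1, 1),
                                                  right = c(5, 4, 8))),
               "background")
  # a border that does not separate leaves both centroids in one component
  no_border <- array(FALSE, d)
  labs2 <- labs; labs2[, 8, ] <- 1L           # connect everything
  expect_error(isolate_breasts(labs2, no_border, cents), "does not separate")
})

test_that("isolated breasts match the phantom ground truth", {
  res <- process_subject(small_phantom_spec(seed = 12), anterior_offset = 6)
  tr <- res$phantom$truth
  expect_gte(dice_coefficient(res$seg$left_breast, tr$breast_left), 0.95)
  expect_gte(dice_coefficient(res$seg$right_breast, tr$breast_right), 0.95)
  expect_gte(dice_coefficient(res$fgt_left, tr$fgt_left), 0.90)
})

test_that("fibroglandular segmentation applies the strict cutoff", {
  d <- c(2, 2, 1)
  breast <- array(TRUE, d)
  labs <- array(c(1L, 1L, 1L, 2L), d)        # last voxel fat-dominant
  pdff <- array(c(5, 15, 25, 90), d)
  fgt <- segment_fibroglandular(breast, labs, pdff, 20)
  expect_identical(as.vector(fgt), c(TRUE, TRUE, FALSE, FALSE))
  # boundary voxels exactly at the cutoff are excluded
  pdff[2] <- 20
  fgt2 <- segment_fibroglandular(breast, labs, pdff, 20)
  expect_identical(as.vector(fgt2), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(segment_fibroglandular(breast, labs, pdff, 0), "cutoff")
  expect_error(segment_fibroglandular(breast, labs, pdff, 100), "cutoff")
  expect_warning(segment_fibroglandular(breast, labs, array(50, d), 20),
                 "empty")
})

test_that("raising the cutoff never shrinks the fibroglandular mask", {
  res <- process_subject(small_phantom_spec(seed = 14, snr = 40),
                         anterior_offset = 6)
  prev <- 0
  for (cut in c(10, 20, 35, 60)) {
    fgt <- suppressWarnings(
      segment_fibroglandular(res$seg$left_breast, res$tissue_labels,
                             res$maps$pdff_percent, cut))
    expect_gte(sum(fgt), prev)
    prev <- sum(fgt)
  }
})

test_that("an almost entirely fatty breast has a small fibroglandular fraction", {
  res <- process_subject(small_phantom_spec(seed = 15,
                                            fgt_volume_fraction = 0.04),
                         anterior_offset = 6)
  frac <- sum(res$fgt_left) / sum(res$seg$left_breast)
  expect_lt(frac, 0.10)
})

test_that("breast summaries are means over usable voxels", {
  d <- c(2, 1, 1)
  breast <- array(TRUE, d); fgt <- array(FALSE, d)
  pdff <- array(c(10, 30), d); t2 <- array(c(20, 25), d)
  qc <- array(0L, d)
  s <- summarize_breast(breast, fgt, pdff, t2, qc, "p1", "left")
  expect_equal(s$mean_pdff_breast, 20)
  expect_true(is.na(s$mean_pdff_fgt))
  # uniform 80% phantom breast
  s2 <- summarize_breast(breast, breast, array(80, d), t2, qc, "p1", "left")
  expect_equal(s2$mean_pdff_breast, 80)
  expect_equal(s2$mean_pdff_fgt, 80)
  # flagged voxels are excluded from the means
  qc[2] <- 2L
  s3 <- summarize_breast(breast, fgt, pdff, t2, qc, "p1", "left")
  expect_equal(s3$mean_pdff_breast, 10)
  expect_error(summarize_breast(array(FALSE, d), fgt, pdff, t2, qc), "empty")
  half <- array(c(TRUE, FALSE), d)
  expect_error(summarize_breast(half, !half, pdff, t2, qc), "outside")
})
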