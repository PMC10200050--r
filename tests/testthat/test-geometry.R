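test_that("surplus crop planning splits the remainder evenly", {
  cp <- plan_crop(image_dims(9287, 10399), 1400)
  expect_equal(cp$surplus_length_px, 887)
  expect_equal(cp$surplus_width_px, 599)
  expect_equal(cp$cropped_dims$length_px, 8400)
  expect_equal(cp$cropped_dims$width_px, 9800)
  expect_equal(cp$offset_top, 443)
  expect_equal(cp$offset_left, 299)

  exact <- plan_crop(image_dims(1400, 1400), 1400)
  expect_equal(exact$surplus_length_px, 0)
  expect_equal(exact$offset_top, 0)

  # odd surplus: the extra pixel is removed from the bottom
  odd <- plan_crop(image_dims(1401, 1400), 1400)
  expect_equal(odd$surplus_length_px, 1)
  expect_equal(odd$offset_top, 0)

  expect_error(plan_crop(image_dims(1399, 1400), 1400), "too small")
})

test_that("crop symmetry: removed sides differ by at most one pixel", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(1400:20000, 1)
    W <- sample(1400:20000, 1)
    cp <- plan_crop(image_dims(L, W), 1400)
    bottom <- cp$surplus_length_px - cp$offset_top
    right <- cp$surplus_width_px - cp$offset_left
    expect_lte(abs(cp$offset_top - bottom), 1)
    expect_lte(abs(cp$offset_left - right), 1)
    expect_gte(bottom, cp$offset_top)  # extra pixel goes bottom/right
    expect_equal(cp$cropped_dims$length_px %% 1400, 0)
  }
})

test_that("tile planning partitions the cropped image in row-major order", {
  cp <- plan_crop(image_dims(9287, 10399), 1400)
  tiles <- plan_tiles(cp, padding_px = 100)
  expect_equal(nrow(tiles), 42)  # 6 x 7 grid
  expect_equal(tiles$padded_size_px[1], 1600)
  # row-major: first row of tiles first
  expect_equal(tiles$row_index[1:7], rep(0L, 7))
  expect_equal(tiles$col_index[1:7], 0:6)
  # cores partition exactly: total core area equals cropped area
  expect_equal(sum(rep(1400^2, nrow(tiles))), 8400 * 9800)
  # cores are disjoint and aligned
  expect_true(all(tiles$core_row %% 1400 == 0))
  expect_equal(sort(unique(tiles$core_row)), seq(0, 7000, by = 1400))

  single <- plan_tiles(plan_crop(image_dims(1400, 1400)), padding_px = 100)
  expect_equal(nrow(single), 1)
  expect_equal(single$core_row, 0)
  expect_equal(single$core_col, 0)

  # adjacent padded tiles overlap in a 2 * padding band
  two <- plan_tiles(plan_crop(image_dims(2800, 1400)), padding_px = 100)
  expect_equal(nrow(two), 2)
  overlap <- (two$padded_row[1] + two$padded_size_px[1]) - two$padded_row[2]
  expect_equal(overlap, 200)
})

test_that("tile extraction pulls real pixels from the surplus and reflects beyond", {
  # constant image: any tile is constant
  cp <- plan_crop(image_dims(1400, 1400))
  tiles <- plan_tiles(cp, padding_px = 100)
  img <- array(0.5, c(1400, 1400, 3))
  blk <- extract_tile(img, tiles[1, ], cp)
  expect_equal(dim(blk), c(1600, 1600, 3))
  expect_true(all(blk == 0.5))

  # structured image: interior of the padded window must equal a direct crop
  set.seed(1)
  img2 <- array(runif(1700 * 1600 * 3), c(1700, 1600, 3))
  cp2 <- plan_crop(image_dims(1700, 1600))  # surplus 300 x 200
  t2 <- plan_tiles(cp2, padding_px = 100)[1, ]
  blk2 <- extract_tile(img2, t2, cp2)
  # padded window rows: cropped rows -100..1499 -> original rows 50..1649,
  # all inside the original image because surplus/2 >= padding
  expect_equal(blk2, img2[51:1650, 1:1600, ])

  # reflection at the true image border: mirrored rows match
  cp3 <- plan_crop(image_dims(1400, 1400))
  t3 <- plan_tiles(cp3, padding_px = 100)[1, ]
  img3 <- array(runif(1400 * 1400 * 3), c(1400, 1400, 3))
  blk3 <- extract_tile(img3, t3, cp3, edge_policy = "reflect")
  # window row 100 is original row 0; window row 99 mirrors it
  expect_equal(blk3[100, , ], blk3[101, , ])
  expect_equal(blk3[1, , ], blk3[200, , ])  # row -100 mirrors row 99
  blk3z <- extract_tile(img3, t3, cp3, edge_policy = "zero")
  expect_true(all(blk3z[1:100, , ] == 0))

  expect_error(extract_tile(array(0, c(10, 10, 3)), t3, cp3), "expects")
})

test_that("box retranslation to global coordinates round-trips exactly", {
  cp <- plan_crop(image_dims(9287, 10399))
  tiles <- plan_tiles(cp, padding_px = 100)
  # tile with core origin (1400, 1400) -> padded origin (1300, 1300)
  t11 <- tiles[tiles$row_index == 1 & tiles$col_index == 1, ]
  expect_equal(t11$padded_row, 1300)
  b <- boxes(5, 5, 25, 25)
  g <- to_global(b, t11, cp)
  expect_equal(g$x1, 5 + 1300 + 299)
  expect_equal(g$y1, 5 + 1300 + 443)
  expect_equal(g$y2 - g$y1, 20)

  # identity tile at the origin with no crop offsets
  cp0 <- plan_crop(image_dims(1400, 1400))
  t0 <- plan_tiles(cp0, padding_px = 0)[1, ]
  expect_equal(to_global(boxes(0, 0, 10, 10), t0, cp0)[, 1:4],
               boxes(0, 0, 10, 10)[, 1:4])

  # round trip is exact for random boxes on random tiles
  set.seed(7)
  for (i in 1:20) {
    tt <- tiles[sample(nrow(tiles), 1), ]
    b <- random_int_boxes(5, canvas = 1600)
    back <- to_tile_local(to_global(b, tt, cp), tt, cp)
    expect_equal(back[, 1:4], b[, 1:4])
  }

  expect_error(to_global(boxes(0, 0, 1700, 10), t11, cp), "padded extent")
})

test_that("exact IoU matches closed forms and is well-behaved", {
  b <- boxes(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  expect_equal(iou(b), 1)
  expect_equal(iou(boxes(c(0, 20), c(0, 20), c(10, 30), c(10, 30))), 0)
  expect_equal(iou(boxes(c(0, 5), c(0, 0), c(10, 15), c(10, 10))), 1 / 3)
  expect_equal(iou(boxes(0, 0, 7, 9)), 1)  # single box
  expect_error(iou(empty_boxes()), "at least one")
})

test_that("IoU is symmetric, translation-invariant and bounded by pairwise IoU", {
  set.seed(99)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    b <- random_int_boxes(k)
    v <- iou(b)
    expect_equal(iou(b[sample(k), ]), v)
    shifted <- b
    dx <- sample(0:50, 1); dy <- sample(0:50, 1)
    shifted$x1 <- shifted$x1 + dx; shifted$x2 <- shifted$x2 + dx
    shifted$y1 <- shifted$y1 + dy; shifted$y2 <- shifted$y2 + dy
    expect_equal(iou(shifted), v)
    if (k > 2) {
      pair_min <- min(apply(utils::combn(k, 2), 2, function(ij)
        iou(b[ij, ])))
      expect_lte(v, pair_min + 1e-12)
    }
  }
})

test_that("exact IoU equals the pixel-rasterization oracle", {
  set.seed(123)
  for (i in 1:200) {
    k <- sample(2:3, 1)
    b <- random_int_boxes(k)
    expect_equal(iou(b), raster_iou(b), tolerance = 1e-12)
  }
})
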