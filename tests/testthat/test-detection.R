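test_that("duplicate merging follows the envelope rule", {
  # identical boxes: one survivor carrying the max confidence
  two <- boxes(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
               confidence = c(0.7, 0.9))
  m <- merge_detections(two, 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$confidence, 0.9)
  expect_equal(unlist(m[1, 1:4]), c(x1 = 0, y1 = 0, x2 = 10, y2 = 10))

  # IoU exactly 1/3 is not above 0.5: no merge
  nm <- merge_detections(boxes(c(0, 5), c(0, 0), c(10, 15), c(10, 10)), 0.5)
  expect_equal(nrow(nm), 2)

  # chained overlaps merge transitively into one envelope
  chain <- boxes(c(0, 3, 6), c(0, 0, 0), c(10, 13, 16), c(10, 10, 10))
  expect_gt(iou(chain[1:2, ]), 0.5)
  expect_gt(iou(chain[2:3, ]), 0.5)
  expect_lt(iou(chain[c(1, 3), ]), 0.5)
  mc <- merge_detections(chain, 0.5)
  expect_equal(nrow(mc), 1)
  expect_equal(unlist(mc[1, 1:4]), c(x1 = 0, y1 = 0, x2 = 16, y2 = 10))

  expect_equal(nrow(merge_detections(empty_boxes(), 0.5)), 0)
})

test_that("merging is idempotent and permutation-invariant", {
  set.seed(11)
  for (i in 1:40) {
    b <- random_int_boxes(sample(2:8, 1), canvas = 40)
    m1 <- merge_detections(b, 0.5)
    expect_equal(merge_detections(m1, 0.5), m1)
    perm <- b[sample(nrow(b)), ]
    expect_equal(merge_detections(perm, 0.5), m1)
    expect_lte(nrow(m1), nrow(b))
  }
})

test_that("merging agrees with the transitive-closure oracle", {
  set.seed(202)
  for (i in 1:300) {
    b <- random_int_boxes(sample(1:6, 1), canvas = 30)
    got <- merge_detections(b, 0.5)
    want <- oracle_merge(b, 0.5)
    expect_equal(got[, 1:4], want[, 1:4])
    expect_equal(got$confidence, want$confidence)
  }
})

test_that("size filter rejects objects outside the 20-90 px band", {
  b <- boxes(c(0, 100, 200), c(0, 0, 0),
             c(19, 145, 240), c(40, 51, 91))
  kept <- filter_size(b, 20, 90)
  expect_equal(nrow(kept), 1)          # only the 45 x 51 average-size egg
  expect_equal(kept$x1, 100)
  rej <- attr(kept, "rejected")
  expect_equal(rej$reason, c("too_small", "too_large"))
  # boundary: exactly 20 and exactly 90 are kept
  edge <- filter_size(boxes(c(0, 0), c(0, 50), c(20, 90), c(20, 140)), 20, 90)
  expect_equal(nrow(edge), 2)
})

test_that("confidence filter keeps the boundary and is monotone in tau", {
  b <- boxes(1:3, 1:3, 11:13, 11:13, confidence = c(0.55, 0.60, 0.65))
  expect_equal(nrow(filter_confidence(b, 0)), 3)
  expect_equal(nrow(filter_confidence(b, 0.6)), 2)
  expect_equal(nrow(filter_confidence(b, 1)), 0)
  taus <- seq(0, 1, by = 0.1)
  sizes <- vapply(taus, function(t) nrow(filter_confidence(b, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("reference detector scores eggs high and trichomes low", {
  eggs <- data.frame(cx = 200, cy = 150, a = 30, b = 12, theta = 0.8,
                     t_col = 0.4)
  truth <- manual_scene(400, 400, eggs, seed = 2)
  img <- render_scene(truth)
  det <- reference_blob_detect(img)
  expect_equal(nrow(det), 1)
  expect_gt(det$confidence, 0.8)
  expect_gt(iou(rbind(det[, 1:6], truth$truth_boxes)), 0.5)

  # trichome-only scene: all components low-confidence or below min area
  cfg <- scene_config(height_px = 600, width_px = 600, n_eggs = 0,
                      n_trichomes = 6, seed = 5)
  ttr <- generate_scene(cfg)
  dtr <- reference_blob_detect(render_scene(ttr))
  expect_true(nrow(dtr) == 0 || all(dtr$confidence < 0.5))

  # empty tile
  cfg0 <- scene_config(height_px = 300, width_px = 300, n_eggs = 0, seed = 1)
  expect_equal(nrow(reference_blob_detect(render_scene(generate_scene(cfg0)))),
               0)
  expect_error(reference_blob_detect(matrix(0, 10, 10)), "RGB")
})

test_that("full pipeline counts well-separated eggs exactly", {
  cfg <- scene_config(height_px = 1450, width_px = 1500, n_eggs = 10,
                      edge_margin_px = 55, seed = 31)
  truth <- generate_scene(cfg)
  img <- render_scene(truth)
  res <- quantify_image(img, reference_backend(), pipeline_config())
  expect_s3_class(res, "egg_count_result")
  expect_equal(res$count, 10)
  m <- match_boxes(truth$truth_boxes, res$final_boxes, 0.5)
  expect_equal(m$tp, 10)
  expect_equal(m$fp, 0)
  # stage monotonicity
  expect_gte(nrow(res$raw_boxes), nrow(res$merged_boxes))
  expect_gte(nrow(res$merged_boxes), nrow(res$size_filtered_boxes))
  expect_gte(nrow(res$size_filtered_boxes), nrow(res$final_boxes))
  # final boxes satisfy the filters and image bounds
  expect_true(all(pmin(res$final_boxes$x2 - res$final_boxes$x1,
                       res$final_boxes$y2 - res$final_boxes$y1) >= 20))
  expect_true(all(res$final_boxes$confidence >= 0.6))
  expect_true(all(res$final_boxes$x2 <= 1500 & res$final_boxes$y2 <= 1450))

  # blank image: zero count
  cfg0 <- scene_config(height_px = 1400, width_px = 1400, n_eggs = 0,
                       seed = 3)
  blank <- render_scene(generate_scene(cfg0))
  expect_equal(quantify_image(blank, reference_backend(),
                              pipeline_config())$count, 0)
})

test_that("padding plus merging removes the straddling-egg double count", {
  eggs <- data.frame(cx = 700, cy = 1400, a = 40, b = 23, theta = 0,
                     t_col = 0.5)
  truth <- manual_scene(2800, 1400, eggs, seed = 3)
  img <- render_scene(truth)
  with_pad <- quantify_image(img, reference_backend(), pipeline_config())
  expect_gte(nrow(with_pad$raw_boxes), 2)  # seen by both padded tiles
  expect_equal(with_pad$count, 1)
  no_pad <- quantify_image(img, reference_backend(drop_border = FALSE),
                           pipeline_config(padding_px = 0))
  expect_equal(no_pad$count, 2)  # two clipped halves, disjoint, unmerged
})

test_that("pipeline config round-trips through the flat key/value file", {
  cfg <- pipeline_config(confidence_threshold = 0.45, padding_px = 80,
                         edge_policy = "replicate")
  f <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back, cfg)
  expect_error(read_config(withr::local_tempfile(lines = "nope = 1")),
               "unknown config keys")
  expect_error(pipeline_config(min_side_px = 90, max_side_px = 20))
})

test_that("size filter removes salted specks and smears without losing eggs", {
  # four eggs on a grid, plus sub-20-px specks and >90-px smears placed
  # in the free cells so nothing overlaps
  eggs <- data.frame(cx = c(300, 1100, 300, 1100),
                     cy = c(300, 300, 1100, 1100),
                     a = c(30, 35, 40, 28), b = c(12, 15, 17, 12),
                     theta = c(0, 0.7, 1.4, 2.4), t_col = c(0.2, 0.4, 0.6, 0.8))
  truth <- manual_scene(1400, 1400, eggs, seed = 13)
  truth$specks <- data.frame(cx = c(700, 150, 1250), cy = c(700, 700, 700),
                             r = c(4, 6, 8))
  truth$smears <- data.frame(cx = c(700, 700), cy = c(150, 1250),
                             rx = c(60, 80), ry = c(55, 70))
  img <- render_scene(truth)
  res <- quantify_image(img, reference_backend(), pipeline_config())
  expect_equal(res$count, 4)
  rejected <- attr(res$size_filtered_boxes, "rejected")
  expect_true(all(c("too_small", "too_large") %in% rejected$reason))
})

test_that("backend failures abort with the tile index", {
  bad <- detector_backend("bad", function(tile) stop("boom"))
  img <- array(0.3, c(1400, 1400, 3))
  expect_error(quantify_image(img, bad, pipeline_config()), "tile 1")
  expect_equal(quantify_image(img, null_backend(), pipeline_config())$count,
               0)
  expect_error(quantify_image(array(0.3, c(100, 100, 3)), null_backend(),
                              pipeline_config()), "too small")
})
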