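#' Pipeline configuration
#'
#' Defaults follow the published quantification protocol: 1400-px tile
#' cores with 100-px padding (1600-px padded tiles), duplicate merging at
#' IoU > 0.5, a 20/90-px object size filter, and a confidence threshold of
#' 0.6 found by a grid sweep.
#'
#' @param core_size_px Tile core size in pixels.
#' @param padding_px Tile padding per side in pixels.
#' @param merge_iou_threshold Boxes with pairwise IoU strictly above this
#'   are merged into one.
#' @param min_side_px Reject a detection if either side is shorter.
#' @param max_side_px Reject a detection if either side is longer.
#' @param confidence_threshold Keep detections with confidence `>= tau`.
#' @param edge_policy Tile-extraction fill outside the original image.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(core_size_px = 1400, padding_px = 100,
                            merge_iou_threshold = 0.5, min_side_px = 20,
                            max_side_px = 90, confidence_threshold = 0.6,
                            edge_policy = "reflect") {
  stopifnot(merge_iou_threshold > 0, merge_iou_threshold <= 1,
            confidence_threshold >= 0, confidence_threshold <= 1,
            min_side_px < max_side_px, core_size_px >= 1, padding_px >= 0)
  structure(list(core_size_px = as.integer(core_size_px),
                 padding_px = as.integer(padding_px),
                 merge_iou_threshold = merge_iou_threshold,
                 min_side_px = min_side_px, max_side_px = max_side_px,
                 confidence_threshold = confidence_threshold,
                 edge_policy = edge_policy),
            class = "pipeline_config")
}

#' Detector backend contract
#'
#' A backend is the pluggable seat of the per-tile object detector: any
#' function that maps a padded RGB tile (numeric array
#' `size x size x 3`) to a box table in tile-local coordinates with
#' confidences in `[0, 1]`. A trained deep-learning detector can be plugged
#' in by wrapping its per-tile inference in this contract (any internal
#' resizing is the backend's private concern). The package ships
#' [reference_backend()] for synthetic scenes and [null_backend()] which
#' detects nothing.
#'
#' @param name Backend name recorded in results.
#' @param detect `function(tile)` returning a box table.
#' @return A `detector_backend` object.
#' @export
detector_backend <- function(name, detect) {
  stopifnot(is.character(name), is.function(detect))
  structure(list(name = name, detect = detect), class = "detector_backend")
}

#' @rdname detector_backend
#' @export
null_backend <- function() {
  detector_backend("null", function(tile) empty_boxes())
}

#' @rdname detector_backend
#' @param ... Parameters passed to [reference_blob_detect()].
#' @export
reference_backend <- function(...) {
  detector_backend("reference", function(tile) {
    reference_blob_detect(tile, ...)
  })
}

#' Reference blob detector for synthetic leaf scenes
#'
#' A deterministic colour-contrast detector used as the stand-alone
#' backend for testing the full pipeline without a trained model. Eggs
#' (translucent green to brown) score high on the `2R - G` channel
#' contrast against the green leaf background. Pixels above
#' `score_threshold` are labelled into connected components; each
#' component's bounding box becomes a detection.
#'
#' The confidence is a shape score in `[0, 1]`: the product of a fill-ratio
#' term (component area over box area, saturating at 0.5 — a solid ellipse
#' fills at least ~54% of its bounding box at any rotation) and a term
#' rewarding proximity of the moment-based axis ratio to 0.4, the
#' length-to-width ratio of a whitefly egg (0.2 mm by 0.08 mm). Thin
#' trichome strands score below 0.5 on the axis-ratio term alone.
#'
#' @param tile Numeric RGB array `h x w x 3`.
#' @param score_threshold Threshold on the `2R - G` contrast.
#' @param min_area_px Minimum component pixel area.
#' @param drop_border Drop components touching the tile border; a clipped,
#'   partially visible object is always seen whole by a neighbouring
#'   padded tile, and its clipped duplicate could not be IoU-merged.
#' @param bbox_grow_px Grow each component box by this many pixels per
#'   side to recover the anti-aliased rim lost to thresholding.
#' @return A box table in tile-local coordinates.
#' @export
reference_blob_detect <- function(tile, score_threshold = 0.35,
                                  min_area_px = 40, drop_border = TRUE,
                                  bbox_grow_px = 1) {
  d <- dim(tile)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("reference detector requires an RGB tile (h x w x 3 array)")
  }
  score <- 2 * tile[, , 1] - tile[, , 2]
  mask <- score > score_threshold
  if (!any(mask)) return(empty_boxes())
  lab <- EBImage::bwlabel(mask)
  px <- which(mask, arr.ind = TRUE)
  ids <- lab[mask]
  rows <- px[, 1]
  cols <- px[, 2]
  area <- tabulate(ids)
  keep_ids <- which(area >= min_area_px)
  if (!length(keep_ids)) return(empty_boxes())
  agg <- function(v, fun) {
    out <- rep(NA_real_, max(ids))
    s <- vapply(split(v, ids), fun, numeric(1))
    out[as.integer(names(s))] <- s
    out
  }
  rmin <- agg(rows, min); rmax <- agg(rows, max)
  cmin <- agg(cols, min); cmax <- agg(cols, max)
  if (drop_border) {
    interior <- rmin > 1 & cmin > 1 & rmax < d[1] & cmax < d[2]
    keep_ids <- keep_ids[interior[keep_ids]]
    if (!length(keep_ids)) return(empty_boxes())
  }
  # moment-based axis ratio: eigenvalues of the per-component pixel
  # covariance are rotation-invariant estimates of the squared semi-axes
  mr <- agg(rows, mean); mc <- agg(cols, mean)
  vr <- agg(rows, stats::var); vc <- agg(cols, stats::var)
  n_id <- area
  cv <- rep(0, max(ids))
  cov_s <- vapply(split(seq_along(ids), ids), function(i) {
    if (length(i) < 2) return(0)
    stats::cov(rows[i], cols[i])
  }, numeric(1))
  cv[as.integer(names(cov_s))] <- cov_s
  vr[is.na(vr)] <- 0; vc[is.na(vc)] <- 0
  tr2 <- (vr + vc) / 2
  disc <- sqrt(pmax(0, ((vr - vc) / 2)^2 + cv^2))
  lam1 <- tr2 + disc
  lam2 <- pmax(0, tr2 - disc)
  axis_ratio <- ifelse(lam1 > 0, sqrt(lam2 / lam1), 0)

  i <- keep_ids
  # half-open pixel boxes from 1-based inclusive index bounds, grown
  x1 <- pmax(0, cmin[i] - 1 - bbox_grow_px)
  y1 <- pmax(0, rmin[i] - 1 - bbox_grow_px)
  x2 <- pmin(d[2], cmax[i] + bbox_grow_px)
  y2 <- pmin(d[1], rmax[i] + bbox_grow_px)
  fill <- area[i] / ((cmax[i] - cmin[i] + 1) * (rmax[i] - rmin[i] + 1))
  s_fill <- pmin(fill / 0.5, 1)
  s_ratio <- exp(-(axis_ratio[i] - 0.4)^2 / (2 * 0.25^2))
  conf <- pmin(pmax(s_fill * s_ratio, 0), 1)
  sort_boxes(boxes(x1, y1, x2, y2, confidence = conf))
}

#' Merge overlapping duplicate detections
#'
#' Detections of the same egg from adjacent padded tiles overlap heavily.
#' Boxes whose pairwise IoU exceeds `iou_threshold` are grouped (connected
#' components of the overlap graph, so "two or more" mutually chained
#' boxes merge together) and each group is replaced by its coordinate-wise
#' envelope: the lowest `x1`/`y1` and highest `x2`/`y2`. The merged box's
#' confidence is the maximum of its constituents. Because envelopes can
#' create new overlaps, the grouping is recomputed until a fixed point;
#' the result is independent of input order and idempotent.
#'
#' @param b A box table.
#' @param iou_threshold Merge when pairwise IoU is strictly greater.
#' @return The merged box table, sorted by `(y1, x1)`.
#' @export
merge_detections <- function(b, iou_threshold = 0.5) {
  b <- validate_boxes(b)
  if (nrow(b) <= 1L) return(sort_boxes(b))
  repeat {
    m <- iou_matrix(b, b)
    adj <- m > iou_threshold
    comp <- graph_components(adj)
    if (max(comp) == nrow(b)) break
    merged <- lapply(seq_len(max(comp)), function(k) {
      g <- b[comp == k, , drop = FALSE]
      data.frame(x1 = min(g$x1), y1 = min(g$y1),
                 x2 = max(g$x2), y2 = max(g$y2),
                 confidence = max(g$confidence),
                 label = g$label[1], stringsAsFactors = FALSE)
    })
    b <- do.call(rbind, merged)
    if (nrow(b) == 1L) break
  }
  sort_boxes(b)
}

# Connected components of an undirected adjacency matrix (diagonal
# ignored), by iterative label propagation.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ] | adj[, i])
      nb <- nb[nb != i]
      if (length(nb)) {
        new <- min(comp[i], comp[nb])
        if (any(comp[c(i, nb)] != new)) {
          comp[c(i, nb)] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Filter detections by object size
#'
#' Objects with either side shorter than `min_side_px` (trichome
#' fragments, leaf spots) or longer than `max_side_px` (nymphs, smears)
#' are removed. Sides are measured in pixels from the half-open
#' coordinates.
#'
#' @param b A box table.
#' @param min_side_px,max_side_px Size bounds in pixels (kept iff
#'   `min(side) >= min_side_px` and `max(side) <= max_side_px`).
#' @return The surviving boxes; the attribute `"rejected"` holds the
#'   removed boxes with a `reason` column (`"too_small"`/`"too_large"`).
#' @export
filter_size <- function(b, min_side_px = 20, max_side_px = 90) {
  b <- validate_boxes(b)
  w <- box_widths(b)
  h <- box_heights(b)
  too_small <- pmin(w, h) < min_side_px
  too_large <- pmax(w, h) > max_side_px
  keep <- !(too_small | too_large)
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  rej <- b[!keep, , drop = FALSE]
  if (nrow(rej)) {
    rej$reason <- ifelse(too_small[!keep], "too_small", "too_large")
  } else {
    rej$reason <- character(0)
  }
  attr(out, "rejected") <- rej
  out
}

#' Filter detections by confidence
#'
#' @param b A box table.
#' @param tau Threshold in `[0, 1]`; boxes with `confidence >= tau` are
#'   kept (boundary kept, so a sweep grid value keeps exactly the boxes at
#'   or above it).
#' @return The surviving boxes.
#' @export
filter_confidence <- function(b, tau) {
  stopifnot(tau >= 0, tau <= 1)
  b <- validate_boxes(b)
  out <- b[b$confidence >= tau, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify eggs in one leaf image
#'
#' Runs the full pipeline: surplus crop planning, padded tiling, per-tile
#' detection through the backend, retranslation of boxes to original
#' coordinates, then the three post-processing stages in order —
#' duplicate merging, object size filtering, and confidence thresholding.
#' Final boxes are clipped to the original image bounds.
#'
#' @param image Numeric array `height x width x 3` (or matrix), or a file
#'   path readable by [read_image()].
#' @param backend A [detector_backend()].
#' @param config A [pipeline_config()].
#' @param image_id Identifier recorded in the result (defaults to the file
#'   name when `image` is a path).
#' @return An `egg_count_result`: box tables after each stage
#'   (`raw_boxes`, `merged_boxes`, `size_filtered_boxes`, `final_boxes`),
#'   the final `count`, the crop plan, tile count and config snapshot.
#' @export
quantify_image <- function(image, backend = reference_backend(),
                           config = pipeline_config(), image_id = NULL) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  stopifnot(inherits(backend, "detector_backend"),
            inherits(config, "pipeline_config"))
  d <- dim(image)
  crop <- plan_crop(image_dims(d[1], d[2]), config$core_size_px)
  tiles <- plan_tiles(crop, config$core_size_px, config$padding_px)
  raw <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    tile <- tiles[i, ]
    block <- extract_tile(image, tile, crop, config$edge_policy)
    det <- tryCatch(backend$detect(block), error = function(e) {
      stop(sprintf("backend '%s' failed on tile %d (row %d, col %d): %s",
                   backend$name, i, tile$row_index, tile$col_index,
                   conditionMessage(e)))
    })
    raw[[i]] <- to_global(validate_boxes(det), tile, crop)
  }
  raw <- do.call(rbind, c(list(empty_boxes()), raw))
  rownames(raw) <- NULL
  merged <- merge_detections(raw, config$merge_iou_threshold)
  sized <- filter_size(merged, config$min_side_px, config$max_side_px)
  final <- filter_confidence(sized, config$confidence_threshold)
  # clip to original image bounds
  if (nrow(final)) {
    final$x1 <- pmax(final$x1, 0)
    final$y1 <- pmax(final$y1, 0)
    final$x2 <- pmin(final$x2, d[2])
    final$y2 <- pmin(final$y2, d[1])
  }
  structure(list(
    image_id = image_id,
    raw_boxes = sort_boxes(raw),
    merged_boxes = merged,
    size_filtered_boxes = sized,
    final_boxes = final,
    count = nrow(final),
    n_tiles = nrow(tiles),
    crop = crop,
    config = config
  ), class = "egg_count_result")
}

#' @export
print.egg_count_result <- function(x, ...) {
  cat(sprintf(
    "egg count for '%s': %d\n  tiles: %d  raw: %d  merged: %d  size-filtered: %d  final: %d\n",
    x$image_id, x$count, x$n_tiles, nrow(x$raw_boxes),
    nrow(x$merged_boxes), nrow(x$size_filtered_boxes), nrow(x$final_boxes)))
  invisible(x)
}
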