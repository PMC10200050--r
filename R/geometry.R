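#' Image dimensions
#'
#' @param length_px Image height in pixels (number of rows).
#' @param width_px Image width in pixels (number of columns).
#' @return An `image_dims` object.
#' @export
image_dims <- function(length_px, width_px) {
  length_px <- as.integer(length_px)
  width_px <- as.integer(width_px)
  stopifnot(length(length_px) == 1L, length(width_px) == 1L,
            length_px >= 1L, width_px >= 1L)
  structure(list(length_px = length_px, width_px = width_px),
            class = "image_dims")
}

#' Plan the surplus crop of a leaf image
#'
#' Large stitched leaf images rarely measure an exact multiple of the tile
#' size, so before tiling the image is reduced from `L x W` to
#' `(L - S_L) x (W - S_W)`, where the surplus `S_L = L mod core` and
#' `S_W = W mod core`. The surplus of each axis is split as evenly as
#' possible across its two sides; an odd surplus gives the extra pixel to
#' the bottom (length axis) or right (width axis).
#'
#' @param dims An [image_dims()] object (or a length-2 vector
#'   `c(length, width)`).
#' @param core_size_px Tile core size in pixels (default 1400).
#' @return A `crop_plan`: surplus per axis, top/left offsets of the crop
#'   window, original and cropped dimensions, and the core size.
#' @examples
#' plan_crop(image_dims(9287, 10399))  # surplus 887 x 599, cropped 8400 x 9800
#' @export
plan_crop <- function(dims, core_size_px = 1400L) {
  if (!inherits(dims, "image_dims")) dims <- image_dims(dims[[1]], dims[[2]])
  core_size_px <- as.integer(core_size_px)
  stopifnot(core_size_px >= 1L)
  if (dims$length_px < core_size_px || dims$width_px < core_size_px) {
    stop(sprintf(
      "image too small: %d x %d is below one %d x %d tile",
      dims$length_px, dims$width_px, core_size_px, core_size_px))
  }
  s_l <- dims$length_px %% core_size_px
  s_w <- dims$width_px %% core_size_px
  structure(list(
    surplus_length_px = s_l,
    surplus_width_px = s_w,
    offset_top = s_l %/% 2L,
    offset_left = s_w %/% 2L,
    orig_dims = dims,
    cropped_dims = image_dims(dims$length_px - s_l, dims$width_px - s_w),
    core_size_px = core_size_px
  ), class = "crop_plan")
}

#' @export
print.crop_plan <- function(x, ...) {
  cat(sprintf(
    "crop plan: %d x %d -> %d x %d (surplus %d x %d, offsets top %d left %d, core %d)\n",
    x$orig_dims$length_px, x$orig_dims$width_px,
    x$cropped_dims$length_px, x$cropped_dims$width_px,
    x$surplus_length_px, x$surplus_width_px,
    x$offset_top, x$offset_left, x$core_size_px))
  invisible(x)
}

#' Plan the padded tile grid over a cropped image
#'
#' The cropped image is partitioned exactly into `core_size_px` square
#' cores in row-major order; each tile is then extended by `padding_px` on
#' all four sides, so adjacent padded tiles overlap by `2 * padding_px`.
#' The padding lets an egg straddling a core boundary be seen whole by at
#' least one tile, and the resulting duplicate detections are removed
#' later by IoU merging.
#'
#' @param crop A [plan_crop()] result.
#' @param core_size_px Tile core size; defaults to the crop plan's.
#' @param padding_px Padding on each side (default 100), giving
#'   `core + 2 * padding` square padded tiles (1600 for the defaults).
#' @return A data.frame of tiles: `row_index`, `col_index` (0-based),
#'   `core_row`, `core_col` (core origin in cropped-image pixels),
#'   `padded_row`, `padded_col` (padded origin, may be negative),
#'   `core_size_px`, `padding_px`, `padded_size_px`.
#' @export
plan_tiles <- function(crop, core_size_px = crop$core_size_px,
                       padding_px = 100L) {
  stopifnot(inherits(crop, "crop_plan"))
  core_size_px <- as.integer(core_size_px)
  padding_px <- as.integer(padding_px)
  stopifnot(core_size_px >= 1L, padding_px >= 0L)
  cl <- crop$cropped_dims$length_px
  cw <- crop$cropped_dims$width_px
  if (cl %% core_size_px != 0L || cw %% core_size_px != 0L) {
    stop("cropped dimensions must be exact multiples of core_size_px")
  }
  n_rows <- cl %/% core_size_px
  n_cols <- cw %/% core_size_px
  grid <- expand.grid(col_index = seq_len(n_cols) - 1L,
                      row_index = seq_len(n_rows) - 1L)
  tiles <- data.frame(
    row_index = grid$row_index,
    col_index = grid$col_index,
    core_row = grid$row_index * core_size_px,
    core_col = grid$col_index * core_size_px,
    core_size_px = core_size_px,
    padding_px = padding_px
  )
  tiles$padded_row <- tiles$core_row - padding_px
  tiles$padded_col <- tiles$core_col - padding_px
  tiles$padded_size_px <- core_size_px + 2L * padding_px
  tiles
}

# Reflect out-of-range 0-based indices back into [0, n): symmetric
# reflection about the array edge (-1 -> 0, -2 -> 1, n -> n-1, ...).
reflect_index <- function(i, n) {
  i <- ((i %% (2L * n)) + 2L * n) %% (2L * n)
  ifelse(i >= n, 2L * n - 1L - i, i)
}

#' Extract one padded tile from an image
#'
#' The padded window of a tile can extend beyond the cropped image. Those
#' pixels are taken from the original (uncropped) image where the surplus
#' region provides them; beyond the original image the window is filled
#' per `edge_policy`.
#'
#' @param image A numeric array `height x width x channels` (or a matrix)
#'   matching the original dimensions used to build `crop`.
#' @param tile One row of a [plan_tiles()] data.frame.
#' @param crop The [plan_crop()] result for this image.
#' @param edge_policy `"reflect"` (default) mirrors interior pixels,
#'   `"replicate"` repeats the edge pixel, `"zero"` fills with 0.
#' @return A numeric array `padded_size x padded_size x channels`.
#' @export
extract_tile <- function(image, tile, crop,
                         edge_policy = c("reflect", "replicate", "zero")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(crop, "crop_plan"))
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("image must be a matrix or array")
  if (d[1] != crop$orig_dims$length_px || d[2] != crop$orig_dims$width_px) {
    stop(sprintf("image is %d x %d but crop plan expects %d x %d",
                 d[1], d[2], crop$orig_dims$length_px,
                 crop$orig_dims$width_px))
  }
  ps <- tile$padded_size_px
  # 0-based row/col indices of the padded window in original-image frame
  rows <- tile$padded_row + crop$offset_top + seq_len(ps) - 1L
  cols <- tile$padded_col + crop$offset_left + seq_len(ps) - 1L
  map_idx <- function(i, n) {
    switch(edge_policy,
           reflect = reflect_index(i, n),
           replicate = pmin(pmax(i, 0L), n - 1L),
           zero = i)
  }
  ri <- map_idx(rows, d[1])
  ci <- map_idx(cols, d[2])
  if (edge_policy == "zero") {
    ok_r <- ri >= 0L & ri < d[1]
    ok_c <- ci >= 0L & ci < d[2]
    out <- array(0, c(ps, ps, if (length(d) == 3L) d[3] else 1L))
    block <- if (length(d) == 3L) {
      image[ri[ok_r] + 1L, ci[ok_c] + 1L, , drop = FALSE]
    } else {
      image[ri[ok_r] + 1L, ci[ok_c] + 1L, drop = FALSE]
    }
    out[which(ok_r), which(ok_c), ] <- block
    if (length(d) == 2L) out <- out[, , 1L]
    return(out)
  }
  if (length(d) == 3L) {
    image[ri + 1L, ci + 1L, , drop = FALSE]
  } else {
    image[ri + 1L, ci + 1L, drop = FALSE]
  }
}

#' Retranslate tile-local boxes to original-image coordinates
#'
#' Detections are produced in the padded tile's local frame; stitching the
#' image back together amounts to adding the tile's padded origin and the
#' crop offsets to every box.
#'
#' @param b A box table in tile-local coordinates (within
#'   `[0, padded_size]` on both axes).
#' @param tile One row of a [plan_tiles()] data.frame.
#' @param crop The [plan_crop()] result.
#' @return The box table in original-image coordinates; confidence and
#'   label are unchanged. The inverse is [to_tile_local()].
#' @export
to_global <- function(b, tile, crop) {
  b <- validate_boxes(b)
  stopifnot(inherits(crop, "crop_plan"))
  ps <- tile$padded_size_px
  if (nrow(b) && (any(b$x1 < 0) || any(b$y1 < 0) ||
                  any(b$x2 > ps) || any(b$y2 > ps))) {
    stop("box outside the tile's padded extent")
  }
  dx <- tile$padded_col + crop$offset_left
  dy <- tile$padded_row + crop$offset_top
  b$x1 <- b$x1 + dx
  b$x2 <- b$x2 + dx
  b$y1 <- b$y1 + dy
  b$y2 <- b$y2 + dy
  b
}

#' @rdname to_global
#' @export
to_tile_local <- function(b, tile, crop) {
  b <- validate_boxes(b)
  dx <- tile$padded_col + crop$offset_left
  dy <- tile$padded_row + crop$offset_top
  b$x1 <- b$x1 - dx
  b$x2 <- b$x2 - dx
  b$y1 <- b$y1 - dy
  b$y2 <- b$y2 - dy
  b
}
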