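#' Construct a table of detection boxes
#'
#' Boxes are axis-aligned rectangles in image pixel coordinates, 0-based and
#' half-open: a box covers `[x1, x2) x [y1, y2)` with `x` as column and `y`
#' as row. Width is `x2 - x1` and height `y2 - y1`, so area arithmetic is
#' exact and unambiguous.
#'
#' @param x1,y1,x2,y2 Numeric vectors of equal length; `x1 < x2`, `y1 < y2`,
#'   all finite and non-negative.
#' @param confidence Detection confidence in `[0, 1]` (recycled).
#' @param label Category tag; the pipeline uses the single class `"egg"`.
#' @return A `data.frame` with columns `x1, y1, x2, y2, confidence, label`.
#' @examples
#' boxes(0, 0, 10, 10, confidence = 0.9)
#' @export
boxes <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                  y2 = numeric(), confidence = 1, label = "egg") {
  n <- length(x1)
  b <- data.frame(
    x1 = as.numeric(x1), y1 = as.numeric(y1),
    x2 = as.numeric(x2), y2 = as.numeric(y2),
    confidence = rep_len(as.numeric(confidence), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  validate_boxes(b)
}

#' Validate a box table
#'
#' @param b A data.frame with at least columns `x1, y1, x2, y2`; missing
#'   `confidence`/`label` columns are filled with defaults.
#' @return The validated data.frame (invisibly unchanged apart from filled
#'   defaults).
#' @export
validate_boxes <- function(b) {
  stopifnot(is.data.frame(b))
  req <- c("x1", "y1", "x2", "y2")
  if (!all(req %in% names(b))) {
    stop("box table must have columns x1, y1, x2, y2")
  }
  if (!"confidence" %in% names(b)) b$confidence <- 1
  if (!"label" %in% names(b)) b$label <- "egg"
  if (nrow(b)) {
    coords <- as.matrix(b[, req])
    if (any(!is.finite(coords)) || any(coords < 0)) {
      stop("box coordinates must be finite and >= 0")
    }
    if (any(b$x1 >= b$x2) || any(b$y1 >= b$y2)) {
      stop("boxes must satisfy x1 < x2 and y1 < y2")
    }
    if (any(!is.finite(b$confidence)) || any(b$confidence < 0) ||
        any(b$confidence > 1)) {
      stop("confidence must lie in [0, 1]")
    }
  }
  b
}

#' @rdname boxes
#' @export
empty_boxes <- function() boxes()

box_widths <- function(b) b$x2 - b$x1
box_heights <- function(b) b$y2 - b$y1
box_areas <- function(b) (b$x2 - b$x1) * (b$y2 - b$y1)

#' Exact intersection-over-union of one or more boxes
#'
#' For two boxes this is the usual overlap-over-union ratio; the k-ary form
#' divides the area of the common intersection of all boxes by the area of
#' their union. The union area is computed exactly by coordinate
#' compression (no rasterization), so the result is correct for real-valued
#' coordinates. A single box gives 1.
#'
#' @param b A box table (see [boxes()]) with at least one row.
#' @return A value in `[0, 1]`.
#' @examples
#' iou(boxes(c(0, 5), c(0, 0), c(10, 15), c(10, 10)))  # 1/3
#' @export
iou <- function(b) {
  b <- validate_boxes(b)
  if (nrow(b) == 0L) stop("iou() requires at least one box")
  if (nrow(b) == 1L) return(1)
  ix <- max(0, min(b$x2) - max(b$x1))
  iy <- max(0, min(b$y2) - max(b$y1))
  inter <- ix * iy
  union_area <- rect_union_area(b)
  inter / union_area
}

# Exact area of the union of axis-aligned rectangles via coordinate
# compression: the plane is cut into a grid by all box edges and each grid
# cell is counted once if covered by any box.
rect_union_area <- function(b) {
  xs <- sort(unique(c(b$x1, b$x2)))
  ys <- sort(unique(c(b$y1, b$y2)))
  dx <- diff(xs)
  dy <- diff(ys)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  covered_x <- outer(cx, b$x1, ">=") & outer(cx, b$x2, "<")
  covered_y <- outer(cy, b$y1, ">=") & outer(cy, b$y2, "<")
  total <- 0
  for (j in seq_along(cy)) {
    active <- covered_y[j, ]
    if (!any(active)) next
    any_cov <- rowSums(covered_x[, active, drop = FALSE]) > 0
    total <- total + sum(dx[any_cov]) * dy[j]
  }
  total
}

#' Pairwise IoU matrix between two box tables
#'
#' @param a,b Box tables.
#' @return An `nrow(a)` by `nrow(b)` matrix of two-box IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- validate_boxes(a)
  b <- validate_boxes(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(), nrow(a), nrow(b)))
  }
  ix <- pmax(0, outer(a$x2, b$x2, pmin) - outer(a$x1, b$x1, pmax))
  iy <- pmax(0, outer(a$y2, b$y2, pmin) - outer(a$y1, b$y1, pmax))
  inter <- ix * iy
  un <- outer(box_areas(a), box_areas(b), "+") - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}

sort_boxes <- function(b) {
  if (nrow(b) <= 1L) return(b)
  b <- b[order(b$y1, b$x1, b$y2, b$x2), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Read and write box annotations
#'
#' Two on-disk dialects are supported and converted to/from the package's
#' 0-based half-open pixel convention:
#'
#' * **YOLO text**: one line per box, `class cx cy w h`, all four geometry
#'   fields normalized by image width/height; an optional sixth field is
#'   read as confidence. Class index 0 maps to label `"egg"`.
#' * **CSV**: header `image,x1,y1,x2,y2,confidence,label` with pixel
#'   coordinates.
#'
#' @param path File path.
#' @param width_px,height_px Image dimensions used to (de)normalize the
#'   YOLO dialect.
#' @param b Box table to write.
#' @param image Image identifier written to the CSV `image` column.
#' @return Readers return a box table; writers return `path` invisibly.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_yolo <- function(path, width_px, height_px) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  fields <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  nf <- lengths(fields)
  if (any(nf < 5)) stop("YOLO lines must have at least 5 fields: class cx cy w h")
  m <- t(vapply(fields, function(f) f[1:5], numeric(5)))
  conf <- vapply(fields, function(f) if (length(f) >= 6) f[6] else 1, numeric(1))
  cx <- m[, 2] * width_px
  cy <- m[, 3] * height_px
  w <- m[, 4] * width_px
  h <- m[, 5] * height_px
  boxes(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2,
        confidence = conf,
        label = ifelse(m[, 1] == 0, "egg", as.character(m[, 1])))
}

#' @rdname annotation_io
#' @export
write_yolo <- function(b, path, width_px, height_px) {
  b <- validate_boxes(b)
  cls <- ifelse(b$label == "egg", 0L, suppressWarnings(as.integer(b$label)))
  cx <- (b$x1 + b$x2) / 2 / width_px
  cy <- (b$y1 + b$y2) / 2 / height_px
  w <- (b$x2 - b$x1) / width_px
  h <- (b$y2 - b$y1) / height_px
  lines <- sprintf("%d %.10g %.10g %.10g %.10g %.6g", cls, cx, cy, w, h,
                   b$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_boxes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(d))) {
    stop("boxes CSV must have header image,x1,y1,x2,y2[,confidence,label]")
  }
  if (!"confidence" %in% names(d)) d$confidence <- 1
  if (!"label" %in% names(d)) d$label <- "egg"
  b <- validate_boxes(d[, c("x1", "y1", "x2", "y2", "confidence", "label")])
  b$image <- d$image
  b[, c("image", "x1", "y1", "x2", "y2", "confidence", "label")]
}

#' @rdname annotation_io
#' @export
write_boxes_csv <- function(b, path, image = "image") {
  b <- validate_boxes(b)
  out <- data.frame(image = if ("image" %in% names(b)) b$image else
                      rep_len(image, nrow(b)),
                    b[, c("x1", "y1", "x2", "y2", "confidence", "label")],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
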