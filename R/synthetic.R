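#' Configure a synthetic leaf scene
#'
#' Describes a microscope-like leaf image: a textured green background,
#' `n_eggs` ellipse-shaped whitefly eggs whose colours range from
#' translucent green to brown and whose axis ratio sits near 0.4 (a real
#' egg is ~0.2 mm long by 0.08 mm wide), plus optional distractors —
#' thin bright trichome strands, translucent honeydew discs, small
#' specks, large smears, and locally blurred patches emulating leaf-curl
#' defocus. The default egg bounding-box extents (22 to 88 px) match eggs
#' imaged at roughly 350 px/mm.
#'
#' @param height_px,width_px Canvas size in pixels.
#' @param n_eggs Number of eggs to place.
#' @param egg_major_px Range of the full major-axis length in pixels.
#' @param egg_axis_ratio Range of minor/major axis ratio.
#' @param egg_minor_px Allowed range of the full minor-axis length; the
#'   drawn minor axis is clamped into it.
#' @param min_center_dist_px Minimum distance between egg centers (the
#'   overlap policy; the default keeps eggs disjoint).
#' @param edge_margin_px Extra clearance between an egg's extent and the
#'   canvas edge. When a scene will be quantified through the tiling
#'   pipeline, set this at least to the crop surplus half-width plus a few
#'   pixels so no egg falls in the cropped-away border (a clip-cage
#'   sample sits centrally in a real image for the same reason).
#' @param n_trichomes,n_honeydew,n_specks,n_smears Distractor counts.
#' @param n_blur_patches Number of locally blurred discs.
#' @param blur_radius_px Radius range of blur patches.
#' @param seed Integer seed; a fixed seed gives a bit-identical scene.
#' @return A `scene_config` list.
#' @export
scene_config <- function(height_px = 1600, width_px = 1600, n_eggs = 20,
                         egg_major_px = c(47, 86),
                         egg_axis_ratio = c(0.35, 0.47),
                         egg_minor_px = c(22, 45),
                         min_center_dist_px = 110,
                         edge_margin_px = 4,
                         n_trichomes = 0, n_honeydew = 0,
                         n_specks = 0, n_smears = 0,
                         n_blur_patches = 0,
                         blur_radius_px = c(80, 200),
                         seed = 1L) {
  stopifnot(height_px >= 1, width_px >= 1, n_eggs >= 0,
            all(egg_major_px > 0), all(egg_minor_px > 0),
            all(egg_axis_ratio > 0), all(egg_axis_ratio <= 1))
  structure(as.list(environment()), class = "scene_config")
}

#' Generate the ground truth of a synthetic scene
#'
#' Places eggs by seeded rejection sampling under the minimum
#' center-distance policy, then places distractors. Ground-truth boxes
#' are the exact axis-aligned bounds of each ellipse (floor/ceil to whole
#' pixels, half-open), not dilated.
#'
#' @param config A [scene_config()].
#' @return A `scene_truth`: `eggs` (data.frame of center, semi-axes,
#'   rotation, colour), `truth_boxes` (box table), distractor tables and
#'   the config snapshot.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  h <- config$height_px
  w <- config$width_px
  n <- config$n_eggs
  eggs <- data.frame(cx = numeric(), cy = numeric(), a = numeric(),
                     b = numeric(), theta = numeric(), t_col = numeric())
  if (n > 0) {
    cx <- cy <- a <- b <- theta <- t_col <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n + 1000L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "placement infeasible: placed %d of %d eggs under min center distance %g on a %d x %d canvas",
          placed, n, config$min_center_dist_px, h, w))
      }
      major <- stats::runif(1, config$egg_major_px[1], config$egg_major_px[2])
      ratio <- stats::runif(1, config$egg_axis_ratio[1],
                            config$egg_axis_ratio[2])
      minor <- min(max(major * ratio, config$egg_minor_px[1]),
                   config$egg_minor_px[2])
      margin <- major / 2 + config$edge_margin_px
      x <- stats::runif(1, margin, w - margin)
      y <- stats::runif(1, margin, h - margin)
      if (placed > 0L) {
        dd <- sqrt((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2)
        if (any(dd < config$min_center_dist_px)) next
      }
      placed <- placed + 1L
      cx[placed] <- x
      cy[placed] <- y
      a[placed] <- major / 2
      b[placed] <- minor / 2
      theta[placed] <- stats::runif(1, 0, pi)
      t_col[placed] <- stats::runif(1)
    }
    eggs <- data.frame(cx = cx, cy = cy, a = a, b = b, theta = theta,
                       t_col = t_col)
  }
  # exact axis-aligned half-extents of a rotated ellipse
  ex <- sqrt((eggs$a * cos(eggs$theta))^2 + (eggs$b * sin(eggs$theta))^2)
  ey <- sqrt((eggs$a * sin(eggs$theta))^2 + (eggs$b * cos(eggs$theta))^2)
  truth_boxes <- if (nrow(eggs)) {
    boxes(floor(eggs$cx - ex), floor(eggs$cy - ey),
          ceiling(eggs$cx + ex), ceiling(eggs$cy + ey))
  } else {
    empty_boxes()
  }
  rand_tab <- function(k, gen) if (k > 0) gen(k) else NULL
  trichomes <- rand_tab(config$n_trichomes, function(k) {
    data.frame(x0 = stats::runif(k, 0, w), y0 = stats::runif(k, 0, h),
               angle = stats::runif(k, 0, 2 * pi),
               length = stats::runif(k, 120, 350),
               width = stats::runif(k, 1.5, 3),
               curl = stats::runif(k, -0.01, 0.01))
  })
  honeydew <- rand_tab(config$n_honeydew, function(k) {
    data.frame(cx = stats::runif(k, 0, w), cy = stats::runif(k, 0, h),
               r = stats::runif(k, 15, 60))
  })
  specks <- rand_tab(config$n_specks, function(k) {
    data.frame(cx = stats::runif(k, 10, w - 10),
               cy = stats::runif(k, 10, h - 10),
               r = stats::runif(k, 3, 8))  # diameter < 20 px: size filter prey
  })
  smears <- rand_tab(config$n_smears, function(k) {
    data.frame(cx = stats::runif(k, 60, w - 60),
               cy = stats::runif(k, 60, h - 60),
               rx = stats::runif(k, 50, 90), ry = stats::runif(k, 48, 80))
  })
  blur_patches <- rand_tab(config$n_blur_patches, function(k) {
    data.frame(cx = stats::runif(k, 0, w), cy = stats::runif(k, 0, h),
               r = stats::runif(k, config$blur_radius_px[1],
                               config$blur_radius_px[2]))
  })
  structure(list(eggs = eggs, truth_boxes = truth_boxes,
                 trichomes = trichomes, honeydew = honeydew,
                 specks = specks, smears = smears,
                 blur_patches = blur_patches, config = config),
            class = "scene_truth")
}

# egg colour gradient: translucent green (t = 0) to brown (t = 1)
egg_color <- function(t) {
  green <- c(0.56, 0.62, 0.25)
  brown <- c(0.45, 0.30, 0.15)
  sapply(seq_along(green), function(i) green[i] + t * (brown[i] - green[i]))
}

# Anti-aliased coverage patch of a rotated filled ellipse: returns the
# 1-based row/col index ranges and the per-pixel coverage matrix, or NULL
# when the ellipse misses the canvas. The caller paints the patch in its
# own frame so the (large) canvas array is modified in place rather than
# copied per object.
ellipse_patch <- function(cx, cy, a, b, theta, h, w, alpha = 1,
                          edge_px = 1) {
  ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2) + edge_px + 1
  ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2) + edge_px + 1
  x_lo <- max(1, floor(cx - ex))
  x_hi <- min(w, ceiling(cx + ex))
  y_lo <- max(1, floor(cy - ey))
  y_hi <- min(h, ceiling(cy + ey))
  if (x_lo > x_hi || y_lo > y_hi) return(NULL)
  xs <- x_lo:x_hi
  ys <- y_lo:y_hi
  # pixel centers at index - 0.5 in the 0-based frame
  px <- matrix(xs - 0.5 - cx, nrow = length(ys), ncol = length(xs),
               byrow = TRUE)
  py <- matrix(ys - 0.5 - cy, nrow = length(ys), ncol = length(xs))
  u <- (px * cos(theta) + py * sin(theta)) / a
  v <- (-px * sin(theta) + py * cos(theta)) / b
  rho <- sqrt(u^2 + v^2)
  # soft edge about one pixel wide
  grad <- min(a, b)
  cov <- pmin(pmax((1 - rho) * grad + 0.5, 0), 1) * alpha
  list(ys = ys, xs = xs, cov = cov)
}

# simple separable box blur of a channel matrix
box_blur_mat <- function(m, r = 4L) {
  k <- 2L * r + 1L
  m <- t(apply(m, 1, running_mean, k = k))
  apply(m, 2, running_mean, k = k)
}

running_mean <- function(v, k) {
  n <- length(v)
  if (n < 2L) return(v)
  r <- (k - 1L) %/% 2L
  pad <- c(rep(v[1], r), v, rep(v[n], r))
  cs <- cumsum(pad)
  (cs[(k):(n + k - 1L)] - c(0, cs[seq_len(n - 1L)])) / k
}

#' Render a synthetic scene to pixels
#'
#' Produces the RGB image for a [generate_scene()] truth: textured green
#' background, anti-aliased egg ellipses, thin bright trichome polylines,
#' translucent honeydew discs, dark specks, large pale smears, and local
#' blur patches.
#'
#' @param truth A `scene_truth`.
#' @return Numeric array `height x width x 3` in `[0, 1]`.
#' @export
render_scene <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  cfg <- truth$config
  set.seed(cfg$seed + 101L)
  h <- cfg$height_px
  w <- cfg$width_px
  base <- c(0.20, 0.55, 0.18)
  img <- array(0, c(h, w, 3))
  # leaf texture: per-pixel noise plus a smooth horizontal tint gradient
  tint <- matrix(rep(seq(-0.02, 0.02, length.out = w), each = h), h, w)
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + matrix(stats::runif(h * w, -0.04, 0.04), h, w) +
      tint
  }
  paint <- function(p, color) {
    if (is.null(p)) return(invisible())
    for (ch in 1:3) {
      img[p$ys, p$xs, ch] <<- img[p$ys, p$xs, ch] * (1 - p$cov) +
        color[ch] * p$cov
    }
  }
  if (!is.null(truth$honeydew)) {
    for (i in seq_len(nrow(truth$honeydew))) {
      d <- truth$honeydew[i, ]
      paint(ellipse_patch(d$cx, d$cy, d$r, d$r, 0, h, w, alpha = 0.12),
            c(0.92, 0.90, 0.65))
    }
  }
  if (!is.null(truth$smears)) {
    for (i in seq_len(nrow(truth$smears))) {
      s <- truth$smears[i, ]
      paint(ellipse_patch(s$cx, s$cy, s$rx, s$ry, 0, h, w, alpha = 0.9),
            c(0.50, 0.42, 0.22))
    }
  }
  if (!is.null(truth$specks)) {
    for (i in seq_len(nrow(truth$specks))) {
      s <- truth$specks[i, ]
      paint(ellipse_patch(s$cx, s$cy, s$r, s$r * 0.8,
                          stats::runif(1, 0, pi), h, w),
            c(0.48, 0.34, 0.16))
    }
  }
  for (i in seq_len(nrow(truth$eggs))) {
    e <- truth$eggs[i, ]
    paint(ellipse_patch(e$cx, e$cy, e$a, e$b, e$theta, h, w),
          egg_color(e$t_col))
  }
  if (!is.null(truth$trichomes)) {
    for (i in seq_len(nrow(truth$trichomes))) {
      tr <- truth$trichomes[i, ]
      n_seg <- max(8L, ceiling(tr$length / 6))
      s <- seq(0, tr$length, length.out = n_seg)
      ang <- tr$angle + tr$curl * s
      xs <- tr$x0 + cumsum(c(0, diff(s)) * cos(ang))
      ys <- tr$y0 + cumsum(c(0, diff(s)) * sin(ang))
      for (j in seq_len(n_seg)) {
        paint(ellipse_patch(xs[j], ys[j], 3.5, tr$width / 2, ang[j], h, w),
              c(0.82, 0.88, 0.78))
      }
    }
  }
  if (!is.null(truth$blur_patches)) {
    for (i in seq_len(nrow(truth$blur_patches))) {
      bp <- truth$blur_patches[i, ]
      ys <- max(1, floor(bp$cy - bp$r)):min(h, ceiling(bp$cy + bp$r))
      xs <- max(1, floor(bp$cx - bp$r)):min(w, ceiling(bp$cx + bp$r))
      if (length(ys) > 16 && length(xs) > 16) {
        # two box-blur passes approximate a wide defocus kernel strong
        # enough to pull small eggs below the detector's contrast threshold
        for (ch in 1:3) {
          img[ys, xs, ch] <- box_blur_mat(box_blur_mat(img[ys, xs, ch],
                                                       r = 8L), r = 8L)
        }
      }
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Simulate detections from ground truth without rendering
#'
#' A detector noise model driving evaluation tests: each truth box is
#' jittered by Gaussian noise on all four coordinates, dropped with
#' probability `fn_rate`, and `Poisson(fp_rate * n_truth)` false-positive
#' boxes of egg-like size are added at random positions. Confidences are
#' drawn uniformly from `conf_true` for surviving truth boxes and
#' `conf_false` for false positives. With all defaults the output equals
#' the truth boxes at confidence 1.
#'
#' @param truth A `scene_truth` or a box table of truth boxes.
#' @param jitter_sd Coordinate jitter standard deviation in pixels.
#' @param fp_rate Expected false positives per true object.
#' @param fn_rate Probability of dropping each true box.
#' @param conf_true,conf_false Uniform confidence ranges.
#' @param seed Integer seed.
#' @return A box table of simulated detections.
#' @export
simulate_detections <- function(truth, jitter_sd = 0, fp_rate = 0,
                                fn_rate = 0, conf_true = c(1, 1),
                                conf_false = c(0.3, 0.55), seed = 1L) {
  stopifnot(fp_rate >= 0, fn_rate >= 0, fn_rate <= 1)
  tb <- if (inherits(truth, "scene_truth")) truth$truth_boxes else
    validate_boxes(truth)
  set.seed(seed)
  n <- nrow(tb)
  keep <- if (n) stats::runif(n) >= fn_rate else logical(0)
  det <- tb[keep, , drop = FALSE]
  if (nrow(det)) {
    det$x1 <- pmax(0, det$x1 + stats::rnorm(nrow(det), 0, jitter_sd))
    det$y1 <- pmax(0, det$y1 + stats::rnorm(nrow(det), 0, jitter_sd))
    det$x2 <- pmax(det$x1 + 1, det$x2 + stats::rnorm(nrow(det), 0, jitter_sd))
    det$y2 <- pmax(det$y1 + 1, det$y2 + stats::rnorm(nrow(det), 0, jitter_sd))
    det$confidence <- stats::runif(nrow(det), conf_true[1], conf_true[2])
  }
  n_fp <- if (n > 0 && fp_rate > 0) stats::rpois(1, fp_rate * n) else 0L
  if (n_fp > 0) {
    span_x <- max(tb$x2, 100)
    span_y <- max(tb$y2, 100)
    wdt <- stats::runif(n_fp, 22, 60)
    hgt <- stats::runif(n_fp, 22, 60)
    x1 <- stats::runif(n_fp, 0, span_x - wdt)
    y1 <- stats::runif(n_fp, 0, span_y - hgt)
    fp <- boxes(x1, y1, x1 + wdt, y1 + hgt,
                confidence = stats::runif(n_fp, conf_false[1],
                                          conf_false[2]))
    det <- rbind(det, fp)
  }
  rownames(det) <- NULL
  det
}

#' Write a batch of synthetic scenes to disk
#'
#' Renders `n_images` scenes (seeds `seed`, `seed + 1`, ...) and writes
#' PNG images plus YOLO-dialect and CSV annotations and a JSON manifest.
#'
#' @param config A [scene_config()]; its seed field is overridden per
#'   image.
#' @param n_images Number of scenes.
#' @param seed Base seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_scene_batch <- function(config, n_images, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1L)
    truth <- generate_scene(cfg)
    img <- render_scene(truth)
    stem <- sprintf("scene_%03d", i)
    png_path <- file.path(out_dir, paste0(stem, ".png"))
    write_image(img, png_path)
    write_yolo(truth$truth_boxes, file.path(out_dir, paste0(stem, ".txt")),
               cfg$width_px, cfg$height_px)
    write_boxes_csv(truth$truth_boxes,
                    file.path(out_dir, paste0(stem, ".csv")),
                    image = paste0(stem, ".png"))
    files[[i]] <- list(image = paste0(stem, ".png"),
                       yolo = paste0(stem, ".txt"),
                       csv = paste0(stem, ".csv"),
                       seed = cfg$seed, n_eggs = nrow(truth$truth_boxes))
  }
  manifest <- list(command = "simulate", n_images = n_images,
                   base_seed = seed,
                   config = unclass(config)[setdiff(names(config), "seed")],
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
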