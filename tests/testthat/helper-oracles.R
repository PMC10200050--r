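# Independent oracles used to cross-check the package's exact arithmetic.

# Pixel-rasterization IoU for integer-coordinate boxes on a small canvas:
# counts covered cells directly.
raster_iou <- function(b, canvas = 64L) {
  paint <- function(row) {
    m <- matrix(FALSE, canvas, canvas)
    xs <- (row$x1 + 1):row$x2
    ys <- (row$y1 + 1):row$y2
    m[ys, xs] <- TRUE
    m
  }
  masks <- lapply(seq_len(nrow(b)), function(i) paint(b[i, ]))
  inter <- Reduce(`&`, masks)
  un <- Reduce(`|`, masks)
  if (sum(un) == 0) return(NA_real_)
  sum(inter) / sum(un)
}

random_int_boxes <- function(n, canvas = 64L, min_side = 1L) {
  x1 <- sample.int(canvas - min_side, n)
  y1 <- sample.int(canvas - min_side, n)
  x2 <- vapply(x1, function(a) a + sample.int(canvas - a, 1), numeric(1))
  y2 <- vapply(y1, function(a) a + sample.int(canvas - a, 1), numeric(1))
  boxes(x1, y1, x2, y2)
}

# Independent two-box IoU by inclusion-exclusion (no shared code with
# iou()/iou_matrix()).
oracle_pair_iou <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(0, ix) * max(0, iy)
  area <- function(r) (r[3] - r[1]) * (r[4] - r[2])
  inter / (area(a) + area(b) - inter)
}

# Transitive-closure merge oracle: adjacency where pairwise IoU > thr,
# reachability via boolean matrix powers, envelope per closure class,
# repeated until the box set stabilizes.
oracle_merge <- function(b, thr = 0.5) {
  repeat {
    n <- nrow(b)
    if (n <= 1L) break
    adj <- diag(TRUE, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- oracle_pair_iou(unlist(b[i, 1:4]), unlist(b[j, 1:4]))
        adj[i, j] <- adj[j, i] <- v > thr
      }
    }
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    classes <- unique(apply(reach, 1, function(r) min(which(r))))
    if (length(classes) == n) break
    b <- do.call(rbind, lapply(classes, function(k) {
      g <- b[reach[k, ], , drop = FALSE]
      data.frame(x1 = min(g$x1), y1 = min(g$y1), x2 = max(g$x2),
                 y2 = max(g$y2), confidence = max(g$confidence),
                 label = g$label[1], stringsAsFactors = FALSE)
    }))
  }
  b <- b[order(b$y1, b$x1, b$y2, b$x2), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# Optimal one-to-one assignment tp count by exhaustive enumeration over
# candidate pairs (feasible for <= 6 boxes a side).
oracle_best_tp <- function(truth, pred, thr = 0.5) {
  m <- iou_matrix(truth, pred)
  cand <- which(m > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  best <- 0L
  recurse <- function(k, used_t, used_p, count) {
    best <<- max(best, count)
    if (k > nrow(cand)) return()
    recurse(k + 1L, used_t, used_p, count)
    ti <- cand[k, 1]; pi <- cand[k, 2]
    if (!used_t[ti] && !used_p[pi]) {
      used_t[ti] <- TRUE; used_p[pi] <- TRUE
      recurse(k + 1L, used_t, used_p, count + 1L)
    }
  }
  recurse(1L, logical(nrow(truth)), logical(nrow(pred)), 0L)
  best
}

# A tiny manual scene: background plus explicitly placed eggs, bypassing
# the random placement.
manual_scene <- function(height_px, width_px, eggs, seed = 1L, ...) {
  cfg <- scene_config(height_px = height_px, width_px = width_px,
                      n_eggs = 0, seed = seed, ...)
  truth <- generate_scene(cfg)
  truth$eggs <- eggs
  ex <- sqrt((eggs$a * cos(eggs$theta))^2 + (eggs$b * sin(eggs$theta))^2)
  ey <- sqrt((eggs$a * sin(eggs$theta))^2 + (eggs$b * cos(eggs$theta))^2)
  truth$truth_boxes <- boxes(floor(eggs$cx - ex), floor(eggs$cy - ey),
                             ceiling(eggs$cx + ex), ceiling(eggs$cy + ey))
  truth
}
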