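# Deterministic synthetic OCTA angiogram generator.
#
# Vessels are grown as branching random-walk trees: each branch is a short
# polyline with a per-branch width; at its tip it may split into two thinner
# children. Rasterization produces both a width-dilated pixel mask and a
# one-pixel centerline mask (the two annotation levels of OCTA vessel
# datasets). Rendering places bright vessels on a darker background, applies
# a mild blur and multiplicative speckle, emulating the low-contrast,
# low-SNR character of en-face angiograms. Everything is reproducible from
# (params, seed). Coordinates are row-major with the origin at the top-left.

#' Parameters of the synthetic vessel-tree generator
#'
#' @param n_roots number of root vessels entering from the image border.
#' @param branch_prob probability that a branch tip splits in two.
#' @param max_depth maximum branching generation.
#' @param width_root root vessel width (pixels, diameter).
#' @param width_decay width multiplier applied at each split, in (0, 1].
#' @param step_len random-walk step length in pixels.
#' @param steps_per_branch walk steps per branch segment.
#' @param curvature_sigma std. dev. of the per-step heading change (radians).
#' @param image_size canvas size `c(H, W)`.
#' @return a `vessel_tree_params` list.
#' @export
vessel_tree_params <- function(n_roots = 3L, branch_prob = 0.5, max_depth = 3L,
                               width_root = 4, width_decay = 0.7,
                               step_len = 3, steps_per_branch = 9L,
                               curvature_sigma = 0.25,
                               image_size = c(64L, 64L)) {
  stopifnot(branch_prob >= 0, branch_prob <= 1, width_decay > 0,
            width_decay <= 1, n_roots >= 0, max_depth >= 1)
  structure(list(n_roots = as.integer(n_roots), branch_prob = branch_prob,
                 max_depth = as.integer(max_depth), width_root = width_root,
                 width_decay = width_decay, step_len = step_len,
                 steps_per_branch = as.integer(steps_per_branch),
                 curvature_sigma = curvature_sigma,
                 image_size = as.integer(image_size)),
            class = "vessel_tree_params")
}

#' Grow a branching vessel tree
#'
#' Roots start on the image border heading inward; each branch is a curved
#' random walk that may split into two thinner children at its tip (so a tree
#' of depth d holds at most `2^d - 1` branches per root).
#'
#' @param params a [vessel_tree_params()].
#' @param rng_seed integer seed; the tree is a pure function of
#'   (params, seed).
#' @return list of segments, each `list(points = n x 2 matrix of (row, col),
#'   width, depth)`.
#' @export
grow_tree <- function(params, rng_seed) {
  set.seed(as.integer(rng_seed))
  H <- params$image_size[1L]; W <- params$image_size[2L]
  segs <- list()
  if (params$n_roots == 0L) return(segs)

  walk_branch <- function(start, heading, width, depth) {
    pts <- matrix(0, params$steps_per_branch + 1L, 2L)
    pts[1L, ] <- start
    pos <- start
    for (s in seq_len(params$steps_per_branch)) {
      heading <- heading + stats::rnorm(1L, 0, params$curvature_sigma)
      pos <- pos + params$step_len * c(sin(heading), cos(heading))
      # reflect walks at the canvas border so trees stay in frame
      if (pos[1L] < 1) { pos[1L] <- 2 - pos[1L]; heading <- -heading }
      else if (pos[1L] > H) { pos[1L] <- 2 * H - pos[1L]; heading <- -heading }
      if (pos[2L] < 1) { pos[2L] <- 2 - pos[2L]; heading <- pi - heading }
      else if (pos[2L] > W) { pos[2L] <- 2 * W - pos[2L]; heading <- pi - heading }
      pts[s + 1L, ] <- pos
    }
    segs[[length(segs) + 1L]] <<- list(points = pts, width = width,
                                       depth = depth)
    if (depth < params$max_depth &&
        stats::runif(1L) < params$branch_prob &&
        pos[1L] > -H / 4 && pos[1L] < 5 * H / 4 &&
        pos[2L] > -W / 4 && pos[2L] < 5 * W / 4) {
      split <- stats::runif(1L, 0.3, 0.8)
      cw <- max(1, width * params$width_decay)
      walk_branch(pos, heading - split, cw, depth + 1L)
      walk_branch(pos, heading + split, cw, depth + 1L)
    }
  }

  for (r in seq_len(params$n_roots)) {
    edge <- sample.int(4L, 1L)
    t <- stats::runif(1L, 0.15, 0.85)
    start <- switch(edge,
                    c(1, t * W),        # top, heading down
                    c(H, t * W),        # bottom, heading up
                    c(t * H, 1),        # left, heading right
                    c(t * H, W))        # right, heading left
    heading <- switch(edge, 0, pi, pi / 2, -pi / 2) +
      stats::rnorm(1L, 0, 0.3)
    walk_branch(start, heading, params$width_root, 1L)
  }
  segs
}

disk_offsets <- function(radius) {
  r <- max(0, radius)
  ri <- floor(r)
  grid <- expand.grid(di = -ri:ri, dj = -ri:ri)
  keep <- grid$di^2 + grid$dj^2 <= r^2 + 1e-9
  cbind(grid$di[keep], grid$dj[keep])
}

#' Rasterize a vessel tree into pixel and centerline masks
#'
#' The pixel mask is the union of width-dilated strokes; the centerline mask
#' marks the one-pixel polyline trace. The centerline is OR-ed into the pixel
#' mask so containment holds by construction.
#'
#' @param tree output of [grow_tree()].
#' @param image_size canvas size `c(H, W)`; strokes are clipped to it.
#' @return list `pixel_mask`, `centerline_mask` (0/1 integer matrices).
#' @export
rasterize <- function(tree, image_size) {
  H <- image_size[1L]; W <- image_size[2L]
  pm <- matrix(0L, H, W)
  cm <- matrix(0L, H, W)
  for (seg in tree) {
    pts <- seg$points
    offs <- disk_offsets(seg$width / 2)
    for (s in seq_len(nrow(pts) - 1L)) {
      a <- pts[s, ]; b <- pts[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      nsub <- max(2L, ceiling(len / 0.4))
      ts <- seq(0, 1, length.out = nsub)
      rr <- round(a[1L] + ts * (b[1L] - a[1L]))
      cc <- round(a[2L] + ts * (b[2L] - a[2L]))
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      if (any(ok)) cm[cbind(rr[ok], cc[ok])] <- 1L
      for (u in seq_len(nrow(offs))) {
        r2 <- rr + offs[u, 1L]; c2 <- cc + offs[u, 2L]
        ok2 <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
        if (any(ok2)) pm[cbind(r2[ok2], c2[ok2])] <- 1L
      }
    }
  }
  pm[cm == 1L] <- 1L
  list(pixel_mask = pm, centerline_mask = cm)
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2 * sigma))
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad <- function(m, k) m[pmin(pmax(seq_len(nrow(m) + 2 * k) - k, 1), nrow(m)), ,
                          drop = FALSE]
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H, W)
  xp <- pad(img, r)
  for (i in seq_along(kern)) tmp <- tmp + kern[i] * xp[(i - 1) + seq_len(H), ]
  out <- matrix(0, H, W)
  xp <- t(pad(t(tmp), r))
  for (i in seq_along(kern)) out <- out + kern[i] * xp[, (i - 1) + seq_len(W)]
  out
}

#' Render an angiogram image from a vessel mask
#'
#' Vessels at `background + contrast`, background at `background`, mild
#' Gaussian blur, multiplicative speckle `1 + noise_level * N(0,1)`, clipped
#' to `[0, 1]`. With `noise_level = 0` and `blur_sigma = 0` the image is
#' exactly two-valued.
#'
#' @param pixel_mask binary vessel mask.
#' @param rng_seed integer seed for the speckle.
#' @param contrast vessel-over-background intensity lift.
#' @param noise_level speckle amplitude.
#' @param background background intensity.
#' @param blur_sigma Gaussian blur std. dev. in pixels (0 disables).
#' @return image matrix in `[0, 1]`.
#' @export
render_angiogram <- function(pixel_mask, rng_seed, contrast = 0.5,
                             noise_level = 0.25, background = 0.15,
                             blur_sigma = 0.7) {
  set.seed(as.integer(rng_seed))
  img <- background + contrast * (pixel_mask > 0)
  img <- gauss_blur(img, blur_sigma)
  if (noise_level > 0) {
    img <- img * (1 + noise_level * stats::rnorm(length(img)))
  }
  matrix(pmin(pmax(img, 0), 1), nrow(pixel_mask), ncol(pixel_mask))
}

#' Generate one synthetic sample
#'
#' @param params a [vessel_tree_params()].
#' @param seed integer seed controlling tree, rasterization and rendering.
#' @param ... passed to [render_angiogram()].
#' @return list `image`, `pixel_mask`, `centerline_mask`, `seed`.
#' @export
synthetic_sample <- function(params, seed, ...) {
  tree <- grow_tree(params, seed)
  masks <- rasterize(tree, params$image_size)
  img <- render_angiogram(masks$pixel_mask, seed + 1L, ...)
  list(image = img, pixel_mask = masks$pixel_mask,
       centerline_mask = masks$centerline_mask, seed = as.integer(seed))
}

#' Write a synthetic train/test dataset to disk
#'
#' Produces the standard OCTA layout: `train/img`, `train/gt`,
#' `train/gt_centerline` and the same under `test/`, as 8-bit grayscale PNGs,
#' plus `manifest.json` recording the per-sample seeds and parameters.
#'
#' @param n_train,n_test sample counts.
#' @param params a [vessel_tree_params()].
#' @param base_seed root seed; sample i uses `base_seed + 101 * i`.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
make_dataset <- function(n_train, n_test, params, base_seed, out_dir) {
  splits <- list(train = n_train, test = n_test)
  idx <- 0L
  manifest <- list(base_seed = as.integer(base_seed),
                   params = unclass(params), samples = list())
  for (split in names(splits)) {
    for (sub in c("img", "gt", "gt_centerline")) {
      dir.create(file.path(out_dir, split, sub), recursive = TRUE,
                 showWarnings = FALSE)
    }
    if (!dir.exists(file.path(out_dir, split, "img"))) {
      stop("make_dataset: cannot create output directory ", out_dir)
    }
    for (i in seq_len(splits[[split]])) {
      idx <- idx + 1L
      seed_i <- as.integer(base_seed) + 101L * idx
      smp <- synthetic_sample(params, seed_i)
      stem <- sprintf("%03d.png", idx)
      png::writePNG(smp$image, file.path(out_dir, split, "img", stem))
      png::writePNG(smp$pixel_mask + 0, file.path(out_dir, split, "gt", stem))
      png::writePNG(smp$centerline_mask + 0,
                    file.path(out_dir, split, "gt_centerline", stem))
      manifest$samples[[length(manifest$samples) + 1L]] <-
        list(split = split, file = stem, seed = seed_i)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
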