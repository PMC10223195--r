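# Dataset readers/writers and run configuration files.
#
# Directory layout (the common OCTA distribution shape):
#   root/{train,test}/img/*.png          grayscale angiograms
#   root/{train,test}/gt/*.png           pixel-level masks
#   root/{train,test}/gt_centerline/*.png  optional centerline masks
# Images and masks pair by filename stem.

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Load a paired image/mask dataset split
#'
#' Images are scaled to `[0, 1]`; masks binarized at `> 0`. Unpaired files on
#' either side are an error, listed explicitly.
#'
#' @param root dataset root directory.
#' @param split `"train"` or `"test"`.
#' @param with_centerline also load `gt_centerline` masks when present.
#' @return list of samples `list(image, pixel_mask, centerline_mask?, name)`.
#' @export
load_dataset <- function(root, split = "train", with_centerline = FALSE) {
  img_dir <- file.path(root, split, "img")
  gt_dir <- file.path(root, split, "gt")
  if (!dir.exists(img_dir) || !dir.exists(gt_dir)) {
    stop("load_dataset: missing img/ or gt/ under ", file.path(root, split))
  }
  imgs <- sort(list.files(img_dir, pattern = "\\.png$"))
  gts <- sort(list.files(gt_dir, pattern = "\\.png$"))
  orphans <- c(setdiff(imgs, gts), setdiff(gts, imgs))
  if (length(orphans) > 0L) {
    stop("load_dataset: unpaired files: ", paste(orphans, collapse = ", "))
  }
  cl_dir <- file.path(root, split, "gt_centerline")
  lapply(imgs, function(f) {
    s <- list(image = read_gray_png(file.path(img_dir, f)),
              pixel_mask = (read_gray_png(file.path(gt_dir, f)) > 0) + 0L,
              name = sub("\\.png$", "", f))
    if (with_centerline && file.exists(file.path(cl_dir, f))) {
      s$centerline_mask <- (read_gray_png(file.path(cl_dir, f)) > 0) + 0L
    }
    s
  })
}

# --- 16-bit grayscale PNG writer -------------------------------------------
# Probability maps need 16-bit depth; the installed PNG bindings write 8-bit
# only, so the container is assembled directly: IHDR/IDAT/IEND chunks with a
# zlib stream of stored (uncompressed) deflate blocks. readPNG reads the
# result natively.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320 as signed int
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(bitwAnd(c, -256L), 8L))
  }
  bitwXor(c, -1L)
}

u32_bytes <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- as.numeric(crc32(body)) %% 2^32
  c(u32_bytes(length(data)), body, u32_bytes(crc))
}

zlib_stored <- function(data) {
  n <- length(data)
  blocks <- raw(0)
  pos <- 1L
  repeat {
    len <- min(65535L, n - pos + 1L)
    final <- if (pos + len - 1L >= n) as.raw(1L) else as.raw(0L)
    blocks <- c(blocks, final,
                as.raw(c(len %% 256L, len %/% 256L,
                         255L - len %% 256L, 255L - len %/% 256L)),
                data[pos:(pos + len - 1L)])
    pos <- pos + len
    if (pos > n) break
  }
  # adler32 over the uncompressed data
  v <- as.integer(data)
  a <- 1; b <- 0
  # process in chunks to stay in exact double arithmetic
  for (i in seq(1L, length(v), by = 3000L)) {
    seg <- v[i:min(i + 2999L, length(v))]
    ca <- cumsum(seg)
    b <- (b + length(seg) * a + sum(ca)) %% 65521
    a <- (a + ca[length(ca)]) %% 65521
  }
  c(as.raw(c(0x78, 0x01)), blocks, u32_bytes(b * 65536 + a))
}

write_png16_gray <- function(mat, path) {
  H <- nrow(mat); W <- ncol(mat)
  vals <- round(pmin(pmax(mat, 0), 1) * 65535)
  hi <- as.raw(t(vals) %/% 256)
  lo <- as.raw(t(vals) %% 256)
  inter <- as.vector(rbind(hi, lo))          # big-endian 16-bit, row-major
  scan <- matrix(inter, nrow = 2L * W)
  idat <- as.raw(unlist(lapply(seq_len(H), function(r) {
    c(as.raw(0L), scan[, r])                 # filter byte 0 per scanline
  })))
  ihdr <- c(u32_bytes(W), u32_bytes(H),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib_stored(idat)), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Save a prediction as probability and binary-mask PNGs
#'
#' Writes a 16-bit probability map to `path` and the thresholded 8-bit binary
#' mask alongside (suffix `_mask`).
#'
#' @param score_map probability matrix in `[0, 1]`.
#' @param path output PNG path.
#' @param threshold binarization threshold for the companion mask.
#' @return paths of the two files, invisibly.
#' @export
save_prediction <- function(score_map, path, threshold = 0.5) {
  if (any(score_map < 0 | score_map > 1)) {
    stop("save_prediction: scores must lie in [0, 1]")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_png16_gray(as.matrix(score_map), path)
  mask_path <- sub("\\.png$", "_mask.png", path)
  png::writePNG((score_map >= threshold) + 0, mask_path)
  invisible(c(path, mask_path))
}

config_to_list <- function(model_cfg, train_cfg = NULL) {
  att <- model_cfg$attention
  out <- list(model = list(variant = model_cfg$variant,
                           in_channels = model_cfg$in_channels,
                           num_classes = model_cfg$num_classes,
                           base_width = model_cfg$base_width,
                           channel_widths = model_cfg$channel_widths),
              attention = list(num_heads = att$num_heads,
                               reduction_factor = att$reduction_factor,
                               reduction_mode = att$reduction_mode))
  if (!is.null(train_cfg)) {
    out$train <- list(epochs = train_cfg$epochs, lr = train_cfg$lr,
                      weight_decay = train_cfg$weight_decay,
                      batch_size = train_cfg$batch_size,
                      poly_power = train_cfg$poly_power,
                      rotation_deg = train_cfg$rotation_deg,
                      augment = train_cfg$augment, seed = train_cfg$seed)
  }
  out
}

#' Write a run configuration to a YAML file
#'
#' @param model_cfg a [model_config()].
#' @param train_cfg optional [train_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(model_cfg, train_cfg = NULL, path) {
  yaml::write_yaml(config_to_list(model_cfg, train_cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with `model`, `attention` and optional `train`
#'   sections.
#' @return list with `model` ([model_config()]) and `train`
#'   ([train_config()] or `NULL`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  att <- do.call(attention_config, y$attention %||% list())
  m <- y$model %||% list()
  mc <- model_config(variant = m$variant %||% "full",
                     in_channels = m$in_channels %||% 1L,
                     num_classes = m$num_classes %||% 1L,
                     base_width = m$base_width %||% 32L,
                     channel_widths = unlist(m$channel_widths),
                     attention = att)
  tc <- if (!is.null(y$train)) {
    yt <- y$train
    train_config(epochs = yt$epochs %||% 50L, lr = yt$lr %||% 6e-4,
                 weight_decay = yt$weight_decay %||% 1e-4,
                 batch_size = yt$batch_size %||% 2L,
                 poly_power = yt$poly_power %||% 0.9,
                 rotation_deg = unlist(yt$rotation_deg) %||% c(-10, 10),
                 augment = yt$augment %||% TRUE, seed = yt$seed %||% 1L)
  }
  list(model = mc, train = tc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
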