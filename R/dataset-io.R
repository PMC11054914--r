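#' Convert an RGB image to normalized grayscale
#'
#' Applies the BT.601 luma weights (0.299, 0.587, 0.114) and scales the
#' result to \[0, 1\]. Channel values may be 8-bit codes (0-255) or already
#' normalized to \[0, 1\] (as returned by [png::readPNG()]); the scale is
#' detected from the data maximum.
#'
#' @param rgb_image A height x width x 3 numeric array.
#' @return A height x width matrix of intensities in \[0, 1\].
#' @export
#' @examples
#' px <- array(c(100, 150, 200) / 255, dim = c(1, 1, 3))
#' to_grayscale(px)
to_grayscale <- function(rgb_image) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] != 3) {
    pg_stop("expected a 3-channel (height x width x 3) image", "format")
  }
  scale <- if (max(rgb_image) > 1) 255 else 1
  g <- (0.299 * rgb_image[, , 1] + 0.587 * rgb_image[, , 2] +
          0.114 * rgb_image[, , 3]) / scale
  pmin(pmax(g, 0), 1)
}

#' Resize a grayscale image by bilinear interpolation
#'
#' @param img A height x width matrix with intensities in \[0, 1\].
#' @param out_w,out_h Target size in pixels (>= 1).
#' @return The resized matrix, clipped to \[0, 1\]. A same-size resize
#'   returns the input unchanged.
#' @export
resize_image <- function(img, out_w, out_h) {
  if (out_w < 1 || out_h < 1) pg_stop("target size must be positive", "size")
  if (out_w == ncol(img) && out_h == nrow(img)) return(img)
  # EBImage stores images as (x, y); transpose in and out
  res <- EBImage::resize(t(img), w = out_w, h = out_h, filter = "bilinear")
  out <- t(as.matrix(res))
  pmin(pmax(out, 0), 1)
}

#' Rescale a pupil annotation to a new image size
#'
#' Coordinates are multiplied by the per-axis size ratios, rounded to the
#' nearest integer (ties toward +Inf) and clipped into the target bounds,
#' so labels follow the image through a resize.
#'
#' @param ann Named vector `c(cx, cy)` (0-based pixels).
#' @param in_size,out_size `c(width, height)` pairs.
#' @return Named integer vector `c(cx, cy)` valid for `out_size`.
#' @export
#' @examples
#' scale_annotation(c(cx = 100, cy = 50), c(640, 480), c(320, 240))
scale_annotation <- function(ann, in_size, out_size) {
  cx <- round_half_up(ann[["cx"]] * out_size[1] / in_size[1])
  cy <- round_half_up(ann[["cy"]] * out_size[2] / in_size[2])
  c(cx = as.integer(min(max(cx, 0), out_size[1] - 1)),
    cy = as.integer(min(max(cy, 0), out_size[2] - 1)))
}

#' Crop the central window of an image
#'
#' Returns the centered `out_w` x `out_h` window together with the
#' `(dx, dy)` offset of its top-left corner, so annotations can be shifted
#' by `ann - offset`. Odd margins are split with the extra pixel on the
#' bottom/right (tie toward the top-left).
#'
#' @param img A height x width matrix.
#' @param out_w,out_h Target size; must not exceed the source size.
#' @return A list with `image` and `offset = c(dx, dy)`.
#' @export
crop_center <- function(img, out_w, out_h) {
  h <- nrow(img)
  w <- ncol(img)
  if (out_w > w || out_h > h) {
    pg_stop("crop window larger than the source image", "size")
  }
  dx <- floor((w - out_w) / 2)
  dy <- floor((h - out_h) / 2)
  list(image = img[(dy + 1):(dy + out_h), (dx + 1):(dx + out_w),
                   drop = FALSE],
       offset = c(dx = as.integer(dx), dy = as.integer(dy)))
}

#' Map a pupil position to its position class
#'
#' The low-resolution classifier assigns one class per pixel, numbered
#' row-major from 1: class 1 is the top-left corner, class 2 the first row
#' / second column, and class `width * height` the bottom-right corner.
#'
#' @param cx,cy 0-based pixel coordinates (vectors allowed).
#' @param width,height Grid size in pixels.
#' @return Integer class indices (1-based).
#' @export
#' @examples
#' coord_to_class(0, 0, 20, 15)   # 1
#' coord_to_class(9, 7, 20, 15)   # 150, the central class of a 20x15 grid
coord_to_class <- function(cx, cy, width, height) {
  if (any(cx < 0 | cx >= width | cy < 0 | cy >= height)) {
    pg_stop("annotation outside the class grid", "range")
  }
  as.integer(cy) * as.integer(width) + as.integer(cx) + 1L
}

#' Inverse of [coord_to_class()]
#'
#' @param class_index 1-based class indices (vector allowed).
#' @param width,height Grid size in pixels.
#' @return A tibble with integer columns `cx`, `cy`.
#' @export
#' @examples
#' class_to_coord(300, 20, 15)  # bottom-right corner (19, 14)
class_to_coord <- function(class_index, width, height) {
  if (any(class_index < 1 | class_index > width * height)) {
    pg_stop("class index out of range", "range")
  }
  i0 <- as.integer(class_index) - 1L
  tibble(cx = i0 %% as.integer(width), cy = i0 %/% as.integer(width))
}

#' Write a labeled dataset to disk
#'
#' Writes each image as an 8-bit grayscale PNG (`img_00001.png`, ...) plus
#' a `labels.csv` sidecar with columns `filename, cx, cy, width, height,
#' profile, seed`.
#'
#' @param samples A dataset tibble as returned by [generate_dataset()] or
#'   [load_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(samples, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(samples)
  fns <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(samples$image[[i]], file.path(path, fns[i]))
  }
  seed <- attr(samples, "pg_seed") %||% NA_integer_
  labels <- tibble(
    filename = fns,
    cx = samples$cx, cy = samples$cy,
    width = samples$width, height = samples$height,
    profile = samples$source_tag,
    seed = as.integer(seed)
  )
  readr::write_csv(labels, file.path(path, "labels.csv"))
  invisible(path)
}

#' Read a labeled dataset from disk
#'
#' Loads `labels.csv` and the PNG files it references. Every labeled file
#' must exist and every PNG in the directory must be labeled; a mismatch
#' raises a consistency error naming the offending file. Color PNGs are
#' converted with [to_grayscale()].
#'
#' @param path Dataset directory containing `labels.csv`.
#' @return A dataset tibble (`image`, `cx`, `cy`, `width`, `height`,
#'   `source_tag`).
#' @export
load_dataset <- function(path) {
  lf <- file.path(path, "labels.csv")
  if (!file.exists(lf)) {
    pg_stop(paste0("no labels.csv in ", path), "io")
  }
  labels <- readr::read_csv(lf, show_col_types = FALSE)
  need <- c("filename", "cx", "cy", "width", "height")
  if (!all(need %in% names(labels))) {
    pg_stop("labels.csv is missing required columns", "format")
  }
  pngs <- list.files(path, pattern = "\\.png$")
  extra <- setdiff(pngs, labels$filename)
  if (length(extra) > 0) {
    pg_stop(paste0("unlabeled image file: ", extra[1]), "consistency")
  }
  missing <- setdiff(labels$filename, pngs)
  if (length(missing) > 0) {
    pg_stop(paste0("labels.csv references absent file: ", missing[1]),
            "consistency")
  }
  images <- purrr::map(labels$filename, function(fn) {
    im <- png::readPNG(file.path(path, fn))
    if (length(dim(im)) == 3) {
      im <- if (dim(im)[3] >= 3) to_grayscale(im[, , 1:3]) else im[, , 1]
    }
    im
  })
  for (i in seq_len(nrow(labels))) {
    if (labels$cx[i] < 0 || labels$cx[i] >= labels$width[i] ||
        labels$cy[i] < 0 || labels$cy[i] >= labels$height[i]) {
      pg_stop(paste0("annotation out of bounds for ", labels$filename[i]),
              "consistency")
    }
  }
  tibble(
    image = images,
    cx = as.integer(labels$cx), cy = as.integer(labels$cy),
    width = as.integer(labels$width), height = as.integer(labels$height),
    source_tag = if ("profile" %in% names(labels))
      as.character(labels$profile) else "unknown"
  )
}
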