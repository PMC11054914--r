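#' Difficulty presets for the synthetic eye renderer
#'
#' A difficulty profile maps every scene parameter to a sampling range.
#' Three presets are provided:
#'
#' * `"easy"`: pupil and iris well inside the frame, no occluders, no
#'   illumination gradient, sensor noise sd at most 0.02, glints kept off
#'   the pupil. Under this profile the pupil is guaranteed to be the
#'   darkest structure in the image (dark-pupil regime).
#' * `"realistic"`: mild illumination gradients, up to three glints, up to
#'   two eyelash-like dark strokes, partial upper-eyelid coverage.
#' * `"hard"`: pupils allowed at the image border, glints that may sit on
#'   the pupil boundary, occluders that may cross the pupil, strong
#'   gradients and noise sd up to 0.08.
#'
#' All geometric ranges are expressed as fractions of `min(width, height)`
#' so the same profile scales from 20x15 thumbnails to 320x240 frames.
#'
#' @param name One of `"easy"`, `"realistic"`, `"hard"`.
#' @return A `difficulty_profile` object (a named list of ranges).
#' @export
#' @examples
#' difficulty_profile("easy")$n_occluders
difficulty_profile <- function(name = c("easy", "realistic", "hard")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    pupil_a = c(0.08, 0.16),      # semi-major axis, fraction of min dim
    axis_ratio = c(0.70, 1.00),   # b / a, off-axis ellipticity
    pupil_int = c(0.02, 0.10),
    iris_int = c(0.35, 0.55),
    sclera_int = c(0.75, 0.95),
    iris_scale = c(2.2, 3.2),     # iris radius as multiple of pupil a
    glint_r = c(0.012, 0.030),    # glint sd, fraction of min dim
    glint_int = c(0.60, 0.95),
    occ_int = c(0.05, 0.20),
    occ_thick = c(0.008, 0.020)
  )
  extra <- switch(name,
    easy = list(
      margin = 0.05, n_glints = 0:2, glints_on_pupil = FALSE,
      n_occluders = 0L, occluders_cross_pupil = FALSE,
      grad_strength = c(0, 0), noise_sd = c(0.005, 0.02),
      eyelid = c(0, 0)
    ),
    realistic = list(
      margin = 0.02, n_glints = 0:3, glints_on_pupil = FALSE,
      n_occluders = 0:2, occluders_cross_pupil = FALSE,
      grad_strength = c(0, 0.15), noise_sd = c(0.01, 0.04),
      eyelid = c(0, 0.15)
    ),
    hard = list(
      margin = 0.0, n_glints = 1:4, glints_on_pupil = TRUE,
      n_occluders = 1:3, occluders_cross_pupil = TRUE,
      grad_strength = c(0.1, 0.3), noise_sd = c(0.02, 0.08),
      eyelid = c(0, 0.3)
    )
  )
  structure(c(base, extra), class = "difficulty_profile")
}

as_profile <- function(profile) {
  if (inherits(profile, "difficulty_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1) {
    return(difficulty_profile(profile))
  }
  pg_stop("`profile` must be a difficulty_profile or a preset name", "config")
}

runifr <- function(r) runif(1, r[1], r[2])

#' Sample the parameters of one synthetic eye scene
#'
#' Draws a full scene description (pupil ellipse, iris, intensities, glints,
#' occluders, illumination and noise) from the ranges of a difficulty
#' profile. The draw is fully determined by `rng_seed`, the profile and the
#' image size; the session RNG state is not consumed.
#'
#' @param rng_seed Integer seed for this scene.
#' @param profile A [difficulty_profile()] or preset name.
#' @param width,height Image size in pixels; at least 20x15.
#' @return A `scene_params` list. Coordinates are 0-based pixels with
#'   x = column and y = row, origin at the top-left.
#' @export
#' @examples
#' sc <- sample_scene(7, "easy", 320, 240)
#' sc$pupil_center
sample_scene <- function(rng_seed, profile, width, height) {
  if (width < 20 || height < 15) {
    pg_stop("image size must be at least 20x15 pixels", "size")
  }
  prof <- as_profile(profile)
  m <- min(width, height)
  with_seed(rng_seed, {
    lo_x <- prof$margin * (width - 1)
    lo_y <- prof$margin * (height - 1)
    cx <- runif(1, lo_x, (width - 1) - lo_x)
    cy <- runif(1, lo_y, (height - 1) - lo_y)
    a <- runifr(prof$pupil_a) * m
    b <- a * runifr(prof$axis_ratio)
    ang <- runif(1, 0, pi)
    p_int <- runifr(prof$pupil_int)
    i_int <- runifr(prof$iris_int)
    s_int <- runifr(prof$sclera_int)
    iris_r <- a * runifr(prof$iris_scale)

    n_g <- if (length(prof$n_glints) == 1) prof$n_glints else
      sample(prof$n_glints, 1)
    glints <- list()
    if (n_g > 0) {
      for (i in seq_len(n_g)) {
        th <- runif(1, 0, 2 * pi)
        dist <- if (prof$glints_on_pupil) {
          b * runif(1, 0.7, 1.3)            # on or near the pupil boundary
        } else {
          a * runif(1, 1.5, 2.5) + 2        # out on the iris / sclera
        }
        glints[[i]] <- list(
          x = min(max(cx + dist * cos(th), 0), width - 1),
          y = min(max(cy + dist * sin(th), 0), height - 1),
          radius = max(runifr(prof$glint_r) * m, 0.5),
          intensity = runifr(prof$glint_int)
        )
      }
    }

    n_o <- if (length(prof$n_occluders) == 1) prof$n_occluders else
      sample(prof$n_occluders, 1)
    occluders <- list()
    if (n_o > 0) {
      for (i in seq_len(n_o)) {
        if (prof$occluders_cross_pupil && runif(1) < 0.5) {
          # lash falling across the pupil
          x0 <- cx + runif(1, -a, a)
          y0 <- max(cy - iris_r, 0)
          xs <- x0 + cumsum(c(0, runif(3, -0.08, 0.08) * m))
          ys <- y0 + cumsum(c(0, runif(3, 0.15, 0.4) * m))
        } else {
          x0 <- runif(1, 0, width - 1)
          y0 <- runif(1, 0, 0.25 * (height - 1))
          xs <- x0 + cumsum(c(0, runif(3, -0.12, 0.12) * m))
          ys <- y0 + cumsum(c(0, runif(3, 0.1, 0.3) * m))
        }
        occluders[[i]] <- list(
          type = "polyline",
          pts = cbind(x = xs, y = ys),
          thickness = max(runifr(prof$occ_thick) * m, 0.6),
          intensity = runifr(prof$occ_int)
        )
      }
    }

    g_str <- runifr(prof$grad_strength)
    g_dir <- if (g_str > 0) {
      v <- c(runif(1, -1, 1), runif(1, -1, 1))
      n <- sqrt(sum(v^2))
      if (n < 1e-9) c(1, 0) else v / n
    } else c(0, 0)

    scene <- list(
      width = as.integer(width), height = as.integer(height),
      pupil_center = c(cx = cx, cy = cy),
      pupil_axes = c(a = a, b = b),
      pupil_angle = ang,
      pupil_intensity = p_int,
      iris_radius = iris_r,
      iris_intensity = i_int,
      sclera_intensity = s_int,
      glints = glints,
      occluders = occluders,
      illumination_gradient = c(gx = g_dir[1], gy = g_dir[2],
                                strength = g_str),
      noise_sd = runifr(prof$noise_sd),
      eyelid_coverage = runifr(prof$eyelid),
      eyelid_intensity = runif(1, 0.20, 0.40),
      noise_seed = sample.int(.Machine$integer.max, 1),
      profile = prof$name
    )
    class(scene) <- "scene_params"
    validate_scene(scene)
    scene
  })
}

validate_scene <- function(scene) {
  ctr <- scene$pupil_center
  if (ctr["cx"] < 0 || ctr["cx"] >= scene$width ||
      ctr["cy"] < 0 || ctr["cy"] >= scene$height) {
    pg_stop("pupil center outside the image", "range")
  }
  if (any(scene$pupil_axes <= 0)) pg_stop("pupil axes must be > 0", "config")
  ints <- c(scene$pupil_intensity, scene$iris_intensity,
            scene$sclera_intensity)
  if (any(ints < 0 | ints > 1)) {
    pg_stop("intensities must lie in [0, 1]", "config")
  }
  if (!(scene$pupil_intensity < scene$iris_intensity &&
        scene$iris_intensity < scene$sclera_intensity)) {
    pg_stop("dark-pupil ordering pupil < iris < sclera violated", "config")
  }
  invisible(scene)
}

# soft-edged coverage of an ellipse: ~1 inside, ~0 outside, linear ramp of
# about one pixel at the boundary
ellipse_alpha <- function(xg, yg, cx, cy, a, b, angle) {
  dx <- xg - cx
  dy <- yg - cy
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  e <- sqrt((u / a)^2 + (v / b)^2)
  pmin(pmax((1 - e) * min(a, b) + 0.5, 0), 1)
}

seg_dist <- function(xg, yg, x1, y1, x2, y2) {
  vx <- x2 - x1
  vy <- y2 - y1
  len2 <- vx^2 + vy^2
  if (len2 < 1e-12) {
    return(sqrt((xg - x1)^2 + (yg - y1)^2))
  }
  t <- pmin(pmax(((xg - x1) * vx + (yg - y1) * vy) / len2, 0), 1)
  sqrt((xg - x1 - t * vx)^2 + (yg - y1 - t * vy)^2)
}

#' Render a synthetic infrared-style eye image
#'
#' Rasterizes a scene sampled by [sample_scene()] into a grayscale image:
#' sclera background, iris disc, anti-aliased elliptical pupil (the darkest
#' structure), additive Gaussian glints, dark eyelash strokes, an upper
#' eyelid band, a linear illumination gradient and additive Gaussian sensor
#' noise, finally clipped to \[0, 1\]. Rendering is bit-reproducible: the
#' noise stream is seeded from the scene itself.
#'
#' @param scene A `scene_params` object.
#' @param width,height Output size; must match the size the scene was
#'   sampled for.
#' @return A list with `image` (height x width matrix in \[0,1\]) and
#'   `annotation` (named integer vector `c(cx, cy)`, the pupil-center
#'   parameter rounded to the nearest pixel).
#' @export
#' @examples
#' sc <- sample_scene(1, "easy", 20, 15)
#' out <- render_eye(sc, 20, 15)
#' dim(out$image)
render_eye <- function(scene, width = scene$width, height = scene$height) {
  validate_scene(scene)
  if (width != scene$width || height != scene$height) {
    pg_stop("requested size differs from the size the scene was sampled for",
            "size")
  }
  xg <- matrix(0:(width - 1), height, width, byrow = TRUE)
  yg <- matrix(0:(height - 1), height, width)
  cx <- scene$pupil_center[["cx"]]
  cy <- scene$pupil_center[["cy"]]
  a <- scene$pupil_axes[["a"]]
  b <- scene$pupil_axes[["b"]]

  img <- matrix(scene$sclera_intensity, height, width)
  al_iris <- ellipse_alpha(xg, yg, cx, cy, scene$iris_radius,
                           scene$iris_radius, 0)
  img <- img * (1 - al_iris) + scene$iris_intensity * al_iris
  al_pup <- ellipse_alpha(xg, yg, cx, cy, a, b, scene$pupil_angle)
  img <- img * (1 - al_pup) + scene$pupil_intensity * al_pup

  for (g in scene$glints) {
    img <- img + g$intensity *
      exp(-((xg - g$x)^2 + (yg - g$y)^2) / (2 * g$radius^2))
  }
  for (oc in scene$occluders) {
    pts <- oc$pts
    for (s in seq_len(nrow(pts) - 1)) {
      d <- seg_dist(xg, yg, pts[s, 1], pts[s, 2], pts[s + 1, 1],
                    pts[s + 1, 2])
      al <- pmin(pmax(oc$thickness / 2 + 0.5 - d, 0), 1)
      img <- img * (1 - al) + oc$intensity * al
    }
  }
  if (scene$eyelid_coverage > 0) {
    yb <- scene$eyelid_coverage * (height - 1)
    al <- pmin(pmax(yb - yg + 0.5, 0), 1)
    img <- img * (1 - al) + scene$eyelid_intensity * al
  }
  grad <- scene$illumination_gradient
  if (grad[["strength"]] > 0) {
    img <- img + grad[["strength"]] *
      (grad[["gx"]] * (xg / (width - 1) - 0.5) +
       grad[["gy"]] * (yg / (height - 1) - 0.5))
  }
  if (scene$noise_sd > 0) {
    img <- img + with_seed(scene$noise_seed,
                           matrix(rnorm(height * width, 0, scene$noise_sd),
                                  height, width))
  }
  img <- pmin(pmax(img, 0), 1)
  ann <- c(cx = round_half_up(cx), cy = round_half_up(cy))
  ann <- c(cx = min(max(ann[["cx"]], 0), width - 1),
           cy = min(max(ann[["cy"]], 0), height - 1))
  list(image = img, annotation = as.integer(ann) |>
         stats::setNames(c("cx", "cy")))
}

#' Generate a labeled synthetic eye-image dataset
#'
#' Draws `n` independent scenes from a difficulty profile and renders each
#' one; stands in for a labeled corpus of infrared eye images. Pupil
#' centers cover the image interior per the profile's margin. The whole
#' dataset is reproducible from `(n, profile, width, height, seed)`.
#'
#' @param n Number of images (>= 1).
#' @param profile A [difficulty_profile()] or preset name.
#' @param width,height Image size in pixels.
#' @param seed Integer seed.
#' @return A tibble with one row per sample: `image` (list of matrices),
#'   `cx`, `cy` (integer pupil center), `width`, `height`, `source_tag`
#'   (profile name) and `scene` (list of `scene_params`). The seed is kept
#'   in `attr(x, "pg_seed")`.
#' @export
#' @examples
#' ds <- generate_dataset(5, "easy", 20, 15, seed = 1)
#' ds[, c("cx", "cy")]
generate_dataset <- function(n, profile, width = 320, height = 240,
                             seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    pg_stop("`n` must be a positive count", "count")
  }
  n <- as.integer(n)
  prof <- as_profile(profile)
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  rows <- purrr::map(seq_len(n), function(i) {
    scene <- sample_scene(scene_seeds[i], prof, width, height)
    out <- render_eye(scene, width, height)
    list(image = out$image, cx = out$annotation[["cx"]],
         cy = out$annotation[["cy"]], scene = scene)
  })
  ds <- tibble(
    image = purrr::map(rows, "image"),
    cx = purrr::map_int(rows, "cx"),
    cy = purrr::map_int(rows, "cy"),
    width = as.integer(width),
    height = as.integer(height),
    source_tag = prof$name,
    scene = purrr::map(rows, "scene")
  )
  attr(ds, "pg_seed") <- as.integer(seed)
  ds
}
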