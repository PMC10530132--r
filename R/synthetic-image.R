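#' Render a synthetic pellet image with known ground truth
#'
#' Draws near-circular pellets (or squares/ellipses for circularity tests) as
#' hard-edged shapes on a uniform background, optionally adds Gaussian pixel
#' noise, and returns the ground-truth particle table. The defaults emulate a
#' washed-pellet photograph: dark pellets (intensity 0.2) on a light tray
#' (0.9), diameters drawn from a Normal(2.10, 0.52^2) mm distribution
#' truncated to positive values by resampling, at a pixel scale of 0.05
#' mm/px. When `overlap = FALSE` (default) rejection sampling guarantees
#' disjoint particles with a two-pixel clearance, so labeled counts equal
#' `n` exactly.
#'
#' @param n Number of particles (>= 0).
#' @param width,height Image size in pixels.
#' @param scale Pixel scale in mm per pixel.
#' @param diameter_mean,diameter_sd Diameter distribution in mm (Normal,
#'   truncated > 0). `diameter_sd = 0` gives identical particles.
#' @param diameters Optional explicit diameters in mm (overrides the
#'   distribution); recycled to length `n`.
#' @param shape `"disk"` (default), `"square"` (side = diameter) or
#'   `"ellipse"` (major axis = diameter, minor = diameter / `axis_ratio`).
#' @param axis_ratio Major/minor axis ratio for ellipses (>= 1).
#' @param overlap Allow particles to overlap (default FALSE).
#' @param fg,bg Foreground and background intensities in `[0, 1]`.
#' @param noise_sd Additive Gaussian pixel noise SD (intensity units; the
#'   image is clamped back to `[0, 1]`).
#' @param margin Clearance from the image border in pixels.
#' @param seed Optional integer seed.
#' @param max_attempts Placement attempts before giving up when
#'   `overlap = FALSE` (default `200 * n`).
#' @return List with `image` (numeric matrix in `[0, 1]`) and `truth`
#'   (tibble: `id`, `cx`, `cy` in pixels, `diameter_px`, `diameter_mm`,
#'   `shape`).
#' @examples
#' im <- draw_pellet_image(n = 5, width = 256, height = 256, scale = 0.05,
#'                         diameter_mean = 2.1, diameter_sd = 0.3, seed = 7)
#' nrow(im$truth)
#' @export
draw_pellet_image <- function(n = 500, width = 1536, height = 1536, scale = 0.05,
                              diameter_mean = 2.10, diameter_sd = 0.52,
                              diameters = NULL,
                              shape = c("disk", "square", "ellipse"),
                              axis_ratio = 1, overlap = FALSE,
                              fg = 0.2, bg = 0.9, noise_sd = 0,
                              margin = 2, seed = NULL, max_attempts = NULL) {
  shape <- match.arg(shape)
  check_number(n, "n", lower = 0)
  check_number(scale, "scale", lower = 0, closed_lower = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(axis_ratio, "axis_ratio", lower = 1)
  for (v in c(fg, bg)) check_number(v, "fg/bg", lower = 0, upper = 1)
  n <- as.integer(n)
  max_attempts <- max_attempts %||% max(200L * n, 1000L)

  if (n == 0L) {
    return(list(
      image = matrix(bg, nrow = width, ncol = height),
      truth = tibble(id = integer(), cx = numeric(), cy = numeric(),
                     diameter_px = numeric(), diameter_mm = numeric(),
                     shape = character())
    ))
  }

  with_optional_seed(seed, {
    img <- matrix(bg, nrow = width, ncol = height)
    d_mm <- if (!is.null(diameters)) {
      rep_len(as.numeric(diameters), n)
    } else {
      d <- rnorm(n, diameter_mean, diameter_sd)
      tries <- 0L
      while (any(bad <- d <= 0)) {
        tries <- tries + 1L
        if (tries > 1000L) abort_domain("diameter distribution has too much mass at or below zero.")
        d[bad] <- rnorm(sum(bad), diameter_mean, diameter_sd)
      }
      d
    }
    if (any(d_mm <= 0)) abort_validation("explicit diameters must be positive.")
    d_px <- d_mm / scale
    r_px <- d_px / 2
    # place the largest first so rejection sampling fails early if infeasible
    ord <- order(r_px, decreasing = TRUE)

    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L; attempts <- 0L
    placed_idx <- integer(0)
    for (i in ord) {
      r <- r_px[i]
      if (2 * r + 2 * margin > min(width, height)) {
        abort_domain(sprintf("particle of diameter %.1f px does not fit in the image.", 2 * r))
      }
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort_domain(sprintf(
            "could not place %d non-overlapping particles in %d attempts; enlarge the image or reduce n.",
            n, max_attempts))
        }
        x <- stats::runif(1, r + margin, width - r - margin)
        y <- stats::runif(1, r + margin, height - r - margin)
        if (overlap || !length(placed_idx)) break
        dmin <- sqrt((cx[placed_idx] - x)^2 + (cy[placed_idx] - y)^2)
        # 2 px clearance keeps digitized particles 8-disconnected
        if (all(dmin > r + r_px[placed_idx] + 2)) break
      }
      cx[i] <- x; cy[i] <- y
      placed_idx <- c(placed_idx, i)
      placed <- placed + 1L
    }

    for (i in seq_len(n)) {
      r <- r_px[i]
      xr <- max(1L, floor(cx[i] - r - 1)):min(width, ceiling(cx[i] + r + 1))
      yr <- max(1L, floor(cy[i] - r - 1)):min(height, ceiling(cy[i] + r + 1))
      dx <- xr - cx[i]; dy <- yr - cy[i]
      inside <- switch(shape,
        disk = outer(dx^2, dy^2, "+") <= r^2,
        square = outer(abs(dx) <= r, abs(dy) <= r, "&"),
        ellipse = outer(dx^2 / r^2, dy^2 / (r / axis_ratio)^2, "+") <= 1
      )
      img[xr, yr][inside] <- fg
    }

    if (noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = width)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    truth <- tibble(id = seq_len(n), cx = cx, cy = cy,
                    diameter_px = d_px, diameter_mm = d_mm, shape = shape)
    list(image = img, truth = truth)
  })
}

#' Write a synthetic (or any) grayscale image to PNG or TIFF
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path; format follows the file extension.
#' @return `path`, invisibly.
#' @export
write_pellet_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(img), path)
  invisible(path)
}
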