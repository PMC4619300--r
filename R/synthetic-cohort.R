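#' Grade-conditioned generator defaults
#'
#' Default geometry for the three disease groups used by the synthetic
#' epithelium generator. Spacing is the target centre-to-centre
#' nearest-neighbour distance of the nuclear lattice; dysplastic epithelium
#' shows larger nuclei packed more densely, so spacing falls and radius grows
#' from NORMAL to HIGH. With these values a jitter-free specimen lands inside
#' the published grading bands: ENC ratio pi*r^2 / ((sqrt(3)/2) d^2) gives
#' 0.036 (NORMAL), 0.110 (LOW) and 0.326 (HIGH), and the lattice constant is
#' itself the three-nearest-neighbour distance (30, 23, 15 um).
#'
#' @return A tibble with one row per grade: `grade`, `spacing_mean_um`,
#'   `radius_mean_um`.
#' @export
grade_defaults <- function() {
  tibble(
    grade           = c("NORMAL", "LOW", "HIGH"),
    spacing_mean_um = c(30, 23, 15),
    radius_mean_um  = c(3.0, 4.0, 4.5)
  )
}

#' Specification of one synthetic specimen
#'
#' Bundles every parameter needed to synthesise a single acriflavine-like
#' confocal frame: field geometry, nuclear lattice statistics, gray levels,
#' blur and noise. Unspecified spacing/radius fall back to [grade_defaults()]
#' for the requested grade.
#'
#' @param grade One of `"NORMAL"`, `"LOW"`, `"HIGH"`.
#' @param field_of_view_um Side length of the square field (um). The default,
#'   445 um, is a 512-pixel frame at 0.87 um per pixel.
#' @param pixel_size_um Pixel pitch (um per pixel).
#' @param spacing_mean_um,spacing_sd_um Target nearest-neighbour spacing of
#'   nucleus centres and the Gaussian jitter applied per point (um).
#' @param radius_mean_um,radius_sd_um Nuclear radius distribution (um).
#' @param nucleus_intensity,background_intensity Mean gray levels (0-255).
#' @param noise_sd Additive Gaussian noise standard deviation (gray levels).
#' @param blur_sigma_um Gaussian point-spread blur (um).
#' @param depth_um Optional acquisition-depth tag carried into the frame.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `specimen_spec`.
#' @export
specimen_spec <- function(grade = c("NORMAL", "LOW", "HIGH"),
                          field_of_view_um = 445,
                          pixel_size_um = 0.87,
                          spacing_mean_um = NULL,
                          spacing_sd_um = 1.5,
                          radius_mean_um = NULL,
                          radius_sd_um = 0.3,
                          nucleus_intensity = 180,
                          background_intensity = 40,
                          noise_sd = 6,
                          blur_sigma_um = 0.5,
                          depth_um = NA_real_,
                          seed = 1L) {
  grade <- match.arg(grade)
  defs <- grade_defaults()
  row <- defs[defs$grade == grade, ]
  if (is.null(spacing_mean_um)) spacing_mean_um <- row$spacing_mean_um
  if (is.null(radius_mean_um)) radius_mean_um <- row$radius_mean_um

  check_number(field_of_view_um, "field_of_view_um")
  check_number(pixel_size_um, "pixel_size_um")
  check_number(spacing_mean_um, "spacing_mean_um")
  check_number(spacing_sd_um, "spacing_sd_um", allow_zero = TRUE)
  check_number(radius_mean_um, "radius_mean_um")
  check_number(radius_sd_um, "radius_sd_um", allow_zero = TRUE)
  check_number(noise_sd, "noise_sd", allow_zero = TRUE)
  check_number(blur_sigma_um, "blur_sigma_um", allow_zero = TRUE)
  if (spacing_mean_um <= 2 * radius_mean_um) {
    stop_validation(
      "spacing_mean_um (%g) must exceed twice radius_mean_um (%g): nuclei must not be forced to overlap",
      spacing_mean_um, radius_mean_um
    )
  }
  for (v in c(nucleus_intensity, background_intensity)) {
    if (v < 0 || v > 255) stop_validation("intensities must lie in [0, 255]")
  }
  structure(
    list(
      grade = grade,
      field_of_view_um = field_of_view_um,
      pixel_size_um = pixel_size_um,
      spacing_mean_um = spacing_mean_um,
      spacing_sd_um = spacing_sd_um,
      radius_mean_um = radius_mean_um,
      radius_sd_um = radius_sd_um,
      nucleus_intensity = nucleus_intensity,
      background_intensity = background_intensity,
      noise_sd = noise_sd,
      blur_sigma_um = blur_sigma_um,
      depth_um = depth_um,
      seed = as.integer(seed)
    ),
    class = "specimen_spec"
  )
}

#' @export
print.specimen_spec <- function(x, ...) {
  cat(sprintf(
    "<specimen_spec> grade %s | field %g um @ %g um/px | spacing %g +/- %g um | radius %g +/- %g um | seed %d\n",
    x$grade, x$field_of_view_um, x$pixel_size_um, x$spacing_mean_um,
    x$spacing_sd_um, x$radius_mean_um, x$radius_sd_um, x$seed
  ))
  invisible(x)
}

#' Sample nucleus centres for a synthetic specimen
#'
#' Draws nucleus centre positions from a jittered hexagonal lattice with
#' hard-core rejection. The lattice constant is `spacing_mean_um`; each point
#' receives isotropic Gaussian jitter with sd `spacing_sd_um`, and points are
#' accepted in fixed row-major order only if they stay at least
#' `radius_mean_um` away from the field border and at least
#' `2 * radius_mean_um` away from every previously accepted point. The
#' hexagonal backbone reproduces the regular packing of squamous epithelium
#' that makes Voronoi cell areas interpretable as cytoplasm proxies; a
#' homogeneous Poisson process would not.
#'
#' @param spec A [specimen_spec()].
#' @return A tibble with columns `x`, `y` (um, pixel-centre convention:
#'   x runs along columns, y along rows, origin at the first pixel centre).
#' @export
sample_nucleus_centers <- function(spec) {
  if (!inherits(spec, "specimen_spec")) {
    stop_validation("`spec` must be a specimen_spec")
  }
  L <- spec$field_of_view_um
  d <- spec$spacing_mean_um
  margin <- spec$radius_mean_um
  dy <- d * sqrt(3) / 2

  ys <- seq(margin, L - margin, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(k) {
    x0 <- margin + ((k - 1L) %% 2L) * d / 2
    xs <- seq(x0, L - margin, by = d)
    cbind(xs, rep(ys[k], length(xs)))
  }))

  if (spec$spacing_sd_um > 0) {
    jit <- with_seed(spec$seed, {
      matrix(rnorm(2L * nrow(pts), 0, spec$spacing_sd_um), ncol = 2L)
    })
    pts <- pts + jit
  }

  # hard-core rejection in deterministic row-major order
  rmin2 <- (2 * spec$radius_mean_um)^2
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (p[1] < margin || p[1] > L - margin || p[2] < margin || p[2] > L - margin) next
    prev <- pts[keep, , drop = FALSE]
    if (nrow(prev) == 0L ||
        min((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2) >= rmin2) {
      keep[i] <- TRUE
    }
  }
  tibble(x = pts[keep, 1], y = pts[keep, 2])
}

#' Rasterise a synthetic confocal frame with exact ground truth
#'
#' Renders each nucleus as a bright disk (`nucleus_intensity`) over a darker
#' cytoplasmic background, applies Gaussian blur of `blur_sigma_um`, then adds
#' Gaussian noise clipped to the 0-255 gray range. The returned ground truth
#' holds the pre-blur disk label mask: a pixel belongs to nucleus `i` when its
#' centre lies within `radii[i]` of `centers[i, ]` (ties to the nearer centre).
#'
#' @param centers Tibble/data frame with `x`, `y` in um, inside the field.
#' @param radii Numeric vector of nuclear radii (um), one per centre.
#' @param spec A [specimen_spec()] (supplies geometry, gray levels, seed).
#' @return A list with `frame` (a [confocal_frame()]) and `truth`, a
#'   `ground_truth` list of `centers`, `radii` and the integer `label_mask`
#'   (0 = background).
#' @export
render_frame <- function(centers, radii, spec) {
  if (!inherits(spec, "specimen_spec")) stop_validation("`spec` must be a specimen_spec")
  check_number(spec$pixel_size_um, "pixel_size_um")
  centers <- as.data.frame(centers)
  if (nrow(centers) != length(radii)) {
    stop_validation("need exactly one radius per centre (%d centres, %d radii)",
                    nrow(centers), length(radii))
  }
  L <- spec$field_of_view_um
  s <- spec$pixel_size_um
  n_px <- max(1L, round(L / s))
  if (nrow(centers) > 0 &&
      (any(centers$x < 0 | centers$x > L) || any(centers$y < 0 | centers$y > L))) {
    stop_validation("all centres must lie inside the field of view")
  }

  label <- matrix(0L, nrow = n_px, ncol = n_px)   # [row, col] = [y, x]
  # squared distance to owning centre, for nearest-centre tie-breaks
  best_d2 <- matrix(Inf, nrow = n_px, ncol = n_px)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    if (r <= 0) next
    cx <- centers$x[i]; cy <- centers$y[i]
    cols <- max(1L, floor((cx - r) / s) + 1L):min(n_px, ceiling((cx + r) / s) + 1L)
    rows <- max(1L, floor((cy - r) / s) + 1L):min(n_px, ceiling((cy + r) / s) + 1L)
    px <- (cols - 1L) * s
    py <- (rows - 1L) * s
    d2 <- outer(py, px, function(yy, xx) (xx - cx)^2 + (yy - cy)^2)
    hit <- d2 <= r^2 & d2 < best_d2[rows, cols]
    sub <- label[rows, cols]
    sub[hit] <- i
    label[rows, cols] <- sub
    bd <- best_d2[rows, cols]
    bd[hit] <- d2[hit]
    best_d2[rows, cols] <- bd
  }

  img <- matrix(spec$background_intensity, nrow = n_px, ncol = n_px)
  img[label > 0L] <- spec$nucleus_intensity
  if (spec$blur_sigma_um > 0) {
    img <- gaussian_blur(img, spec$blur_sigma_um / s)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 2L, {
      matrix(rnorm(length(img), 0, spec$noise_sd), nrow = n_px)
    })
    img <- pmin(pmax(img + noise, 0), 255)
  }

  frame <- confocal_frame(img, pixel_size_um = s, depth_um = spec$depth_um,
                          specimen_id = sprintf("%s_seed%d", spec$grade, spec$seed))
  truth <- structure(
    list(centers = as_tibble(centers), radii = radii, label_mask = label),
    class = "ground_truth"
  )
  list(frame = frame, truth = truth)
}

#' Synthesise one complete specimen
#'
#' Convenience wrapper: samples centres ([sample_nucleus_centers()]), draws
#' per-nucleus radii (Gaussian around `radius_mean_um`, floored at 0.5 um),
#' and renders the frame ([render_frame()]). Sub-seeds are derived from
#' `spec$seed` (`seed` for centres, `seed + 1` for radii, `seed + 2` for
#' noise) so the whole specimen is reproducible from the spec alone.
#'
#' @param spec A [specimen_spec()].
#' @return As [render_frame()]: list with `frame` and `truth`.
#' @export
generate_specimen <- function(spec) {
  centers <- sample_nucleus_centers(spec)
  radii <- if (spec$radius_sd_um > 0) {
    with_seed(spec$seed + 1L, {
      pmax(0.5, rnorm(nrow(centers), spec$radius_mean_um, spec$radius_sd_um))
    })
  } else {
    rep(spec$radius_mean_um, nrow(centers))
  }
  render_frame(centers, radii, spec)
}

#' Generate a grade-balanced synthetic cohort
#'
#' Emits `n_per_grade` specimens for each of NORMAL, LOW and HIGH using the
#' grade geometry in `grade_params` (defaults: [grade_defaults()]). The
#' per-specimen seed is derived deterministically from `base_seed` and the
#' specimen index, and is recorded in the output so any specimen can be
#' regenerated in isolation.
#'
#' @param n_per_grade Specimens per grade (>= 1).
#' @param base_seed Integer base seed for the whole cohort.
#' @param grade_params Tibble like [grade_defaults()] (`grade`,
#'   `spacing_mean_um`, `radius_mean_um`).
#' @param ... Further arguments passed to [specimen_spec()] (e.g. a smaller
#'   `field_of_view_um`, a `depth_um` tag, or noise overrides).
#' @return A tibble with one row per specimen: `specimen_id`, `grade`,
#'   `seed`, and list-columns `spec`, `frame`, `truth`.
#' @export
generate_cohort <- function(n_per_grade, base_seed = 1L,
                            grade_params = grade_defaults(), ...) {
  if (!is.numeric(n_per_grade) || n_per_grade < 1) {
    stop_validation("`n_per_grade` must be >= 1")
  }
  bad <- setdiff(grade_params$grade, c("NORMAL", "LOW", "HIGH"))
  if (length(bad) > 0) {
    stop_validation("unknown grade key(s): %s", paste(bad, collapse = ", "))
  }
  idx <- 0L
  rows <- purrr::pmap(grade_params, function(grade, spacing_mean_um, radius_mean_um) {
    purrr::map(seq_len(n_per_grade), function(k) {
      idx <<- idx + 1L
      seed_i <- (as.integer(base_seed) + 1009L * idx) %% 2147483647L
      spec <- specimen_spec(
        grade = grade, spacing_mean_um = spacing_mean_um,
        radius_mean_um = radius_mean_um, seed = seed_i, ...
      )
      out <- generate_specimen(spec)
      tibble(
        specimen_id = sprintf("%s_%02d", grade, k),
        grade = grade, seed = seed_i,
        spec = list(spec), frame = list(out$frame), truth = list(out$truth)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
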