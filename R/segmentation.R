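#' Confocal frame object
#'
#' One en-face grayscale confocal image with its physical calibration.
#' Pixels are stored `[row, col]`; the physical coordinate of a pixel centre
#' is `x = (col - 1) * pixel_size_um`, `y = (row - 1) * pixel_size_um`. This
#' convention is used everywhere in the package.
#'
#' @param pixels Numeric matrix of gray levels (>= 0).
#' @param pixel_size_um Pixel pitch in um (> 0).
#' @param depth_um Optional acquisition depth below the epithelial surface.
#' @param specimen_id Optional identifier.
#' @return An object of class `confocal_frame`.
#' @export
confocal_frame <- function(pixels, pixel_size_um, depth_um = NA_real_,
                           specimen_id = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop_validation("`pixels` must be a nonempty matrix")
  }
  if (any(pixels < 0)) stop_validation("gray levels must be >= 0")
  check_number(pixel_size_um, "pixel_size_um")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         depth_um = depth_um, specimen_id = specimen_id),
    class = "confocal_frame"
  )
}

#' @export
print.confocal_frame <- function(x, ...) {
  cat(sprintf(
    "<confocal_frame> %d x %d px @ %g um/px (%.0f x %.0f um)%s%s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    nrow(x$pixels) * x$pixel_size_um, ncol(x$pixels) * x$pixel_size_um,
    if (is.na(x$depth_um)) "" else sprintf(" | depth %g um", x$depth_um),
    if (is.na(x$specimen_id)) "" else sprintf(" | %s", x$specimen_id)
  ))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Binary mask congruent with a frame, restricting which nuclei enter the
#' analysis (the published workflow drew this by hand to exclude noisy frame
#' regions; here it is an explicit input). `roi_full()` selects the whole
#' frame.
#'
#' @param mask Logical (or 0/1) matrix; at least one pixel must be TRUE.
#' @param pixel_size_um Pixel pitch in um.
#' @return An object of class `roi_mask` with derived `area_um2`.
#' @export
roi_mask <- function(mask, pixel_size_um) {
  if (!is.matrix(mask)) stop_validation("`mask` must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stop_validation("ROI mask must contain at least one TRUE pixel")
  check_number(pixel_size_um, "pixel_size_um")
  structure(
    list(mask = mask, pixel_size_um = pixel_size_um,
         area_um2 = sum(mask) * pixel_size_um^2),
    class = "roi_mask"
  )
}

#' @rdname roi_mask
#' @param frame A [confocal_frame()] whose full extent becomes the ROI.
#' @export
roi_full <- function(frame) {
  roi_mask(matrix(TRUE, nrow(frame$pixels), ncol(frame$pixels)),
           frame$pixel_size_um)
}

# --- low-level image ops ----------------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(img, sigma_px) {
  k <- gaussian_kernel_1d(sigma_px)
  kern <- outer(k, k)
  EBImage::imageData(EBImage::filter2(img, kern, boundary = "replicate"))
}

# Derivative-of-Gaussian gradients along x (columns) and y (rows).
dog_gradients <- function(pixels, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  dg <- -(x / sigma_px^2) * exp(-x^2 / (2 * sigma_px^2))
  dg <- dg / sum(x * -dg) * -1  # normalise so a unit ramp gives unit gradient
  # separable kernels; matrix layout is [row=y, col=x]
  kx <- outer(g, dg)   # smooth in y, differentiate in x
  ky <- outer(dg, g)   # differentiate in y, smooth in x
  gx <- EBImage::imageData(EBImage::filter2(pixels, kx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(pixels, ky, boundary = "replicate"))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Gradient magnitude of a frame
#'
#' Per-pixel magnitude of the derivative-of-Gaussian intensity gradient, the
#' first stage of the edge-detection pipeline.
#'
#' @param frame A [confocal_frame()].
#' @param sigma_px Gaussian smoothing scale in pixels (> 0).
#' @return Non-negative numeric matrix, same shape as the frame.
#' @export
gradient_magnitude <- function(frame, sigma_px = 1.5) {
  check_number(sigma_px, "sigma_px")
  dog_gradients(frame$pixels, sigma_px)$mag
}

shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

# Euclidean disk structuring element: offsets with dr^2 + dc^2 <= r^2
# (radius 1 gives the 4-connected cross).
disk_brush <- function(r) {
  r <- as.integer(r)
  off <- (-r):r
  1 * (outer(off, off, function(a, b) a^2 + b^2) <= r^2)
}

# Geodesic propagation of `seed` inside `mask` (binary morphological
# reconstruction by dilation, 8-connected).
reconstruct_binary <- function(seed, mask) {
  cur <- seed & mask
  box <- matrix(1, 3, 3)
  repeat {
    grown <- EBImage::imageData(EBImage::dilate(cur * 1, box)) > 0 & mask
    if (sum(grown) == sum(cur)) return(grown)
    cur <- grown
  }
}

#' Canny edge detection
#'
#' Detects strong and weak edges: derivative-of-Gaussian gradient,
#' non-maximum suppression along the quantised gradient direction, then
#' double-threshold hysteresis in which weak edge pixels survive only when
#' 8-connected to a strong pixel. The high threshold is the `high_frac`
#' quantile of the nonzero gradient magnitudes; the low threshold is
#' `low_frac * high` (the published pipeline states no values, so both are
#' exposed).
#'
#' @param frame A [confocal_frame()].
#' @param sigma_px Gaussian derivative scale (pixels).
#' @param low_frac Low threshold as a fraction of the high threshold,
#'   in (0, 1).
#' @param high_frac Quantile of nonzero gradient magnitude defining the
#'   strong-edge threshold, in (0, 1].
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(frame, sigma_px = 1.5, low_frac = 0.4, high_frac = 0.9) {
  check_number(sigma_px, "sigma_px")
  if (!(low_frac > 0 && low_frac < 1)) stop_validation("`low_frac` must be in (0, 1)")
  if (!(high_frac > 0 && high_frac <= 1)) stop_validation("`high_frac` must be in (0, 1]")
  g <- dog_gradients(frame$pixels, sigma_px)
  mag <- g$mag
  nz <- mag[mag > 1e-12]
  if (length(nz) == 0L) return(matrix(FALSE, nrow(mag), ncol(mag)))
  hi <- unname(quantile(nz, high_frac))
  lo <- low_frac * hi

  # non-maximum suppression: compare to the two neighbours along the
  # gradient direction, quantised to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx)          # gy = d/drow, gx = d/dcol
  ang <- ang %% pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4L)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nbr <- list(
    list(c(0L, 1L),  c(0L, -1L)),   # gradient along x -> compare left/right
    list(c(1L, 1L),  c(-1L, -1L)),
    list(c(1L, 0L),  c(-1L, 0L)),   # gradient along y -> compare up/down
    list(c(1L, -1L), c(-1L, 1L))
  )
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (sct in 0:3) {
    sel <- sector == sct
    n1 <- shift_mat(mag, nbr[[sct + 1]][[1]][1], nbr[[sct + 1]][[1]][2], fill = 0)
    n2 <- shift_mat(mag, nbr[[sct + 1]][[2]][1], nbr[[sct + 1]][[2]][2], fill = 0)
    keep[sel] <- (mag >= n1 & mag >= n2)[sel]
  }
  nms <- mag * keep

  strong <- nms >= hi
  weak <- nms >= lo
  if (!any(strong)) return(matrix(FALSE, nrow(mag), ncol(mag)))
  reconstruct_binary(strong, weak)
}

#' Fill enclosed holes in a binary edge image
#'
#' Morphological-reconstruction hole filling: every background region not
#' connected to the image border becomes foreground, so a closed nuclear
#' contour becomes a solid object while open arcs are left unchanged.
#' Idempotent, and its output always contains its input.
#'
#' @param edges Logical (or 0/1) matrix.
#' @return Logical matrix.
#' @export
fill_nuclei <- function(edges) {
  if (!is.matrix(edges)) stop_validation("`edges` must be a matrix")
  m <- edges > 0
  EBImage::imageData(EBImage::fillHull(m * 1)) > 0
}

#' Morphological cleanup by iterated opening
#'
#' Applies `n_rounds` of (erosion then dilation) with a disk structuring
#' element of radius `se_radius_px`, removing structures thinner than
#' `2 * se_radius_px` — the stage that discards edge responses that do not
#' correspond to nucleus bodies. At the image border, erosion ignores
#' neighbours outside the grid and dilation treats them as background.
#'
#' @param bin Logical (or 0/1) matrix.
#' @param se_radius_px Disk radius in pixels (>= 1).
#' @param n_rounds Number of erosion/dilation rounds (>= 1).
#' @return Logical matrix.
#' @export
morphological_cleanup <- function(bin, se_radius_px = 1L, n_rounds = 2L) {
  if (!is.matrix(bin)) stop_validation("`bin` must be a matrix")
  if (se_radius_px < 1) stop_validation("`se_radius_px` must be >= 1")
  if (n_rounds < 1) stop_validation("`n_rounds` must be >= 1")
  brush <- disk_brush(se_radius_px)
  cur <- (bin > 0) * 1
  for (i in seq_len(n_rounds)) {
    cur <- EBImage::imageData(EBImage::dilate(EBImage::erode(cur, brush), brush))
  }
  cur > 0
}

# Lattice-point count inside the convex hull of integer pixel coordinates
# (Pick's theorem: interior + boundary = A + B/2 + 1), used for solidity.
hull_pixel_count <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(n)
  h <- grDevices::chull(cols, rows)
  hx <- cols[h]; hy <- rows[h]
  if (length(h) < 3L) return(n)  # collinear component
  A <- polygon_area(hx, hy)
  nh <- length(h)
  j <- c(seq_len(nh)[-1], 1L)
  B <- sum(mapply(function(a, b, c, d) {
    dx <- abs(c - a); dy <- abs(d - b)
    if (dx == 0 && dy == 0) 0 else gcd2(dx, dy)
  }, hx, hy, hx[j], hy[j]))
  A + B / 2 + 1
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Extract nucleus objects from a filled binary image
#'
#' Connected-component labelling followed by the automated quality filter
#' that replaces manual object review: components are kept only when their
#' centroid falls inside the ROI, their area lies within
#' `[min_area_um2, max_area_um2]`, and their solidity (pixel area over
#' convex-hull pixel area) is at least `min_solidity`. Areas and centroids
#' are converted to physical units with the frame calibration.
#'
#' @param filled Logical matrix of candidate nucleus pixels.
#' @param roi A [roi_mask()] congruent with the frame.
#' @param frame The source [confocal_frame()].
#' @param min_area_um2,max_area_um2 Area acceptance band (um^2).
#' @param min_solidity Minimum solidity in (0, 1].
#' @return An object of class `segmentation`: list with `nuclei` (tibble:
#'   `id`, `centroid_x_um`, `centroid_y_um`, `area_um2`, `solidity`,
#'   `n_pixels`), `label_mask` (surviving components, relabelled 1..n),
#'   `roi`, `pixel_size_um`, and `params`. Zero surviving nuclei is a valid
#'   result with an empty tibble.
#' @export
extract_nuclei <- function(filled, roi, frame,
                           min_area_um2 = 10, max_area_um2 = 200,
                           min_solidity = 0.7) {
  if (!inherits(roi, "roi_mask")) stop_validation("`roi` must be a roi_mask")
  if (!all(dim(filled) == dim(roi$mask)) || !all(dim(filled) == dim(frame$pixels))) {
    stop_validation("frame, ROI and binary grid must be congruent")
  }
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2)) {
    stop_validation("need 0 < min_area_um2 < max_area_um2")
  }
  s <- frame$pixel_size_um
  lab <- EBImage::imageData(EBImage::bwlabel((filled > 0) * 1))
  params <- list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_solidity = min_solidity, pixel_size_um = s)

  nuc <- tibble(id = integer(), centroid_x_um = double(), centroid_y_um = double(),
                area_um2 = double(), solidity = double(), n_pixels = integer())
  out_mask <- matrix(0L, nrow(filled), ncol(filled))
  nmax <- max(lab)
  if (nmax > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    by_lab <- split(seq_len(nrow(idx)), lab[idx])
    keep_id <- 0L
    rows_list <- vector("list", length(by_lab))
    for (nm in names(by_lab)) {
      ii <- by_lab[[nm]]
      rr <- idx[ii, 1]; cc <- idx[ii, 2]
      n_px <- length(rr)
      area <- n_px * s^2
      cx <- (mean(cc) - 1) * s
      cy <- (mean(rr) - 1) * s
      sol <- min(1, n_px / hull_pixel_count(rr, cc))
      in_roi <- roi$mask[round(mean(rr)), round(mean(cc))]
      if (in_roi && area >= min_area_um2 && area <= max_area_um2 && sol >= min_solidity) {
        keep_id <- keep_id + 1L
        out_mask[cbind(rr, cc)] <- keep_id
        rows_list[[keep_id]] <- tibble(
          id = keep_id, centroid_x_um = cx, centroid_y_um = cy,
          area_um2 = area, solidity = sol, n_pixels = n_px
        )
      }
    }
    if (keep_id > 0L) nuc <- dplyr::bind_rows(rows_list[seq_len(keep_id)])
  }
  structure(
    list(nuclei = nuc, label_mask = out_mask, roi = roi,
         pixel_size_um = s, params = params),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d nuclei in %.3g mm^2 ROI (%g um/px)\n",
              nrow(x$nuclei), x$roi$area_um2 / 1e6, x$pixel_size_um))
  invisible(x)
}

#' @export
tidy.segmentation <- function(x, ...) x$nuclei

#' @export
glance.segmentation <- function(x, ...) {
  tibble(n_nuclei = nrow(x$nuclei), roi_area_um2 = x$roi$area_um2,
         pixel_size_um = x$pixel_size_um)
}

#' Segment nuclei in a confocal frame
#'
#' The full two-step segmentation pipeline: Canny edge detection
#' ([canny_edges()]), a one-pixel dilation bridging small contour gaps,
#' morphological-reconstruction hole filling ([fill_nuclei()]) followed by
#' the matching erosion, iterated opening cleanup ([morphological_cleanup()])
#' and quality-filtered component extraction ([extract_nuclei()]). All
#' parameters are recorded in the result's `params`.
#'
#' @param frame A [confocal_frame()].
#' @param roi A [roi_mask()]; defaults to the whole frame.
#' @param sigma_px,low_frac,high_frac Canny parameters; see [canny_edges()].
#' @param bridge_px Radius of an optional gap-bridging dilation applied to
#'   the edge set before hole filling (matching erosion afterwards). Off by
#'   default: hysteresis already closes contours at the default contrast,
#'   and bridging can merge tightly packed nuclei. Useful for low-contrast
#'   material where contours break.
#' @param se_radius_px,n_rounds Cleanup parameters; see
#'   [morphological_cleanup()].
#' @param min_area_um2,max_area_um2,min_solidity Quality filters; see
#'   [extract_nuclei()].
#' @return A `segmentation` object (see [extract_nuclei()]).
#' @export
segment_nuclei <- function(frame, roi = NULL,
                           sigma_px = 1.5, low_frac = 0.4, high_frac = 0.9,
                           bridge_px = 0L, se_radius_px = 1L, n_rounds = 2L,
                           min_area_um2 = 10, max_area_um2 = 200,
                           min_solidity = 0.7) {
  if (is.null(roi)) roi <- roi_full(frame)
  edges <- canny_edges(frame, sigma_px = sigma_px,
                       low_frac = low_frac, high_frac = high_frac)
  work <- edges
  if (bridge_px > 0) {
    brush <- disk_brush(bridge_px)
    work <- EBImage::imageData(EBImage::dilate(work * 1, brush)) > 0
    work <- fill_nuclei(work)
    work <- EBImage::imageData(EBImage::erode(work * 1, brush)) > 0
  } else {
    work <- fill_nuclei(work)
  }
  work <- morphological_cleanup(work, se_radius_px = se_radius_px, n_rounds = n_rounds)
  res <- extract_nuclei(work, roi, frame,
                        min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                        min_solidity = min_solidity)
  res$params <- c(res$params,
                  list(sigma_px = sigma_px, low_frac = low_frac,
                       high_frac = high_frac, bridge_px = bridge_px,
                       se_radius_px = se_radius_px, n_rounds = n_rounds))
  res
}

#' Score a segmentation against synthetic ground truth
#'
#' Greedy one-to-one matching: each true nucleus is matched to the nearest
#' unclaimed detected centroid lying within one nuclear radius of the true
#' centre. Reports recall (matched fraction of true nuclei), false-positive
#' rate (unmatched fraction of detections) and the relative area error of
#' matched nuclei against the rendered label-mask areas.
#'
#' @param seg A `segmentation` from [segment_nuclei()].
#' @param truth A `ground_truth` from [render_frame()].
#' @return One-row tibble: `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `fp_rate`, `median_area_error`.
#' @export
evaluate_segmentation <- function(seg, truth) {
  s <- seg$pixel_size_um
  det <- seg$nuclei
  n_truth <- nrow(truth$centers)
  truth_area <- tabulate(truth$label_mask[truth$label_mask > 0], nbins = n_truth) * s^2
  matched <- rep(NA_integer_, n_truth)
  used <- logical(nrow(det))
  if (nrow(det) > 0 && n_truth > 0) {
    for (i in seq_len(n_truth)) {
      d <- sqrt((det$centroid_x_um - truth$centers$x[i])^2 +
                  (det$centroid_y_um - truth$centers$y[i])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) == 1L && d[j] <= truth$radii[i]) {
        matched[i] <- j
        used[j] <- TRUE
      }
    }
  }
  ok <- !is.na(matched)
  area_err <- if (any(ok)) {
    abs(det$area_um2[matched[ok]] - truth_area[ok]) / truth_area[ok]
  } else {
    NA_real_
  }
  tibble(
    n_truth = n_truth, n_detected = nrow(det), n_matched = sum(ok),
    recall = if (n_truth > 0) sum(ok) / n_truth else NA_real_,
    fp_rate = if (nrow(det) > 0) sum(!used) / nrow(det) else NA_real_,
    median_area_error = median(area_err)
  )
}
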