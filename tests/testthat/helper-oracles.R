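# Independent brute-force oracles used to cross-check the geometric and
# statistical machinery. These deliberately share no code with the package
# implementation.

# Border-seeded flood fill: returns the hole-filled version of a binary grid
# by growing the background from the border (4-connected) and declaring
# everything unreached as foreground.
oracle_fill_holes <- function(bin) {
  bin <- bin > 0
  nr <- nrow(bin); nc <- ncol(bin)
  reached <- matrix(FALSE, nr, nc)
  queue <- which(!bin & (row(bin) %in% c(1, nr) | col(bin) %in% c(1, nc)))
  reached[queue] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    r <- (cur - 1) %% nr + 1
    c <- (cur - 1) %/% nr + 1
    for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc) {
        k <- (d[2] - 1) * nr + d[1]
        if (!bin[k] && !reached[k]) {
          reached[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  !reached
}

# Brute-force binary erosion/dilation with a disk structuring element.
# Boundary convention: neighbours outside the grid are ignored by erosion
# (treated as foreground) and contribute background to dilation.
oracle_disk_offsets <- function(r) {
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
}

oracle_erode <- function(bin, r) {
  off <- oracle_disk_offsets(r)
  nr <- nrow(bin); nc <- ncol(bin)
  out <- matrix(TRUE, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- matrix(TRUE, nr, nc)
    rs <- max(1, 1 - off$dr[k]):min(nr, nr - off$dr[k])
    cs <- max(1, 1 - off$dc[k]):min(nc, nc - off$dc[k])
    sh[rs + off$dr[k], cs + off$dc[k]] <- bin[rs, cs] > 0
    out <- out & sh
  }
  out
}

oracle_dilate <- function(bin, r) {
  off <- oracle_disk_offsets(r)
  nr <- nrow(bin); nc <- ncol(bin)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - off$dr[k]):min(nr, nr - off$dr[k])
    cs <- max(1, 1 - off$dc[k]):min(nc, nc - off$dc[k])
    sh[rs + off$dr[k], cs + off$dc[k]] <- bin[rs, cs] > 0
    out <- out | sh
  }
  out
}

# Nearest-point pixel assignment over a rectangular region: every raster cell
# centre inside [x0,x1] x [y0,y1] is assigned to its nearest point. Returns
# per-point areas (cell count * raster^2) and the set of 4-adjacent label
# pairs together with the count of adjacent pixel pairs supporting each.
oracle_voronoi_raster <- function(pts, x0, x1, y0, y1, raster = 0.25) {
  xs <- seq(x0 + raster / 2, x1 - raster / 2, by = raster)
  ys <- seq(y0 + raster / 2, y1 - raster / 2, by = raster)
  lab <- matrix(0L, length(ys), length(xs))
  best <- matrix(Inf, length(ys), length(xs))
  for (i in seq_len(nrow(pts))) {
    d2 <- outer(ys, xs, function(yy, xx) (xx - pts$x[i])^2 + (yy - pts$y[i])^2)
    hit <- d2 < best
    lab[hit] <- i
    best[hit] <- d2[hit]
  }
  areas <- tabulate(lab, nbins = nrow(pts)) * raster^2
  pair_count <- function(a, b) {
    keep <- a != b
    if (!any(keep)) return(NULL)
    data.frame(i = pmin(a[keep], b[keep]), j = pmax(a[keep], b[keep]))
  }
  hp <- pair_count(lab[, -ncol(lab)], lab[, -1])
  vp <- pair_count(lab[-nrow(lab), ], lab[-1, ])
  pairs <- rbind(hp, vp)
  counts <- stats::aggregate(list(n = rep(1L, nrow(pairs))), pairs, sum)
  list(areas = areas, adjacency = counts)
}

# Mid-rank Spearman by explicit formula: midrank(v) = #{u < v} + (#{u == v}+1)/2,
# then the Pearson correlation computed from raw sums.
oracle_spearman <- function(tab, collapse = TRUE) {
  code3 <- c(NORMAL = 1, CIN1 = 2, CIN2 = 3, CIN3 = 3, LOW = 2, HIGH = 3)
  ccodes <- if (collapse) code3[colnames(tab)] else seq_len(ncol(tab))
  x <- c(); y <- c()
  for (r in seq_len(nrow(tab))) for (cc in seq_len(ncol(tab))) {
    x <- c(x, rep(r, tab[r, cc]))
    y <- c(y, rep(ccodes[cc], tab[r, cc]))
  }
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(rx)
  sxy <- sum(rx * ry) - sum(rx) * sum(ry) / n
  sxx <- sum(rx^2) - sum(rx)^2 / n
  syy <- sum(ry^2) - sum(ry)^2 / n
  sxy / sqrt(sxx * syy)
}

# A random 3 x 4 contingency table with both margins non-constant.
random_contingency <- function() {
  repeat {
    m <- matrix(rpois(12, 3), nrow = 3,
                dimnames = list(c("NORMAL", "LOW", "HIGH"),
                                c("NORMAL", "CIN1", "CIN2", "CIN3")))
    rs <- rowSums(m); cs <- colSums(m)
    if (sum(m) >= 4 && sum(rs > 0) >= 2 && sum(cs > 0) >= 2) return(m)
  }
}

# Small fast specimen spec used throughout the unit tests (coarse field,
# 1 um pixels); grade geometry and image statistics keep package defaults.
small_spec <- function(grade, seed = 1L, ...) {
  specimen_spec(grade, field_of_view_um = 150, pixel_size_um = 1,
                seed = seed, ...)
}

# Square ROI of `n` pixels at `s` um/px.
square_roi <- function(n, s = 1) roi_mask(matrix(TRUE, n, n), s)

# Per-cell area agreement against the raster oracle at 1%. A pixel-centre
# oracle can itself err by more than 1% on a cell whose boundary runs almost
# parallel to the raster grid; cells failing at the base raster are therefore
# re-measured once with a 4x finer raster before being declared discrepant.
expect_oracle_areas_match <- function(g, pts, x0, x1, y0, y1, raster = 0.25) {
  o <- oracle_voronoi_raster(pts, x0, x1, y0, y1, raster = raster)
  rel <- abs(g$area_um2 - o$areas) / o$areas
  if (max(rel) > 0.01) {
    fine <- oracle_voronoi_raster(pts, x0, x1, y0, y1, raster = raster / 4)
    bad <- which(rel > 0.01)
    rel[bad] <- abs(g$area_um2[bad] - fine$areas[bad]) / fine$areas[bad]
  }
  testthat::expect_lt(max(rel), 0.01)
  invisible(o)
}

# Length of the part of segment (x1,y1)-(x2,y2) inside a rectangle
# (Liang-Barsky clipping); used to decide which Voronoi edges a raster
# oracle confined to the rectangle can possibly see.
clipped_seg_len <- function(x1, y1, x2, y2, xmin, xmax, ymin, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(0)
    } else {
      tt <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, tt) else t1 <- min(t1, tt)
    }
  }
  if (t0 >= t1) return(0)
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

# Hexagonal lattice of constant d covering [0, lim]^2 with a margin.
hex_points <- function(d, lim, margin) {
  ys <- seq(margin, lim - margin, by = d * sqrt(3) / 2)
  do.call(rbind, lapply(seq_along(ys), function(k) {
    xs <- seq(margin + ((k - 1) %% 2) * d / 2, lim - margin, by = d)
    data.frame(x = xs, y = ys[k])
  }))
}
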