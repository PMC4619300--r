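# ROI boundary as a polygon set usable by polyclip. A full-TRUE mask becomes
# the exact frame rectangle; a general mask is traced along pixel edges.
roi_polygon <- function(roi) {
  s <- roi$pixel_size_um
  nr <- nrow(roi$mask); nc <- ncol(roi$mask)
  half <- s / 2
  if (all(roi$mask)) {
    return(list(list(
      x = c(-half, (nc - 1) * s + half, (nc - 1) * s + half, -half),
      y = c(-half, -half, (nr - 1) * s + half, (nr - 1) * s + half)
    )))
  }
  # mask rows index y, columns x; owin wants the matrix with rows = y too
  w <- spatstat.geom::owin(
    xrange = c(-half, (nc - 1) * s + half),
    yrange = c(-half, (nr - 1) * s + half),
    mask = roi$mask
  )
  wp <- spatstat.geom::as.polygonal(w)
  lapply(wp$bdry, function(b) list(x = b$x, y = b$y))
}

#' Voronoi/Delaunay tessellation of nucleus centres clipped to a ROI
#'
#' Builds the Voronoi diagram of the centre set S and its Delaunay dual
#' (two points are neighbours exactly when their Voronoi cells share an
#' edge). Each cell V(p) is clipped to the ROI boundary; a point is flagged
#' `interior` only when its cell was bounded and unaffected by clipping —
#' boundary cells have truncated cytoplasm estimates and are excluded from
#' the ENC ratio and 3NDND.
#'
#' @param centroids Data frame/tibble with `x`, `y` in um (>= 3 points, not
#'   all collinear).
#' @param roi A [roi_mask()] defining the clip region.
#' @return An object of class `tessellation`: `points` (tibble `x`, `y`),
#'   `tiles` (list of clipped polygon lists), `area_um2` (clipped cell
#'   areas), `edge_length_um` (length of each shared Voronoi edge), `edges`
#'   (tibble with the edge endpoints and lengths),
#'   `adjacency` (two-column index matrix, each shared Voronoi edge
#'   once), `neighbors` (list of neighbour index vectors), `interior`
#'   (logical), `roi_area_um2`.
#' @export
build_tessellation <- function(centroids, roi) {
  pts <- as.data.frame(centroids)
  if (!all(c("x", "y") %in% names(pts))) stop_validation("`centroids` needs columns x, y")
  n <- nrow(pts)
  if (n < 3) stop_geometry("tessellation needs >= 3 points, got %d", n)
  if (anyDuplicated(pts[c("x", "y")])) stop_geometry("duplicate nucleus centres")
  # collinearity: rank of centred coordinates
  cc <- scale(as.matrix(pts[c("x", "y")]), scale = FALSE)
  if (min(svd(cc)$d) < 1e-9 * max(svd(cc)$d, 1)) {
    stop_geometry("all points are collinear; the Voronoi diagram is degenerate")
  }
  if (!inherits(roi, "roi_mask")) stop_validation("`roi` must be a roi_mask")

  roip <- roi_polygon(roi)
  rx <- range(unlist(lapply(roip, `[[`, "x")), pts$x)
  ry <- range(unlist(lapply(roip, `[[`, "y")), pts$y)
  pad <- max(diff(rx), diff(ry)) + 1   # unbounded cells hit this outer frame
  rw <- c(rx[1] - pad, rx[2] + pad, ry[1] - pad, ry[2] + pad)

  dd <- deldir::deldir(pts$x, pts$y, rw = rw, round = FALSE, suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  raw_area <- vapply(tl, function(t) polygon_area(t$x, t$y), 0)
  touches_rw <- vapply(tl, function(t) any(t$bp), TRUE)

  tiles <- vector("list", n)
  area <- numeric(n)
  interior <- logical(n)
  for (i in seq_len(n)) {
    tp <- list(list(x = tl[[i]]$x, y = tl[[i]]$y))
    clip <- polyclip::polyclip(tp, roip, op = "intersection")
    a <- sum(vapply(clip, function(p) polygon_area(p$x, p$y), 0))
    # snap to the exact deldir area when clipping left the cell whole
    if (!touches_rw[i] && abs(a - raw_area[i]) <= 1e-6 * raw_area[i]) {
      a <- raw_area[i]
      interior[i] <- TRUE
      tiles[[i]] <- tp
    } else {
      tiles[[i]] <- clip
    }
    area[i] <- a
  }

  seg <- dd$dirsgs
  # drop zero-length Voronoi edges produced by degenerate co-circular sites
  elen <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  seg <- seg[elen > 1e-12, , drop = FALSE]
  elen <- elen[elen > 1e-12]
  pair <- cbind(pmin(seg$ind1, seg$ind2), pmax(seg$ind1, seg$ind2))
  dup <- duplicated(pair)
  adj <- pair[!dup, , drop = FALSE]
  edges <- tibble(
    i = adj[, 1], j = adj[, 2], length_um = elen[!dup],
    x1 = seg$x1[!dup], y1 = seg$y1[!dup], x2 = seg$x2[!dup], y2 = seg$y2[!dup]
  )
  neighbors <- lapply(seq_len(n), function(i) {
    sort(unique(c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1])))
  })

  structure(
    list(points = as_tibble(pts[c("x", "y")]), tiles = tiles, area_um2 = area,
         adjacency = adj, edge_length_um = edges$length_um, edges = edges,
         neighbors = neighbors, interior = interior,
         roi_area_um2 = roi$area_um2),
    class = "tessellation"
  )
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d points (%d interior), %d Delaunay edges, ROI %.3g mm^2\n",
              nrow(x$points), sum(x$interior), nrow(x$adjacency),
              x$roi_area_um2 / 1e6))
  invisible(x)
}

#' Estimated nuclear-to-cytoplasmic (ENC) ratio
#'
#' Mean over interior points of nucleus area divided by the area of its
#' clipped Voronoi cell, the cell serving as a cytoplasm proxy. Boundary
#' cells are excluded because clipping truncates their area.
#'
#' @param seg A `segmentation` whose nuclei (in order) generated `graph`.
#' @param graph A [build_tessellation()] result over the same nuclei.
#' @return Unitless scalar in (0, 1].
#' @export
enc_ratio <- function(seg, graph) {
  if (nrow(seg$nuclei) != nrow(graph$points)) {
    stop_validation("segmentation (%d nuclei) and tessellation (%d points) do not match",
                    nrow(seg$nuclei), nrow(graph$points))
  }
  if (!any(graph$interior)) {
    stop_insufficient("no interior Voronoi cells: ENC ratio is undefined")
  }
  i <- graph$interior
  mean(seg$nuclei$area_um2[i] / graph$area_um2[i])
}

#' Mean distance to the three nearest Delaunay neighbours (3NDND)
#'
#' For each interior point with at least three Delaunay neighbours, averages
#' the three smallest centre-to-centre neighbour distances; returns the mean
#' over qualifying points in um. Points with fewer than three neighbours are
#' excluded.
#'
#' @param graph A [build_tessellation()] result.
#' @return Scalar distance in um.
#' @export
nddn3 <- function(graph) {
  pts <- as.matrix(graph$points)
  cand <- which(graph$interior)
  vals <- vapply(cand, function(i) {
    nb <- graph$neighbors[[i]]
    if (length(nb) < 3L) return(NA_real_)
    d <- sqrt((pts[nb, 1] - pts[i, 1])^2 + (pts[nb, 2] - pts[i, 2])^2)
    mean(sort(d)[1:3])
  }, 0)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop_insufficient("no interior point has >= 3 Delaunay neighbours: 3NDND is undefined")
  }
  mean(vals)
}

#' Mean nuclear area
#'
#' Arithmetic mean of segmented nucleus areas (um^2) over all nuclei in the
#' ROI (boundary Voronoi cells are irrelevant here: the nucleus itself is
#' fully measured).
#'
#' @param seg A `segmentation`.
#' @return Scalar area in um^2.
#' @export
nuclear_area_mean <- function(seg) {
  if (nrow(seg$nuclei) == 0L) stop_insufficient("empty segmentation: nuclear area undefined")
  mean(seg$nuclei$area_um2)
}

#' Cell density
#'
#' Number of segmented nuclei per square millimetre of ROI.
#'
#' @param seg A `segmentation`.
#' @return Scalar density (nuclei per mm^2).
#' @export
cell_density <- function(seg) {
  if (is.null(seg$roi) || seg$roi$area_um2 <= 0) stop_validation("ROI area must be > 0")
  nrow(seg$nuclei) / (seg$roi$area_um2 / 1e6)
}

#' Compute the four QTP features of a specimen
#'
#' Builds the ROI-clipped tessellation once and returns mean nuclear area,
#' cell density, ENC ratio and 3NDND together with the point counts used.
#'
#' @param seg A `segmentation` with >= 3 nuclei.
#' @param specimen_id,depth_um Optional identifiers copied into the output.
#' @return One-row tibble: `specimen_id`, `depth_um`, `nuclear_area_um2`,
#'   `cell_density_per_mm2`, `enc_ratio`, `nddn3_um`, `n_nuclei`,
#'   `n_interior`.
#' @export
compute_qtp <- function(seg, specimen_id = NA_character_, depth_um = NA_real_) {
  if (nrow(seg$nuclei) < 3L) {
    stop_insufficient("specimen %s: QTP features need >= 3 nuclei, got %d",
                      specimen_id, nrow(seg$nuclei))
  }
  graph <- tryCatch(
    build_tessellation(
      tibble(x = seg$nuclei$centroid_x_um, y = seg$nuclei$centroid_y_um),
      seg$roi
    ),
    error = function(e) {
      abort(sprintf("specimen %s: %s", specimen_id, conditionMessage(e)),
            class = class(e)[1], parent = e)
    }
  )
  tibble(
    specimen_id = specimen_id,
    depth_um = depth_um,
    nuclear_area_um2 = nuclear_area_mean(seg),
    cell_density_per_mm2 = cell_density(seg),
    enc_ratio = enc_ratio(seg, graph),
    nddn3_um = nddn3(graph),
    n_nuclei = nrow(seg$nuclei),
    n_interior = sum(graph$interior)
  )
}
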