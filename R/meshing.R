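# unsigned distance from points to an open polyline (vectorized, chunked)
.dist_to_polyline <- function(points, poly) {
  ax <- poly[-nrow(poly), 1L]; ay <- poly[-nrow(poly), 2L]
  bx <- poly[-1L, 1L]; by <- poly[-1L, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  out <- numeric(nrow(points))
  chunk <- max(1L, floor(4e6 / length(ax)))
  for (i0 in seq(1L, nrow(points), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(points))
    px <- points[idx, 1L]; py <- points[idx, 2L]
    tt <- (outer(px, ax, "-") * rep(dx, each = length(idx)) +
           outer(py, ay, "-") * rep(dy, each = length(idx))) /
      rep(len2, each = length(idx))
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    qx <- rep(ax, each = length(idx)) + tt * rep(dx, each = length(idx))
    qy <- rep(ay, each = length(idx)) + tt * rep(dy, each = length(idx))
    d2 <- (qx - px)^2 + (qy - py)^2
    out[idx] <- sqrt(apply(matrix(d2, nrow = length(idx)), 1L, min))
  }
  out
}

# hexagonal interior lattice clipped to the polygon with a boundary margin
.interior_points <- function(polygon, spacing, margin, jitter, seed,
                             extra_avoid = NULL) {
  xr <- range(polygon[, 1L]); yr <- range(polygon[, 2L])
  dy <- spacing * sqrt(3) / 2
  ys <- seq(yr[1L] + margin / 2, yr[2L], by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(j) {
    off <- if (j %% 2L == 0L) spacing / 2 else 0
    xs <- seq(xr[1L] + margin / 2 + off, xr[2L], by = spacing)
    cbind(xs, ys[j])
  }))
  if (jitter > 0) {
    pts <- .with_seed(seed, pts + matrix(stats::runif(2L * nrow(pts),
                                                      -jitter, jitter),
                                         ncol = 2L))
  }
  ring <- rbind(polygon, polygon[1L, ])
  keep <- pracma::inpolygon(pts[, 1L], pts[, 2L],
                            polygon[, 1L], polygon[, 2L])
  pts <- pts[keep, , drop = FALSE]
  d <- .dist_to_polyline(pts, ring)
  pts <- pts[d >= margin, , drop = FALSE]
  if (!is.null(extra_avoid) && nrow(pts)) {
    d2 <- .dist_to_polyline(pts, extra_avoid)
    pts <- pts[d2 >= margin, , drop = FALSE]
  }
  pts
}

# one damped Laplacian smoothing pass restricted to `movable` vertices
.smooth_points <- function(pts, tris, movable, damp = 0.5) {
  e1 <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  e <- rbind(e1, e1[, 2:1])
  sx <- tapply(pts[e[, 2L], 1L], e[, 1L], mean)
  sy <- tapply(pts[e[, 2L], 2L], e[, 1L], mean)
  idx <- as.integer(names(sx))
  tx <- pts[, 1L]; ty <- pts[, 2L]
  tx[idx] <- (1 - damp) * tx[idx] + damp * sx
  ty[idx] <- (1 - damp) * ty[idx] + damp * sy
  out <- cbind(tx, ty)
  out[!movable, ] <- pts[!movable, ]
  out
}

#' Triangulate a labeled anatomy
#'
#' Unstructured Delaunay meshing of the planar geometry at characteristic
#' length `h`: the labeled boundary is resampled at spacing ~`h`, the interior
#' is seeded with a jittered hexagonal lattice (plus points along the ostium
#' chord so the LA/LAA interface is resolved), triangulated, clipped to the
#' polygon and smoothed. Boundary facets inherit the label of the nearest
#' boundary segment; cells are tagged `LA`/`LAA` by which side of the ostium
#' curve they lie on.
#'
#' @param anatomy an `laa_anatomy` from [generate_anatomy()] or
#'   [polygon_anatomy()].
#' @param h target characteristic cell size (m); must be positive and smaller
#'   than the ostium diameter.
#' @param n_smooth smoothing/retriangulation passes (default 2).
#' @param min_quality minimum accepted cell quality (1 = equilateral).
#' @return an `laa_mesh` with facet and region tags.
#' @export
generate_mesh <- function(anatomy, h, n_smooth = 2L, min_quality = 0.12) {
  stopifnot(inherits(anatomy, "laa_anatomy"))
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("resolution error: h must be a positive length")

  segs <- anatomy$segments
  ns <- length(segs)
  for (k in seq_len(ns)) { # closedness: consecutive endpoints must match
    nxt <- (k %% ns) + 1L
    pend <- segs[[k]]$pts[nrow(segs[[k]]$pts), ]
    pnext <- segs[[nxt]]$pts[1L, ]
    if (sqrt(sum((pend - pnext)^2)) > 1e-9)
      stop("geometry error: boundary outline is not closed")
  }
  if (!is.null(anatomy$ostium)) {
    ost_d <- sqrt(sum((anatomy$ostium[2L, ] - anatomy$ostium[1L, ])^2))
    if (h >= ost_d)
      stop("resolution error: h must be smaller than the ostium diameter")
  }

  # boundary points, each labeled by its source segment
  bnd <- list(); lab <- character(0)
  for (k in seq_len(ns)) {
    rp <- .resample_polyline(segs[[k]]$pts, 0.95 * h)
    rp <- rp[-nrow(rp), , drop = FALSE] # endpoint owned by the next segment
    bnd[[k]] <- rp
    lab <- c(lab, rep(segs[[k]]$label, nrow(rp)))
  }
  bpts <- do.call(rbind, bnd)
  polygon <- bpts

  # internal points on the ostium chord
  opts <- NULL
  if (!is.null(anatomy$ostium)) {
    oc <- .resample_polyline(anatomy$ostium, 0.95 * h)
    if (nrow(oc) > 2L) opts <- oc[-c(1L, nrow(oc)), , drop = FALSE]
  }

  seed <- if (!is.null(anatomy$provenance$seed)) anatomy$provenance$seed else 1L
  ipts <- .interior_points(polygon, h, margin = 0.62 * h, jitter = 0.08 * h,
                           seed = seed, extra_avoid = anatomy$ostium)

  build <- function(ipts) {
    allp <- rbind(bpts, opts, ipts)
    tris <- .cpp_delaunay(allp[, 1L], allp[, 2L])
    cx <- (allp[tris[, 1L], 1L] + allp[tris[, 2L], 1L] + allp[tris[, 3L], 1L]) / 3
    cy <- (allp[tris[, 1L], 2L] + allp[tris[, 2L], 2L] + allp[tris[, 3L], 2L]) / 3
    keep <- pracma::inpolygon(cx, cy, polygon[, 1L], polygon[, 2L])
    list(points = allp, tris = tris[keep, , drop = FALSE])
  }
  tr <- build(ipts)
  if (n_smooth > 0L) {
    nfix <- nrow(bpts) + if (is.null(opts)) 0L else nrow(opts)
    for (pass in seq_len(n_smooth)) {
      movable <- seq_len(nrow(tr$points)) > nfix
      sm <- .smooth_points(tr$points, tr$tris, movable)
      tr <- build(sm[-seq_len(nfix), , drop = FALSE])
    }
  }

  pts <- tr$points; tris <- tr$tris
  used <- sort(unique(as.vector(tris)))
  if (length(used) < nrow(pts)) { # drop orphan points
    remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
    pts <- pts[used, , drop = FALSE]
    tris <- matrix(remap[tris], ncol = 3L)
  }

  ring <- rbind(polygon, polygon[1L, ])
  tag_fun <- function(mx, my) {
    best <- Inf; bl <- "wall"
    for (k in seq_len(ns)) {
      d <- .dist_to_polyline(cbind(mx, my), segs[[k]]$pts)
      if (d < best) { best <- d; bl <- segs[[k]]$label }
    }
    if (best > 0.5 * h)
      stop("geometry error: mesh boundary facet far from the outline")
    bl
  }
  region <- NULL
  if (!is.null(anatomy$laa_polygon)) {
    lp <- anatomy$laa_polygon
    region <- function(cx, cy) pracma::inpolygon(cx, cy, lp[, 1L], lp[, 2L])
  }
  mesh <- laa_mesh(pts, tris, facet_tags = tag_fun, region = region,
                   h = h, ostium = anatomy$ostium, provenance = anatomy)
  if (min(mesh$quality) < min_quality)
    stop(sprintf("meshing error: min cell quality %.3f below threshold %.2f",
                 min(mesh$quality), min_quality))
  mesh
}
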