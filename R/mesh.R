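#' Simplicial mesh container
#'
#' Builds the package's triangular-mesh object: vertices, counter-clockwise
#' triangles, boundary-facet tags and LA/LAA region tags, together with the
#' geometric quantities every downstream consumer needs (P1 basis gradients,
#' cell areas and centroids, face connectivity with oriented normals, lumped
#' mass and stiffness operators).
#'
#' @param vertices numeric matrix (n x 2), coordinates in metres.
#' @param triangles integer matrix (m x 3), 1-based vertex indices.
#' @param facet_tags either a function `f(mx, my)` returning a label for a
#'   boundary facet with midpoint (mx, my), or a single label applied to all
#'   boundary facets. Default tags every boundary facet `"wall"`.
#' @param region either a character vector of length m with values `"LA"` /
#'   `"LAA"`, or a function `f(cx, cy)` of cell centroids, or `NULL`
#'   (everything `"LA"`).
#' @param h characteristic length (m); default is the mean edge length.
#' @param ostium optional 2 x 2 matrix with the endpoints of the internal
#'   curve separating LA from LAA.
#' @param provenance optional object recording how the mesh was built.
#' @return an object of class `laa_mesh`.
#' @export
laa_mesh <- function(vertices, triangles, facet_tags = "wall",
                     region = NULL, h = NULL, ostium = NULL,
                     provenance = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  n <- nrow(vertices); m <- nrow(triangles)
  if (m < 1L) stop("mesh has no cells")
  if (min(triangles) < 1L || max(triangles) > n)
    stop("triangle indices out of range")

  x <- vertices[, 1L]; y <- vertices[, 2L]
  i1 <- triangles[, 1L]; i2 <- triangles[, 2L]; i3 <- triangles[, 3L]
  signed <- 0.5 * ((x[i2] - x[i1]) * (y[i3] - y[i1]) -
                   (x[i3] - x[i1]) * (y[i2] - y[i1]))
  flip <- signed < 0
  if (any(flip)) { # enforce counter-clockwise orientation
    tmp <- triangles[flip, 2L]
    triangles[flip, 2L] <- triangles[flip, 3L]
    triangles[flip, 3L] <- tmp
    i2 <- triangles[, 2L]; i3 <- triangles[, 3L]
    signed <- abs(signed)
  }
  area <- signed
  if (any(area <= 1e-300)) stop("mesh error: degenerate (zero-area) cell")

  # P1 basis gradients, constant per element
  gx <- cbind(y[i2] - y[i3], y[i3] - y[i1], y[i1] - y[i2]) / (2 * area)
  gy <- cbind(x[i3] - x[i2], x[i1] - x[i3], x[i2] - x[i1]) / (2 * area)
  centroid <- cbind((x[i1] + x[i2] + x[i3]) / 3, (y[i1] + y[i2] + y[i3]) / 3)

  l1 <- (x[i2] - x[i3])^2 + (y[i2] - y[i3])^2
  l2 <- (x[i3] - x[i1])^2 + (y[i3] - y[i1])^2
  l3 <- (x[i1] - x[i2])^2 + (y[i1] - y[i2])^2
  quality <- 4 * sqrt(3) * area / (l1 + l2 + l3)
  he <- sqrt(4 * area / sqrt(3))

  faces <- .build_faces(triangles, x, y)
  nb <- sum(faces$right == 0L)
  if (is.function(facet_tags)) {
    tags <- rep(NA_character_, length(faces$left))
    bidx <- which(faces$right == 0L)
    tags[bidx] <- vapply(bidx, function(f)
      facet_tags(faces$mx[f], faces$my[f]), character(1L))
  } else if (length(facet_tags) == 1L) {
    tags <- ifelse(faces$right == 0L, facet_tags, NA_character_)
  } else if (length(facet_tags) == sum(faces$right == 0L)) {
    tags <- rep(NA_character_, length(faces$left))
    tags[faces$right == 0L] <- facet_tags
  } else {
    stop("facet_tags must be a function, a single label, or one label per boundary facet")
  }
  if (anyNA(tags[faces$right == 0L]))
    stop("tagging error: boundary facet without a tag")
  faces$tag <- tags

  if (is.null(region)) {
    region <- rep("LA", m)
  } else if (is.function(region)) {
    region <- ifelse(vapply(seq_len(m), function(e)
      isTRUE(region(centroid[e, 1L], centroid[e, 2L])), logical(1L)), "LAA", "LA")
  }
  region <- as.character(region)
  if (length(region) != m || anyNA(region) || !all(region %in% c("LA", "LAA")))
    stop("tagging error: region tags must cover all cells with 'LA'/'LAA'")

  if (is.null(h)) h <- mean(sqrt(c(l1, l2, l3)))

  mesh <- list(
    vertices = vertices, triangles = triangles,
    area = area, centroid = centroid, gx = gx, gy = gy,
    he = he, quality = quality, faces = faces, region = region,
    h = h, ostium = ostium, provenance = provenance
  )
  mesh$operators <- .build_operators(mesh)
  class(mesh) <- "laa_mesh"
  mesh
}

# face connectivity: oriented interior + boundary edges.
# Normal (nxl, nyl) has length = edge length and points out of `left`
# (toward `right` for interior faces).
.build_faces <- function(triangles, x, y) {
  m <- nrow(triangles)
  ea <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  eb <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  own <- rep(seq_len(m), 3L)
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  first <- !duplicated(key)
  fid <- match(key, key[first])
  nf <- sum(first)
  n1 <- ea[first]; n2 <- eb[first]
  left <- own[first]
  right <- integer(nf)
  dup <- which(!first)
  right[fid[dup]] <- own[dup]
  cnt <- tabulate(fid, nf)
  if (any(cnt > 2L)) stop("geometry error: non-manifold edge")
  nxl <- y[n2] - y[n1]
  nyl <- -(x[n2] - x[n1])
  list(n1 = n1, n2 = n2, left = left, right = right,
       nxl = nxl, nyl = nyl,
       mx = 0.5 * (x[n1] + x[n2]), my = 0.5 * (y[n1] + y[n2]),
       len = sqrt(nxl^2 + nyl^2))
}

# sparse P1 operators: stiffness K, lumped mass, and the weak derivative
# matrices (Gx)_{ij} = int phi_i d(phi_j)/dx (same matrix serves pressure
# gradients and the weak divergence).
.build_operators <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(tri); n <- nrow(mesh$vertices)
  A <- mesh$area
  ii <- rep(as.vector(tri), 3L)
  jj <- as.vector(tri[, rep(1:3, each = 3L)])
  loc_i <- rep(rep(1:3, each = m), 3L)
  loc_j <- rep(1:3, each = 3L * m)
  gxv <- mesh$gx; gyv <- mesh$gy
  Ar <- rep(A, 9L)
  kv <- Ar * (gxv[cbind(rep(seq_len(m), 9L), loc_i)] *
              gxv[cbind(rep(seq_len(m), 9L), loc_j)] +
              gyv[cbind(rep(seq_len(m), 9L), loc_i)] *
              gyv[cbind(rep(seq_len(m), 9L), loc_j)])
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kv, dims = c(n, n))
  gxvals <- (Ar / 3) * gxv[cbind(rep(seq_len(m), 9L), loc_j)]
  gyvals <- (Ar / 3) * gyv[cbind(rep(seq_len(m), 9L), loc_j)]
  Gx <- Matrix::sparseMatrix(i = ii, j = jj, x = gxvals, dims = c(n, n))
  Gy <- Matrix::sparseMatrix(i = ii, j = jj, x = gyvals, dims = c(n, n))
  Ml <- as.vector(Matrix::sparseMatrix(i = as.vector(tri),
                                       j = rep(1L, 3L * m),
                                       x = rep(A / 3, 3L), dims = c(n, 1L)))
  list(K = K, Gx = Gx, Gy = Gy, Mlump = Ml)
}

#' @export
print.laa_mesh <- function(x, ...) {
  cat(sprintf("laa_mesh: %d vertices, %d triangles (h = %.3g m)\n",
              nrow(x$vertices), nrow(x$triangles), x$h))
  cat(sprintf("  regions: LA %d cells, LAA %d cells\n",
              sum(x$region == "LA"), sum(x$region == "LAA")))
  bt <- x$faces$tag[x$faces$right == 0L]
  cat("  boundary facets:",
      paste(sprintf("%s (%d)", names(table(bt)), table(bt)), collapse = ", "),
      "\n")
  cat(sprintf("  min cell quality: %.3f\n", min(x$quality)))
  invisible(x)
}

#' Structured triangulation of a rectangle
#'
#' A deterministic, mirror-symmetric triangular mesh of
#' `[x0, x0+Lx] x [y0, y0+Ly]`, used for solver verification on canonical
#' domains (channels, cavities, unit squares). Cell diagonals alternate so
#' that, for even `ny`, the mesh is symmetric about the horizontal mid-axis.
#'
#' @param nx,ny number of cells along x and y (each >= 1).
#' @param Lx,Ly side lengths (m).
#' @param x0,y0 origin.
#' @param facet_tags,region as in [laa_mesh()].
#' @return an `laa_mesh`.
#' @export
structured_rect_mesh <- function(nx, ny, Lx = 1, Ly = 1, x0 = 0, y0 = 0,
                                 facet_tags = "wall", region = NULL) {
  stopifnot(nx >= 1L, ny >= 1L, Lx > 0, Ly > 0)
  xs <- seq(x0, x0 + Lx, length.out = nx + 1L)
  ys <- seq(y0, y0 + Ly, length.out = ny + 1L)
  g <- expand.grid(x = xs, y = ys)
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- matrix(0L, 2L * nx * ny, 3L)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      a <- vid(i, j); b <- vid(i + 1L, j)
      c2 <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
      if ((i + j) %% 2L == 0L) {
        tris[k + 1L, ] <- c(a, b, c2); tris[k + 2L, ] <- c(a, c2, d)
      } else {
        tris[k + 1L, ] <- c(a, b, d); tris[k + 2L, ] <- c(b, c2, d)
      }
      k <- k + 2L
    }
  }
  laa_mesh(as.matrix(g), tris, facet_tags = facet_tags, region = region,
           h = max(Lx / nx, Ly / ny))
}

#' Region measures of a tagged mesh
#'
#' Exact sums of cell areas per region; in this planar model "volumes" are
#' areas (m^2). Used to normalize appendage integrals and residual-contrast
#' percentages.
#'
#' @param mesh an `laa_mesh`.
#' @return named list with `V_LA`, `V_LAA` and `V_domain`.
#' @export
region_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "laa_mesh"))
  if (is.null(mesh$region) || anyNA(mesh$region))
    stop("tagging error: untagged cells")
  V_LA <- sum(mesh$area[mesh$region == "LA"])
  V_LAA <- sum(mesh$area[mesh$region == "LAA"])
  list(V_LA = V_LA, V_LAA = V_LAA, V_domain = V_LA + V_LAA)
}

# centroid of the internal LA|LAA interface (the ostium curve), computed
# from the mesh itself: length-weighted mean of interface face midpoints.
.interface_centroid <- function(mesh) {
  f <- mesh$faces
  int <- f$right != 0L
  ra <- mesh$region[f$left]
  rb <- rep(NA_character_, length(f$left))
  rb[int] <- mesh$region[f$right[int]]
  sep <- which(int & ra != rb)
  if (!length(sep)) return(NULL)
  w <- f$len[sep]
  c(sum(f$mx[sep] * w), sum(f$my[sep] * w)) / sum(w)
}

# interpolate a vertex field at arbitrary points (barycentric);
# cell fields take the containing cell's value.
.interp_at <- function(points, field, mesh, tol = 1e-9) {
  loc <- .cpp_locate_points(points[, 1L], points[, 2L], mesh$triangles,
                            mesh$vertices[, 1L], mesh$vertices[, 2L],
                            tol = 0.05)
  if (any(loc$triangle == 0L))
    stop("interpolation error: point outside mesh")
  if (length(field) == nrow(mesh$vertices)) {
    tri <- mesh$triangles[loc$triangle, , drop = FALSE]
    rowSums(loc$bary * cbind(field[tri[, 1L]], field[tri[, 2L]],
                             field[tri[, 3L]]))
  } else if (length(field) == nrow(mesh$triangles)) {
    field[loc$triangle]
  } else stop("field length matches neither vertices nor cells")
}
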