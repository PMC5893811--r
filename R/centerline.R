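#' Extract the ostium-to-tip centerline of the appendage
#'
#' Builds the profiling line used for all along-appendage quantities: it
#' starts at the centre of the ostium curve (s = 0) and ends at the LAA tip
#' (s = 1), passing through the centre of gravity of successive appendage
#' cross-sections. Cross-sections are defined as bands of equal geodesic
#' distance from the ostium over the LAA cell-adjacency graph, which remains
#' well defined in bent and multi-lobed appendages; when a band is multiply
#' connected, the connected component containing (the projection of) the
#' previous station is followed, keeping the line path-connected from ostium
#' to tip.
#'
#' @param mesh an `laa_mesh` with a nonempty LAA region.
#' @param n_stations number of stations (>= 8).
#' @return an object of class `laa_centerline`: a data.frame with columns
#'   `x`, `y`, `s` (normalized arclength, strictly increasing from 0 to 1).
#' @export
extract_centerline <- function(mesh, n_stations = 24L) {
  stopifnot(inherits(mesh, "laa_mesh"))
  if (n_stations < 8L)
    stop("argument error: n_stations must be at least 8")
  laa <- which(mesh$region == "LAA")
  if (!length(laa)) stop("region error: mesh has no LAA cells")

  f <- mesh$faces
  int <- which(f$right != 0L)
  rl <- mesh$region[f$left[int]]
  rr <- mesh$region[f$right[int]]
  both_laa <- int[rl == "LAA" & rr == "LAA"]
  cross <- int[rl != rr]
  if (!length(cross))
    stop("region error: no LA/LAA interface (ostium) found")
  ostium_centroid <- .interface_centroid(mesh)

  # cell adjacency graph of the LAA, edge weight = centroid distance
  idx <- integer(nrow(mesh$triangles)); idx[laa] <- seq_along(laa)
  el <- cbind(idx[f$left[both_laa]], idx[f$right[both_laa]])
  w <- sqrt((mesh$centroid[f$left[both_laa], 1L] -
             mesh$centroid[f$right[both_laa], 1L])^2 +
            (mesh$centroid[f$left[both_laa], 2L] -
             mesh$centroid[f$right[both_laa], 2L])^2)
  seeds <- idx[ifelse(rl[match(cross, int)] == "LAA",
                      f$left[cross], f$right[cross])]
  nv <- length(laa) + 1L # extra virtual source vertex
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  g <- igraph::add_edges(g, t(rbind(el,
                                    cbind(rep(nv, length(seeds)), seeds))))
  igraph::E(g)$weight <- c(w, rep(1e-12, length(seeds)))
  d <- as.vector(igraph::distances(g, v = nv))[seq_along(laa)]
  if (any(!is.finite(d)))
    d[!is.finite(d)] <- max(d[is.finite(d)]) # isolated slivers: park at tip

  dmax <- max(d)
  breaks <- seq(0, dmax, length.out = n_stations)
  band <- pmin(n_stations - 1L, pmax(1L, findInterval(d, breaks,
                                                      rightmost.closed = TRUE)))
  stations <- matrix(NA_real_, n_stations, 2L)
  stations[1L, ] <- ostium_centroid
  prev <- ostium_centroid
  areas <- mesh$area[laa]
  cents <- mesh$centroid[laa, , drop = FALSE]
  for (k in seq(2L, n_stations)) {
    cells <- which(band == k - 1L)
    if (!length(cells)) { stations[k, ] <- NA; next }
    # connected components of the band; follow the one holding the previous
    # station's nearest cell
    sub <- igraph::induced_subgraph(g, cells)
    comp <- igraph::components(sub)$membership
    dprev <- (cents[cells, 1L] - prev[1L])^2 + (cents[cells, 2L] - prev[2L])^2
    pick <- comp == comp[which.min(dprev)]
    cc <- cells[pick]
    ctr <- c(sum(cents[cc, 1L] * areas[cc]),
             sum(cents[cc, 2L] * areas[cc])) / sum(areas[cc])
    # keep the station inside the appendage
    loc <- .cpp_locate_points(ctr[1L], ctr[2L], mesh$triangles,
                              mesh$vertices[, 1L], mesh$vertices[, 2L], 0)
    inside <- loc$triangle != 0L && mesh$region[loc$triangle] == "LAA"
    if (!inside) ctr <- cents[cc[which.min(
      (cents[cc, 1L] - ctr[1L])^2 + (cents[cc, 2L] - ctr[2L])^2)], ]
    stations[k, ] <- ctr
    prev <- ctr
  }
  ok <- stats::complete.cases(stations)
  stations <- stations[ok, , drop = FALSE]
  # enforce strictly increasing arclength (merge coincident stations)
  keep <- c(TRUE, sqrt(diff(stations[, 1L])^2 +
                       diff(stations[, 2L])^2) > 1e-12)
  stations <- stations[keep, , drop = FALSE]
  if (nrow(stations) < 8L)
    stop("region error: appendage too small for a centerline at this resolution")
  arc <- c(0, cumsum(sqrt(diff(stations[, 1L])^2 + diff(stations[, 2L])^2)))
  out <- data.frame(x = stations[, 1L], y = stations[, 2L],
                    s = arc / arc[length(arc)])
  class(out) <- c("laa_centerline", "data.frame")
  attr(out, "arclength") <- arc[length(arc)]
  out
}

#' Write a centerline to CSV
#'
#' @param centerline an `laa_centerline`.
#' @param file output path.
#' @export
write_centerline_csv <- function(centerline, file) {
  df <- as.data.frame(centerline)
  df <- cbind(station = seq_len(nrow(df)), df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
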