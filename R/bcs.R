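#' Assemble the boundary-condition set
#'
#' Partitions the tagged boundary facets of a mesh into the three families
#' the flow model uses: rigid no-slip walls, pulmonary-vein inlets held at
#' the reference pressure 0 Pa (traction-free open boundaries, so the
#' pressure field is gauged there and the flow split across veins is an
#' outcome, not an input), and the mitral orifice carrying the prescribed
#' plug-velocity waveform of the chosen rhythm condition.
#'
#' @param mesh an `laa_mesh` with tagged boundary facets (`wall`, `pv_*`,
#'   `mitral`).
#' @param condition `"healthy"` or `"af"`; ignored when `waveform` is given.
#' @param waveform optional [mitral_waveform()] overriding the default for
#'   the condition.
#' @return an object of class `laa_bcset` with facet and node index sets and
#'   the outward mitral plug direction.
#' @export
assemble_bcs <- function(mesh, condition = c("healthy", "af"),
                         waveform = NULL) {
  stopifnot(inherits(mesh, "laa_mesh"))
  condition <- match.arg(condition)
  if (is.null(waveform)) waveform <- mitral_waveform(condition)
  stopifnot(inherits(waveform, "laa_waveform"))

  f <- mesh$faces
  bidx <- which(f$right == 0L)
  tags <- f$tag[bidx]
  known <- tags == "wall" | tags == "mitral" | grepl("^pv_[0-9]+$", tags)
  if (any(!known))
    stop("tagging error: unknown boundary label(s): ",
         paste(unique(tags[!known]), collapse = ", "))

  wall_facets <- bidx[tags == "wall"]
  mitral_facets <- bidx[tags == "mitral"]
  pv_labels <- sort(unique(tags[grepl("^pv_", tags)]))
  pv_facets <- lapply(pv_labels, function(l) bidx[tags == l])
  names(pv_facets) <- pv_labels

  nodes_of <- function(facets)
    sort(unique(c(f$n1[facets], f$n2[facets])))
  wall_nodes <- nodes_of(wall_facets)
  mitral_nodes <- setdiff(nodes_of(mitral_facets), wall_nodes)
  pv_nodes <- setdiff(nodes_of(unlist(pv_facets)), wall_nodes)

  # outward plug direction: facet-length-weighted mean outward normal
  if (length(mitral_facets)) {
    nx <- sum(f$nxl[mitral_facets]); ny <- sum(f$nyl[mitral_facets])
    plug <- c(nx, ny) / sqrt(nx^2 + ny^2)
  } else plug <- c(0, 0)

  out <- list(wall_facets = wall_facets, pv_facets = pv_facets,
              mitral_facets = mitral_facets,
              wall_nodes = wall_nodes, mitral_nodes = mitral_nodes,
              pv_nodes = pv_nodes, plug_direction = plug,
              p_pv = 0, waveform = waveform, condition = waveform$condition)
  class(out) <- "laa_bcset"
  out
}

#' @export
print.laa_bcset <- function(x, ...) {
  cat(sprintf("laa_bcset [%s]: %d wall facets, %d PV inlets (%d facets), %d mitral facets\n",
              x$condition, length(x$wall_facets), length(x$pv_facets),
              length(unlist(x$pv_facets)), length(x$mitral_facets)))
  cat(sprintf("  PV pressure %.0f Pa; plug direction (%.2f, %.2f)\n",
              x$p_pv, x$plug_direction[1L], x$plug_direction[2L]))
  invisible(x)
}
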