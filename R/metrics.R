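# cell-wise SSR from nodal velocity: sqrt(2 D:D) with D = sym(grad u),
# exact for the piecewise-linear velocity of the P1 discretization
.ssr_cells <- function(mesh, u, v) {
  tri <- mesh$triangles
  dudx <- rowSums(mesh$gx * cbind(u[tri[, 1L]], u[tri[, 2L]], u[tri[, 3L]]))
  dudy <- rowSums(mesh$gy * cbind(u[tri[, 1L]], u[tri[, 2L]], u[tri[, 3L]]))
  dvdx <- rowSums(mesh$gx * cbind(v[tri[, 1L]], v[tri[, 2L]], v[tri[, 3L]]))
  dvdy <- rowSums(mesh$gy * cbind(v[tri[, 1L]], v[tri[, 2L]], v[tri[, 3L]]))
  sqrt(2 * (dudx^2 + dvdy^2) + (dudy + dvdx)^2)
}

#' Shear strain rate field
#'
#' The scalar invariant `SSR = sqrt(2 D : D)` of the symmetric part `D` of the
#' velocity gradient, computed cell-wise (the gradient of a P1 velocity is
#' constant per triangle, so the formula is exact for the discrete field).
#' Uniform flow and rigid rotation give zero; simple shear `u = (g y, 0)`
#' gives `SSR = g`.
#'
#' @param velocity either a list with nodal vectors `u` and `v`, or an
#'   n x 2 matrix.
#' @param mesh an `laa_mesh`.
#' @return cell-wise SSR values (1/s), nonnegative.
#' @export
ssr_field <- function(velocity, mesh) {
  stopifnot(inherits(mesh, "laa_mesh"))
  if (is.matrix(velocity)) velocity <- list(u = velocity[, 1L],
                                            v = velocity[, 2L])
  if (length(velocity$u) != nrow(mesh$vertices))
    stop("velocity must be defined at the mesh vertices")
  if (any(mesh$area <= 0)) stop("mesh error: degenerate cell")
  .ssr_cells(mesh, velocity$u, velocity$v)
}

#' Sample a field along the centerline
#'
#' Interpolates a scalar field at each centerline station: barycentric
#' interpolation for vertex fields, containing-cell value for cell fields.
#'
#' @param field numeric vector on vertices or cells.
#' @param centerline an [extract_centerline()] result.
#' @param mesh the `laa_mesh` the field lives on.
#' @return data.frame with columns `s` and `value`, ordered by `s`.
#' @export
centerline_profile <- function(field, centerline, mesh) {
  stopifnot(inherits(mesh, "laa_mesh"),
            inherits(centerline, "laa_centerline"))
  pts <- cbind(centerline$x, centerline$y)
  vals <- .interp_at(pts, field, mesh)
  data.frame(s = centerline$s, value = vals)
}

#' Region-normalized volume integral
#'
#' `(integral of the field over the region) / (region measure)`: the mean of
#' the field over the LAA (or LA, or the whole domain), the quantity used to
#' compare appendage velocity and SSR levels across rhythm conditions.
#' Vertex fields are integrated with the cell-midpoint rule (exact for affine
#' fields); cell fields exactly.
#'
#' @param field numeric vector on vertices or cells.
#' @param mesh an `laa_mesh`.
#' @param region `"LAA"`, `"LA"` or `"domain"`.
#' @return the normalized integral (same units as the field).
#' @export
normalized_volume_integral <- function(field, mesh,
                                       region = c("LAA", "LA", "domain")) {
  stopifnot(inherits(mesh, "laa_mesh"))
  region <- match.arg(region)
  cells <- switch(region,
                  LAA = which(mesh$region == "LAA"),
                  LA = which(mesh$region == "LA"),
                  domain = seq_len(nrow(mesh$triangles)))
  if (!length(cells)) stop("region error: region '", region, "' is empty")
  fc <- .cell_values(field, mesh)
  sum(fc[cells] * mesh$area[cells]) / sum(mesh$area[cells])
}

# reduce a field to cell values (vertex fields: midpoint rule)
.cell_values <- function(field, mesh) {
  m <- nrow(mesh$triangles); n <- nrow(mesh$vertices)
  if (length(field) == m) return(field)
  if (length(field) == n) {
    tri <- mesh$triangles
    return((field[tri[, 1L]] + field[tri[, 2L]] + field[tri[, 3L]]) / 3)
  }
  stop("field length matches neither vertices nor cells")
}

#' Residual contrast percentage
#'
#' `100 * (integral of c over the domain) / V_norm`, the washout surrogate for
#' residence time: with domain normalization this is the percentage of the
#' initial contrast volume still present; the LAA-normalized variant
#' references the appendage volume instead.
#'
#' @param c cell-wise concentrations in `[0, 1]`.
#' @param mesh an `laa_mesh`.
#' @param normalization `"domain"` or `"laa"`.
#' @return percentage in `[0, 100]` (laa normalization may exceed 100 only if
#'   contrast from the rest of the domain exceeds the appendage volume).
#' @export
residual_contrast <- function(c, mesh, normalization = c("domain", "laa")) {
  stopifnot(inherits(mesh, "laa_mesh"))
  normalization <- match.arg(normalization)
  if (length(c) != nrow(mesh$triangles))
    stop("field error: c must be cell-wise")
  tol <- 1e-6
  if (min(c) < -tol || max(c) > 1 + tol)
    stop("field error: concentrations outside [0, 1]")
  vols <- region_volumes(mesh)
  Vn <- if (normalization == "domain") vols$V_domain else vols$V_LAA
  if (Vn <= 0) stop("region error: empty normalization region")
  100 * sum(c * mesh$area) / Vn
}

#' Arclength localization of the residual dye
#'
#' The concentration-weighted mean of the normalized centerline arclength
#' over the appendage: each LAA cell is assigned the `s` of its nearest
#' centerline station, and the weights are `c * area`. Values near 1 mean the
#' remaining dye sits at the appendage tip; a uniform distribution along a
#' straight uniform-width appendage gives 0.5. Invariant under uniform
#' scaling of `c`.
#'
#' @param c cell-wise concentrations.
#' @param centerline an [extract_centerline()] result.
#' @param mesh the tagged `laa_mesh`.
#' @return normalized arclength in `[0, 1]`.
#' @export
dye_localization <- function(c, centerline, mesh) {
  stopifnot(inherits(mesh, "laa_mesh"),
            inherits(centerline, "laa_centerline"))
  laa <- which(mesh$region == "LAA")
  if (!length(laa)) stop("region error: mesh has no LAA cells")
  if (length(c) != nrow(mesh$triangles))
    stop("field error: c must be cell-wise")
  w <- c[laa] * mesh$area[laa]
  if (sum(w) <= 1e-300)
    stop("undefined-localization error: no dye left in the LAA")
  cx <- mesh$centroid[laa, 1L]; cy <- mesh$centroid[laa, 2L]
  d2 <- outer(cx, centerline$x, function(a, b) (a - b)^2) +
    outer(cy, centerline$y, function(a, b) (a - b)^2)
  s_cell <- centerline$s[max.col(-d2, ties.method = "first")]
  sum(w * s_cell) / sum(w)
}

#' Cycle-to-cycle periodicity metric
#'
#' Relative L2 difference of the velocity fields of two cycles, averaged over
#' the matched snapshot phases: `mean_k ||u_b(k) - u_a(k)||_M / ||u_a(k)||_M`
#' with the lumped-mass norm. Zero for identical cycles; the flow is
#' considered periodic when the metric falls below the configured threshold.
#'
#' @param run an `laa_flow_run` (or a list with `snapshots` and `mesh`).
#' @param cycle_a,cycle_b cycle indices (1-based).
#' @return dimensionless metric.
#' @export
periodicity_metric <- function(run, cycle_a, cycle_b) {
  snaps <- run$snapshots
  if (cycle_a < 1L || cycle_b < 1L || cycle_a > length(snaps) ||
      cycle_b > length(snaps))
    stop("argument error: cycle index out of range")
  sa <- snaps[[cycle_a]]; sb <- snaps[[cycle_b]]
  ok <- !vapply(sa, is.null, logical(1L)) & !vapply(sb, is.null, logical(1L))
  if (!any(ok)) stop("argument error: no matched snapshot phases recorded")
  Ml <- run$mesh$operators$Mlump
  vals <- vapply(which(ok), function(k) {
    den <- sqrt(sum(Ml * (sa[[k]]$u^2 + sa[[k]]$v^2)))
    num <- sqrt(sum(Ml * ((sb[[k]]$u - sa[[k]]$u)^2 +
                          (sb[[k]]$v - sa[[k]]$v)^2)))
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
  }, numeric(1L))
  mean(vals)
}

#' Summarize a washout run into the stasis metrics
#'
#' Aggregates the per-run quantities used to rank thrombosis risk:
#' LAA-normalized velocity and SSR integrals and their ostium-to-tip
#' centerline profiles, all evaluated at the late-diastolic (A-wave peak)
#' phase of the final cycle — the cycle phase at which the two rhythm
#' conditions differ most and the phase convention the comparison figures
#' use; the residual-contrast percentages (domain- and LAA-normalized); the
#' arclength localization of the remaining dye; and the cycle-to-cycle
#' periodicity metric of the last two cycles. The stationary-window time
#' averages of |v| and SSR remain available in `run$time_avg` as
#' diagnostics.
#'
#' @param run an `laa_flow_run`.
#' @param centerline an [extract_centerline()] result for the run's mesh.
#' @param morphology_class optional label recorded in the summary.
#' @return an object of class `stasis_summary`.
#' @export
summarize_run <- function(run, centerline, morphology_class = NULL) {
  stopifnot(inherits(run, "laa_flow_run"),
            inherits(centerline, "laa_centerline"))
  mesh <- run$mesh
  if (is.null(morphology_class) && inherits(mesh$provenance, "laa_anatomy"))
    morphology_class <- mesh$provenance$provenance$morphology_class
  # late-diastolic snapshot: recorded phase nearest the A-wave peak time
  wf <- run$bcs$waveform
  target <- unname(wf$A_timing["center"]) / wf$T
  last <- run$snapshots[[run$config$n_cycles]]
  avail <- which(!vapply(last, is.null, logical(1L)))
  if (!length(avail)) stop("pipeline error: no snapshots recorded")
  ph <- avail[which.min(abs(run$phases[avail] - target))]
  snap <- last[[ph]]
  vmag <- sqrt(snap$u^2 + snap$v^2)
  ssr <- .ssr_cells(mesh, snap$u, snap$v)
  nm <- nrow(run$metrics)
  nc <- run$config$n_cycles
  per <- if (nc >= 2L) periodicity_metric(run, nc - 1L, nc) else NA_real_
  out <- list(
    condition = run$bcs$condition,
    morphology_class = morphology_class,
    mean_velocity_LAA = normalized_volume_integral(vmag, mesh, "LAA"),
    mean_ssr_LAA = normalized_volume_integral(ssr, mesh, "LAA"),
    residual_contrast_domain = residual_contrast(run$state$c, mesh, "domain"),
    residual_contrast_laa = residual_contrast(run$state$c, mesh, "laa"),
    dye_localization = dye_localization(run$state$c, centerline, mesh),
    centerline_velocity = centerline_profile(vmag, centerline, mesh),
    centerline_ssr = centerline_profile(ssr, centerline, mesh),
    periodicity_metric = per,
    snapshot_phase = run$phases[ph],
    n_cycles = nc, dt = run$config$dt,
    n_cells = nrow(mesh$triangles), h = mesh$h
  )
  class(out) <- "stasis_summary"
  out
}

#' @export
print.stasis_summary <- function(x, ...) {
  cat(sprintf("stasis_summary: %s / %s\n",
              x$morphology_class %||% "?", x$condition))
  cat(sprintf("  mean |v| over LAA : %.4g m/s\n", x$mean_velocity_LAA))
  cat(sprintf("  mean SSR over LAA : %.4g 1/s\n", x$mean_ssr_LAA))
  cat(sprintf("  residual contrast : %.3f %% (domain), %.2f %% (LAA)\n",
              x$residual_contrast_domain, x$residual_contrast_laa))
  cat(sprintf("  dye localization  : %.3f (0 = ostium, 1 = tip)\n",
              x$dye_localization))
  cat(sprintf("  periodicity       : %.4f\n", x$periodicity_metric))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
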