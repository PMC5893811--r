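#' Parametric anatomy specification
#'
#' Describes one synthetic planar left atrium + appendage geometry. The four
#' morphology classes follow the clinical naming: a bent dominant lobe
#' ("chicken wing"), a central lobe with secondary lobes ("cactus"), one
#' dominant tapering lobe ("windsock") and a short multi-lobed irregular sac
#' ("cauliflower"). All lengths are in metres; defaults give an atrium of
#' about 5 cm diameter with a 2-4 cm appendage, and the per-class pulmonary
#' vein counts follow the reference anatomies (4, 5, 6, 4).
#'
#' @param morphology_class one of `"chicken_wing"`, `"cactus"`, `"windsock"`,
#'   `"cauliflower"`.
#' @param la_diameter atrial body diameter (m).
#' @param laa_length appendage length from ostium to tip (m); class default
#'   when `NULL` (cauliflower is the shortest, windsock the longest).
#' @param ostium_diameter ostium width (m); must be smaller than `la_diameter`.
#' @param bend_angle chicken-wing bend (degrees).
#' @param n_lobes number of secondary lobes (cactus) or surface lobes
#'   (cauliflower).
#' @param taper_ratio tip-to-ostium width ratio for the windsock lobe.
#' @param n_pv_inlets number of pulmonary-vein inlets (2-6); class default
#'   when `NULL`.
#' @param mitral_diameter mitral orifice width (m).
#' @param pv_diameter pulmonary-vein opening width (m).
#' @param seed integer; fully determines the geometry.
#' @return an object of class `laa_anatomy_spec`.
#' @export
anatomy_spec <- function(morphology_class,
                         la_diameter = 0.05,
                         laa_length = NULL,
                         ostium_diameter = 0.012,
                         bend_angle = 100,
                         n_lobes = NULL,
                         taper_ratio = 0.25,
                         n_pv_inlets = NULL,
                         mitral_diameter = 0.025,
                         pv_diameter = 0.007,
                         seed = 1L) {
  classes <- c("chicken_wing", "cactus", "windsock", "cauliflower")
  if (!is.character(morphology_class) || !(morphology_class %in% classes))
    stop("invalid-spec error: unknown morphology class '",
         paste(morphology_class, collapse = ","), "'")
  defaults <- list(
    chicken_wing = list(laa_length = 0.030, n_pv = 4L, n_lobes = 1L),
    cactus       = list(laa_length = 0.028, n_pv = 5L, n_lobes = 3L),
    windsock     = list(laa_length = 0.035, n_pv = 6L, n_lobes = 1L),
    cauliflower  = list(laa_length = 0.020, n_pv = 4L, n_lobes = 4L)
  )[[morphology_class]]
  if (is.null(laa_length)) laa_length <- defaults$laa_length
  if (is.null(n_pv_inlets)) n_pv_inlets <- defaults$n_pv
  if (is.null(n_lobes)) n_lobes <- defaults$n_lobes

  lens <- c(la_diameter = la_diameter, laa_length = laa_length,
            ostium_diameter = ostium_diameter,
            mitral_diameter = mitral_diameter, pv_diameter = pv_diameter)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("invalid-spec error: all lengths must be positive (",
         paste(names(lens)[!is.finite(lens) | lens <= 0], collapse = ", "), ")")
  if (ostium_diameter >= la_diameter)
    stop("invalid-spec error: ostium_diameter must be smaller than la_diameter")
  if (n_pv_inlets < 2L || n_pv_inlets > 6L)
    stop("invalid-spec error: n_pv_inlets must be in [2, 6]")
  if (morphology_class == "cauliflower" && n_lobes < 3L)
    stop("invalid-spec error: cauliflower requires n_lobes >= 3")
  if (taper_ratio <= 0 || taper_ratio >= 1)
    stop("invalid-spec error: taper_ratio must lie in (0, 1)")

  spec <- list(morphology_class = morphology_class,
               la_diameter = la_diameter, laa_length = laa_length,
               ostium_diameter = ostium_diameter, bend_angle = bend_angle,
               n_lobes = as.integer(n_lobes), taper_ratio = taper_ratio,
               n_pv_inlets = as.integer(n_pv_inlets),
               mitral_diameter = mitral_diameter, pv_diameter = pv_diameter,
               seed = as.integer(seed))
  class(spec) <- "laa_anatomy_spec"
  spec
}

#' Default anatomy specifications for the four morphology classes
#'
#' @param seed integer seed shared by the four specs.
#' @return named list of `laa_anatomy_spec` objects.
#' @export
default_anatomy_specs <- function(seed = 1L) {
  cls <- c("chicken_wing", "cactus", "windsock", "cauliflower")
  stats::setNames(lapply(cls, anatomy_spec, seed = seed), cls)
}

# smooth 0->1 ramp on [0,1]
.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# run `expr` under a deterministic RNG stream without disturbing the caller's
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# arclength-resample an open polyline at spacing <= target; endpoints and
# sharp corners (turn > 30 degrees) are preserved exactly
.resample_polyline <- function(pts, spacing) {
  n <- nrow(pts)
  keep_corner <- rep(FALSE, n)
  if (n >= 3L) {
    d1 <- pts[2:(n - 1L), , drop = FALSE] - pts[1:(n - 2L), , drop = FALSE]
    d2 <- pts[3:n, , drop = FALSE] - pts[2:(n - 1L), , drop = FALSE]
    dot <- rowSums(d1 * d2) /
      pmax(sqrt(rowSums(d1^2)) * sqrt(rowSums(d2^2)), 1e-300)
    keep_corner[2:(n - 1L)] <- dot < cos(30 * pi / 180)
  }
  brk <- c(1L, which(keep_corner), n)
  out <- NULL
  for (k in seq_len(length(brk) - 1L)) {
    piece <- pts[brk[k]:brk[k + 1L], , drop = FALSE]
    seg <- sqrt(diff(piece[, 1L])^2 + diff(piece[, 2L])^2)
    s <- c(0, cumsum(seg))
    L <- s[length(s)]
    rp <- if (L <= 0) piece[c(1L, nrow(piece)), , drop = FALSE] else {
      nseg <- max(1L, ceiling(L / spacing))
      snew <- seq(0, L, length.out = nseg + 1L)
      cbind(stats::approx(s, piece[, 1L], xout = snew)$y,
            stats::approx(s, piece[, 2L], xout = snew)$y)
    }
    out <- if (is.null(out)) rp else rbind(out[-nrow(out), , drop = FALSE], rp)
  }
  out
}

# all-pairs segment intersection test for a closed polygon (adjacent
# segments excluded); polygon decimated to keep the O(n^2) check cheap.
.polygon_is_simple <- function(pts, max_segments = 700L) {
  n <- nrow(pts)
  if (n > max_segments) {
    keep <- unique(c(seq(1L, n, by = ceiling(n / max_segments)), n))
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
  }
  a <- pts
  b <- pts[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n] # wrap-adjacency
    d1x <- b[i, 1L] - a[i, 1L]; d1y <- b[i, 2L] - a[i, 2L]
    d2x <- b[j, 1L] - a[j, 1L]; d2y <- b[j, 2L] - a[j, 2L]
    ex <- a[j, 1L] - a[i, 1L]; ey <- a[j, 2L] - a[i, 2L]
    den <- d1x * d2y - d1y * d2x
    ok <- abs(den) > 1e-30
    t1 <- (ex * d2y - ey * d2x) / den
    t2 <- (ex * d1y - ey * d1x) / den
    hit <- ok & t1 > 1e-9 & t1 < 1 - 1e-9 & t2 > 1e-9 & t2 < 1 - 1e-9
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Generate a labeled planar LA + LAA geometry
#'
#' Builds the closed boundary of the atrial body (an ellipse with labeled
#' pulmonary-vein and mitral openings on it) and attaches the appendage
#' outline for the requested morphology class at the ostium. The appendage is
#' a tube swept along a spine with a class-specific width profile: a
#' prescribed bend (chicken wing), secondary lobes as smooth lateral bulges
#' (cactus), a linear taper (windsock), or a short bulbous outline with
#' several lobes and a seeded irregular perturbation (cauliflower). The
#' ostium is represented explicitly as the internal chord between the two
#' attachment points; it separates the LA from the LAA subdomain.
#'
#' @param spec an [anatomy_spec()].
#' @return an object of class `laa_anatomy` with labeled boundary segments,
#'   the ostium chord, the LAA subpolygon and the construction spine.
#' @export
generate_anatomy <- function(spec) {
  if (!inherits(spec, "laa_anatomy_spec"))
    spec <- do.call(anatomy_spec, as.list(spec))
  .with_seed(spec$seed, .build_anatomy(spec))
}

.build_anatomy <- function(spec) {
  a <- spec$la_diameter / 2
  b <- 0.9 * a
  nell <- 2048L
  th <- seq(0, 2 * pi, length.out = nell + 1L)[-(nell + 1L)]
  ex <- a * cos(th); ey <- b * sin(th)
  seg <- sqrt(diff(c(ex, ex[1L]))^2 + diff(c(ey, ey[1L]))^2)
  arc <- c(0, cumsum(seg))          # length nell + 1, arc[nell+1] = perimeter
  per <- arc[nell + 1L]
  arc_at <- function(angle_deg) {   # arclength position of a given angle
    ang <- (angle_deg %% 360) * pi / 180
    idx <- which.min(abs(((th - ang + pi) %% (2 * pi)) - pi))
    arc[idx]
  }

  # the left-most vein is the left superior PV, immediately adjacent to the
  # appendage orifice: its diastolic jet sweeps the ostium
  pv_angles <- if (spec$n_pv_inlets == 1L) 90 else
    seq(40, 160, length.out = spec$n_pv_inlets)
  # the ostium sits inferolaterally, between the left-sided veins and the
  # lateral mitral annulus, so the appendage mouth sees the main
  # PV-to-mitral stream
  openings <- data.frame(
    label = c("mitral", paste0("pv_", seq_len(spec$n_pv_inlets)), "ostium"),
    angle = c(270, pv_angles, 205),
    width = c(spec$mitral_diameter, rep(spec$pv_diameter, spec$n_pv_inlets),
              spec$ostium_diameter),
    stringsAsFactors = FALSE)
  openings$s0 <- vapply(openings$angle, arc_at, numeric(1L)) - openings$width / 2
  openings$s1 <- openings$s0 + openings$width
  openings <- openings[order(openings$s0), ]
  for (k in seq_len(nrow(openings) - 1L)) {
    if (openings$s1[k] + 5e-4 > openings$s0[k + 1L])
      stop("invalid-spec error: boundary openings overlap (",
           openings$label[k], " / ", openings$label[k + 1L], ")")
  }
  if (openings$s0[1L] + per - openings$s1[nrow(openings)] < 5e-4)
    stop("invalid-spec error: boundary openings overlap around the outline")

  ell_at <- function(s) { # point on the ellipse at arclength s (vectorized)
    s <- s %% per
    cbind(stats::approx(arc, c(ex, ex[1L]), xout = s)$y,
          stats::approx(arc, c(ey, ey[1L]), xout = s)$y)
  }
  arc_pts <- function(s0, s1, ds = 5e-4) {
    ss <- seq(s0, s1, length.out = max(2L, ceiling((s1 - s0) / ds) + 1L))
    ell_at(ss)
  }

  # ordered segment walk (counter-clockwise, starting after the first opening)
  segments <- list()
  no <- nrow(openings)
  for (k in seq_len(no)) {
    op <- openings[k, ]
    nxt <- openings[(k %% no) + 1L, ]
    if (op$label == "ostium") {
      pa <- ell_at(op$s0); pb <- ell_at(op$s1)
      laa <- .build_laa_outline(spec, pa, pb)
      segments[[length(segments) + 1L]] <-
        list(label = "wall", pts = laa$outline, laa = TRUE)
      ostium <- rbind(pa, pb)
      laa_polygon <- laa$polygon
      spine <- laa$spine
    } else if (grepl("^pv_", op$label)) {
      # pulmonary veins enter through short tube stubs (the reference
      # geometries include the vein trunks, not bare orifices): two wall
      # sides and an open cap carrying the pv label
      pa <- ell_at(op$s0); pb <- ell_at(op$s1)
      mid <- (pa + pb) / 2
      dir <- mid / sqrt(sum(mid^2))
      Ls <- 1.2 * op$width
      pa2 <- pa + Ls * dir; pb2 <- pb + Ls * dir
      seg_pts <- function(p, q) rbind(p, q)
      segments[[length(segments) + 1L]] <-
        list(label = "wall", pts = seg_pts(pa, pa2), laa = FALSE)
      segments[[length(segments) + 1L]] <-
        list(label = op$label, pts = seg_pts(pa2, pb2), laa = FALSE)
      segments[[length(segments) + 1L]] <-
        list(label = "wall", pts = seg_pts(pb2, pb), laa = FALSE)
    } else {
      segments[[length(segments) + 1L]] <-
        list(label = op$label, pts = arc_pts(op$s0, op$s1), laa = FALSE)
    }
    gap1 <- op$s1
    gap2 <- if (k < no) nxt$s0 else nxt$s0 + per
    segments[[length(segments) + 1L]] <-
      list(label = "wall", pts = arc_pts(gap1, gap2), laa = FALSE)
  }
  # snap shared joints exactly
  ns <- length(segments)
  for (k in seq_len(ns)) {
    nxt <- (k %% ns) + 1L
    pend <- segments[[k]]$pts[nrow(segments[[k]]$pts), ]
    segments[[nxt]]$pts[1L, ] <- pend
  }

  poly <- do.call(rbind, lapply(segments, function(s)
    s$pts[-nrow(s$pts), , drop = FALSE]))
  if (!.polygon_is_simple(poly))
    stop("geometry error: generated outline self-intersects; adjust spec")

  out <- list(dimension = 2L, segments = segments, polygon = poly,
              ostium = ostium, laa_polygon = laa_polygon, spine = spine,
              signature = list(morphology_class = spec$morphology_class,
                               n_lobes = spec$n_lobes,
                               bend_angle = if (spec$morphology_class ==
                                                "chicken_wing") spec$bend_angle else 0,
                               taper_ratio = if (spec$morphology_class ==
                                                 "windsock") spec$taper_ratio else 1,
                               laa_length = spec$laa_length),
              provenance = spec)
  class(out) <- "laa_anatomy"
  out
}

# appendage outline between the two ostium attachment points pa (entered
# first on the CCW walk) and pb. Returns outline pts (pa ... pb), the closed
# LAA subpolygon and the construction spine.
.build_laa_outline <- function(spec, pa, pb) {
  L <- spec$laa_length
  w0 <- sqrt(sum((pb - pa)^2)) # actual chord width
  O <- (pa + pb) / 2
  d <- O / sqrt(sum(O^2)) # outward direction (ellipse is centred at origin)
  psi0 <- atan2(d[2L], d[1L])

  ns <- 256L
  s <- seq(0, L, length.out = ns)
  u <- s / L
  bend <- if (spec$morphology_class == "chicken_wing")
    spec$bend_angle * pi / 180 else 0
  psi <- psi0 + bend * .smoothstep((u - 0.35) / 0.40)
  ds <- L / (ns - 1L)
  px <- O[1L] + cumsum(c(0, cos(psi[-1L]) * ds))
  py <- O[2L] + cumsum(c(0, sin(psi[-1L]) * ds))
  tx <- cos(psi); ty <- sin(psi)
  nxv <- -ty; nyv <- tx # left normal of the spine

  half <- w0 / 2
  base <- switch(spec$morphology_class,
    chicken_wing = half * (1 - 0.25 * u),
    windsock     = half * (1 - (1 - spec$taper_ratio) * u),
    cactus       = half * (1 - 0.20 * u),
    cauliflower  = half * (1 + 0.55 * sin(pi * u)))

  bumpA <- numeric(ns); bumpB <- numeric(ns) # sides A (left) / B (right)
  nl <- spec$n_lobes
  if (spec$morphology_class == "cactus" && nl >= 1L) {
    sj <- seq(0.35, 0.85, length.out = nl)
    amp <- half * stats::runif(nl, 0.45, 0.65)
    for (j in seq_len(nl)) {
      g <- amp[j] * exp(-((u - sj[j]) / 0.07)^2)
      if (j %% 2L == 1L) bumpA <- bumpA + g else bumpB <- bumpB + g
    }
  }
  if (spec$morphology_class == "cauliflower") {
    sj <- seq(0.30, 0.90, length.out = nl)
    amp <- half * stats::runif(nl, 0.30, 0.45)
    for (j in seq_len(nl)) {
      g <- amp[j] * exp(-((u - sj[j]) / 0.06)^2)
      if (j %% 2L == 1L) bumpA <- bumpA + g else bumpB <- bumpB + g
    }
    for (k in 2:4) { # seeded smooth irregularity
      ak <- 0.07 * half / (k - 1)
      bumpA <- bumpA + ak * sin(k * pi * u + stats::runif(1L, 0, 2 * pi))
      bumpB <- bumpB + ak * sin(k * pi * u + stats::runif(1L, 0, 2 * pi))
    }
  }
  ramp <- .smoothstep(u / 0.18)
  offA <- pmax(base + ramp * bumpA, 0.22 * half)
  offB <- pmax(base + ramp * bumpB, 0.22 * half)

  Ax <- px + nxv * offA; Ay <- py + nyv * offA
  Bx <- px - nxv * offB; By <- py - nyv * offB
  # blend the proximal ends onto the exact ellipse attachment points;
  # side A is the one starting nearer pa
  dA <- sum((c(Ax[1L], Ay[1L]) - pa)^2)
  dB <- sum((c(Bx[1L], By[1L]) - pa)^2)
  if (dB < dA) { # swap sides so A starts at pa
    tmp <- cbind(Ax, Ay); Ax <- Bx; Ay <- By; Bx <- tmp[, 1L]; By <- tmp[, 2L]
  }
  blend <- 1 - .smoothstep(u / 0.15)
  Ax <- Ax + blend * (pa[1L] - Ax[1L]); Ay <- Ay + blend * (pa[2L] - Ay[1L])
  Bx <- Bx + blend * (pb[1L] - Bx[1L]); By <- By + blend * (pb[2L] - By[1L])

  # distal cap: arc around the spine end through the tip point
  tipc <- c(px[ns], py[ns])
  ang_a <- atan2(Ay[ns] - tipc[2L], Ax[ns] - tipc[1L])
  ang_t <- atan2(ty[ns], tx[ns])
  ang_b <- atan2(By[ns] - tipc[2L], Bx[ns] - tipc[1L])
  ra <- sqrt((Ax[ns] - tipc[1L])^2 + (Ay[ns] - tipc[2L])^2)
  rb <- sqrt((Bx[ns] - tipc[1L])^2 + (By[ns] - tipc[2L])^2)
  unwrap <- function(from, to) from + ((to - from + pi) %% (2 * pi)) - pi
  a1 <- ang_a; a2 <- unwrap(a1, ang_t); a3 <- unwrap(a2, ang_b)
  tcap <- seq(0, 1, length.out = 17L)[-c(1L, 17L)]
  angs <- ifelse(tcap < 0.5, a1 + (a2 - a1) * tcap / 0.5,
                 a2 + (a3 - a2) * (tcap - 0.5) / 0.5)
  rads <- ra + (rb - ra) * tcap
  capx <- tipc[1L] + rads * cos(angs)
  capy <- tipc[2L] + rads * sin(angs)

  outline <- rbind(cbind(Ax, Ay), cbind(capx, capy),
                   cbind(rev(Bx), rev(By)))
  colnames(outline) <- NULL
  polygon <- rbind(outline) # closed implicitly by the pb -> pa chord
  list(outline = outline, polygon = polygon,
       spine = cbind(px, py, s = s))
}

#' @export
print.laa_anatomy <- function(x, ...) {
  cat(sprintf("laa_anatomy: %s (seed %d)\n",
              x$provenance$morphology_class, x$provenance$seed))
  cat(sprintf("  boundary segments: %d (%s)\n", length(x$segments),
              paste(unique(vapply(x$segments, `[[`, "", "label")),
                    collapse = ", ")))
  cat(sprintf("  LAA length %.3f m, ostium %.4f m\n",
              x$provenance$laa_length,
              sqrt(sum((x$ostium[2L, ] - x$ostium[1L, ])^2))))
  invisible(x)
}

#' Wrap a raw polygon as a minimal anatomy (test domains)
#'
#' Utility for solver verification on canonical domains: turns a polygon into
#' the labeled-boundary object accepted by [generate_mesh()], with a single
#' label and no appendage.
#'
#' @param pts k x 2 matrix of polygon vertices (not repeated at the end).
#' @param label boundary label for every facet.
#' @param closed set `FALSE` to produce a deliberately open (invalid) outline.
#' @return an `laa_anatomy`.
#' @export
polygon_anatomy <- function(pts, label = "wall", closed = TRUE) {
  pts <- as.matrix(pts)
  ring <- if (closed) rbind(pts, pts[1L, ]) else pts
  out <- list(dimension = 2L,
              segments = list(list(label = label, pts = ring, laa = FALSE)),
              polygon = pts, ostium = NULL, laa_polygon = NULL, spine = NULL,
              signature = NULL, provenance = list(seed = 1L, closed = closed))
  class(out) <- "laa_anatomy"
  out
}
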