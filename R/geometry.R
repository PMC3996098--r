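# Geometry of the heel cross-section.
#
# The computational domain is the soft-tissue shell between the outer
# semi-elliptical skin boundary and its inward normal offset at the
# muscle-bone interface depth (11.3 mm by default).  Bone is excluded: the
# model imposes core temperature on the inner curve.  The outer ellipse has
# horizontal semi-axis a_out and vertical semi-axis b_out, with the flat top
# cut at y = 0 and the heel apex at (0, -b_out).
#
# Parameterisation: E(t) = (-a cos t, -b sin t), t in [0, pi], so t = 0 is
# the end of the arc with the lower x-coordinate, t = pi/2 the apex.  The
# unit outward normal is n(t) = (-b cos t, -a sin t)/|.|, and the point at
# depth s below the surface along the normal ray of column t is
# P(t, s) = E(t) - s n(t).  Offsets stay embedded as long as the maximum
# depth is below the minimum radius of curvature a^2/b (24.3 mm at default
# dimensions, above the 11.3 mm stack).

.ellipse_point <- function(t, a, b) cbind(-a * cos(t), -b * sin(t))

.ellipse_normal <- function(t, a, b) {
  nx <- -b * cos(t); ny <- -a * sin(t)
  len <- sqrt(nx^2 + ny^2)
  cbind(nx / len, ny / len)
}

# Cumulative arc length table of the outer arc, by trapezoidal quadrature on
# a fine parameter grid; returns interpolating functions t(l) and l(t).
.arc_length_table <- function(a, b, n = 8192) {
  t <- seq(0, pi, length.out = n + 1)
  speed <- sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  dl <- diff(t) * (speed[-1] + speed[-(n + 1)]) / 2
  l <- c(0, cumsum(dl))
  list(total = l[n + 1],
       t_of_l = stats::approxfun(l, t, rule = 2),
       l_of_t = stats::approxfun(t, l, rule = 2))
}

#' Heel cross-section geometry
#'
#' Builds the two-dimensional semi-elliptical heel domain: the outer skin
#' arc, the inward-offset layer interface curves at the cumulative layer
#' depths, and the embedded lesion ellipse(s). All lengths in metres
#' internally; constructor arguments in millimetres.
#'
#' @param layers layer stack from [heel_layers()]
#' @param lesion lesion specification from [lesion_spec()] (or `NULL` for a
#'   lesion-free domain)
#' @param a_out_mm outer horizontal semi-axis, mm
#' @param b_out_mm outer vertical semi-axis (apex depth below the flat top), mm
#' @return a `heel_geometry` object
#' @export
heel_geometry <- function(layers = heel_layers(), lesion = lesion_spec(),
                          a_out_mm = 27, b_out_mm = 30) {
  a <- a_out_mm * 1e-3; b <- b_out_mm * 1e-3
  stopifnot(a > 0, b > 0)
  depths <- layer_depths(layers)
  smax <- depths[length(depths)]
  if (smax >= a^2 / b)
    stop("geometry error: layer offsets self-intersect (b_out too small for the stack)")
  if (b <= smax)
    stop("geometry error: b_out must exceed the total soft-tissue thickness")
  if (!is.null(lesion) && lesion$d1 > 0 && lesion$d2 > 0) {
    lo <- lesion$center_depth - lesion$d2 / 2
    hi <- lesion$center_depth + lesion$d2 / 2
    if (lesion$stage %in% c("multilayer_mild", "multilayer_severe")) {
      lo <- lo - lesion$shell_thickness
      hi <- hi + lesion$shell_thickness
    }
    if (lo <= 0) stop("geometry error: lesion (plus shell) reaches the skin surface")
    if (hi >= smax) stop("geometry error: lesion (plus shell) reaches the bone interface")
  } else {
    lesion <- NULL
  }
  arc <- .arc_length_table(a, b)
  structure(list(a_out = a, b_out = b, layers = layers, depths = depths,
                 smax = smax, lesion = lesion, arc = arc),
            class = "heel_geometry")
}

#' @export
print.heel_geometry <- function(x, ...) {
  cat(sprintf("heel_geometry: a_out=%.1f mm, b_out=%.1f mm, arc length %.1f mm\n",
              x$a_out * 1e3, x$b_out * 1e3, x$arc$total * 1e3))
  cat(sprintf("  %d layers to depth %.2f mm\n", length(x$layers), x$smax * 1e3))
  if (is.null(x$lesion)) {
    cat("  no lesion\n")
  } else {
    cat(sprintf("  lesion: stage=%s depth=%.1f mm d1=%.1f d2=%.2f mm\n",
                x$lesion$stage, x$lesion$center_depth * 1e3,
                x$lesion$d1 * 1e3, x$lesion$d2 * 1e3))
  }
  invisible(x)
}

# Lesion core/shell ellipse parameters in physical coordinates.  The centre
# sits center_depth below the skin apex (0, -b_out); rx, ry are semi-axes.
.lesion_ellipses <- function(geom) {
  les <- geom$lesion
  if (is.null(les)) return(NULL)
  ctr <- c(les$lateral_offset, -(geom$b_out - les$center_depth))
  out <- list(core = list(center = ctr, rx = les$d1 / 2, ry = les$d2 / 2))
  if (les$stage %in% c("multilayer_mild", "multilayer_severe")) {
    # constant-thickness inflammation band around the core
    out$shell_w <- les$shell_thickness
  }
  out
}

# Intersections of the normal ray P(s) = p0 - s*n with an axis-aligned
# ellipse: quadratic in s; returns sorted roots within (0, smax), or
# numeric(0).  Tangential grazes (root pair closer than tol) are dropped.
.ray_ellipse_crossings <- function(p0, n, ell, smax, tol = 2e-5) {
  ax <- (p0[1] - ell$center[1]) / ell$rx
  ay <- (p0[2] - ell$center[2]) / ell$ry
  bx <- -n[1] / ell$rx
  by <- -n[2] / ell$ry
  A <- bx^2 + by^2
  B <- 2 * (ax * bx + ay * by)
  C <- ax^2 + ay^2 - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(numeric(0))
  sq <- sqrt(disc)
  r <- sort(c((-B - sq) / (2 * A), (-B + sq) / (2 * A)))
  if (r[2] - r[1] < tol) return(numeric(0))
  r <- r[r > tol & r < smax - tol]
  r
}

# TRUE where points (x, y) lie inside the ellipse.
.in_ellipse <- function(x, y, ell) {
  ((x - ell$center[1]) / ell$rx)^2 + ((y - ell$center[2]) / ell$ry)^2 <= 1
}

# Euclidean distance from a point outside (or on) the ellipse to its
# boundary, by solving the normal-foot condition
#   (rx^2 - ry^2) cos(phi) sin(phi) - q1 rx sin(phi) + q2 ry cos(phi) = 0
# on the first-quadrant image of the point.  Returns 0 for interior points.
.dist_to_ellipse <- function(x, y, ell) {
  q1 <- abs(x - ell$center[1]); q2 <- abs(y - ell$center[2])
  rx <- ell$rx; ry <- ell$ry
  if ((q1 / rx)^2 + (q2 / ry)^2 <= 1) return(0)
  g <- function(phi) (rx^2 - ry^2) * cos(phi) * sin(phi) -
    q1 * rx * sin(phi) + q2 * ry * cos(phi)
  phi <- stats::uniroot(g, c(0, pi / 2), tol = 1e-12)$root
  sqrt((q1 - rx * cos(phi))^2 + (q2 - ry * sin(phi))^2)
}

# TRUE if the point lies within the constant-thickness offset band of width
# w around (and outside of) the core ellipse.
.in_offset_band <- function(x, y, ell, w) {
  if (.in_ellipse(x, y, ell)) return(FALSE)
  # quick reject: outside the enlarged ellipse the distance exceeds w
  if (!.in_ellipse(x, y, list(center = ell$center, rx = ell$rx + w,
                              ry = ell$ry + w))) return(FALSE)
  .dist_to_ellipse(x, y, ell) <= w
}

# All intersections of the normal ray P(s) = p0 - s*n with the outer
# boundary of the offset band (distance w from the core ellipse), located by
# sign changes of dist - w on a fine sampling of s followed by root
# polishing.  Interior core crossings are handled separately.
.ray_offset_band_crossings <- function(p0, n, ell, w, smax, nsamp = 400) {
  sgrid <- seq(0, smax, length.out = nsamp)
  px <- p0[1] - sgrid * n[1]
  py <- p0[2] - sgrid * n[2]
  inside <- .in_ellipse(px, py, ell)
  dv <- numeric(nsamp)
  for (i in seq_len(nsamp))
    dv[i] <- if (inside[i]) -1 else .dist_to_ellipse(px[i], py[i], ell) - w
  roots <- numeric(0)
  sc <- which(dv[-1] * dv[-nsamp] < 0)
  f <- function(s) {
    p <- p0 - s * n
    if (.in_ellipse(p[1], p[2], ell)) -1 else .dist_to_ellipse(p[1], p[2], ell) - w
  }
  for (i in sc) {
    r <- stats::uniroot(f, c(sgrid[i], sgrid[i + 1]), tol = 1e-12)$root
    if (r > 2e-5 && r < smax - 2e-5) roots <- c(roots, r)
  }
  sort(roots)
}
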