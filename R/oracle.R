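# Closed-form steady solution of the one-dimensional multilayer perfusion
# slab, used as an independent verification reference for the FEM solver.
#
# In each homogeneous layer the steady Pennes equation
#   k T'' + w rho_b c_b (T_b - T) + q = 0
# has the general solution
#   T(x) = theta + A cosh(m xi) + B sinh(m xi),  m = sqrt(w rho_b c_b / k),
#   theta = T_b + q / (w rho_b c_b),
# (or a quadratic/linear profile where w = 0), with xi the local depth.  The
# per-layer constants follow from temperature and flux continuity at the
# interfaces, a convective condition at the surface and a fixed temperature
# at the base.

#' Closed-form steady temperature of the layered perfusion slab
#'
#' Solves the one-dimensional steady bioheat problem for the layer stack:
#' convective exchange (`h_inf`, `T_inf`) at the surface `x = 0`, fixed
#' `T_core` at the bottom of the stack, exact per-layer cosh/sinh (or
#' polynomial) profiles matched at the interfaces.
#'
#' @param layers layer stack from [heel_layers()]
#' @param x depths (m) at which to evaluate the temperature
#' @param h_inf film coefficient, W/(m^2 K)
#' @param T_inf ambient temperature, C
#' @param T_core base temperature, C
#' @return numeric vector of temperatures at `x` (degrees C)
#' @export
slab_steady_temperature <- function(layers = heel_layers(), x,
                                    h_inf = 12, T_inf = 22, T_core = 37) {
  depths <- layer_depths(layers)
  N <- length(layers)
  # per-layer descriptors
  lay <- lapply(seq_len(N), function(i) {
    p <- layers[[i]]$props
    w <- p$omega_b * p$rho_b * p$c_b
    if (w > 0) {
      list(perfused = TRUE, k = p$k, m = sqrt(w / p$k),
           theta = p$T_b + p$q_met / w, x0 = depths[i], x1 = depths[i + 1])
    } else {
      list(perfused = FALSE, k = p$k, q = p$q_met,
           x0 = depths[i], x1 = depths[i + 1])
    }
  })
  # basis value and derivative of T - particular at local coordinate xi
  val <- function(L, xi, which) {
    if (L$perfused) {
      if (which == "f") c(cosh(L$m * xi), sinh(L$m * xi))
      else c(L$m * sinh(L$m * xi), L$m * cosh(L$m * xi))
    } else {
      if (which == "f") c(1, xi) else c(0, 1)
    }
  }
  part <- function(L, xi, which) {
    if (L$perfused) {
      if (which == "f") L$theta else 0
    } else {
      if (which == "f") -L$q * xi^2 / (2 * L$k) else -L$q * xi / L$k
    }
  }
  A <- matrix(0, 2 * N, 2 * N)
  b <- numeric(2 * N)
  cols <- function(i) (2 * i - 1):(2 * i)
  # surface: k1 T'(0) = h (T(0) - T_inf)
  L1 <- lay[[1]]
  A[1, cols(1)] <- L1$k * val(L1, 0, "d") - h_inf * val(L1, 0, "f")
  b[1] <- h_inf * (part(L1, 0, "f") - T_inf) - L1$k * part(L1, 0, "d")
  r <- 2
  for (i in seq_len(N - 1)) {
    Li <- lay[[i]]; Lj <- lay[[i + 1]]
    di <- Li$x1 - Li$x0
    # temperature continuity
    A[r, cols(i)] <- val(Li, di, "f")
    A[r, cols(i + 1)] <- -val(Lj, 0, "f")
    b[r] <- part(Lj, 0, "f") - part(Li, di, "f")
    r <- r + 1
    # flux continuity
    A[r, cols(i)] <- Li$k * val(Li, di, "d")
    A[r, cols(i + 1)] <- -Lj$k * val(Lj, 0, "d")
    b[r] <- Lj$k * part(Lj, 0, "d") - Li$k * part(Li, di, "d")
    r <- r + 1
  }
  LN <- lay[[N]]
  dN <- LN$x1 - LN$x0
  A[r, cols(N)] <- val(LN, dN, "f")
  b[r] <- T_core - part(LN, dN, "f")
  cf <- solve(A, b)
  vapply(x, function(xx) {
    i <- max(1L, min(N, findInterval(xx, depths, rightmost.closed = TRUE)))
    L <- lay[[i]]
    xi <- xx - L$x0
    sum(cf[cols(i)] * val(L, xi, "f")) + part(L, xi, "f")
  }, numeric(1))
}
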