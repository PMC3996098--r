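# P1 finite-element discretisation of the Pennes bioheat equation
#
#   rho c dT/dt = div(k grad T) + w_b rho_b c_b (T_b - T) + q
#
# on the tagged triangular mesh.  Interface continuity of temperature and
# conductive flux between layers is implicit in the conforming single-field
# discretisation with per-element coefficients.  Boundary conditions:
# convective (Robin) q" = h (T - Tinf) on the skin arc, fixed core
# temperature on the muscle-bone interface, natural zero flux on the flat
# top.  During the cooling phase of the thermography protocol the skin arc
# switches to a strong Dirichlet condition.

#' Per-element material coefficients for a lesion stage
#'
#' Resolves every element's region tag (and, for `stage = "healthy"`, its
#' underlying layer, making the lesion thermally invisible) to the Pennes
#' coefficients used in assembly.
#'
#' @param mesh a `heel_mesh`
#' @param stage lesion stage
#' @param rho_b,c_b blood density and specific heat
#' @return data frame with one row per element: `k`, `rhoc`, `wbc`
#'   (omega_b rho_b c_b), `T_b`, `q_met`
#' @export
element_coefficients <- function(mesh, stage = "healthy",
                                 rho_b = .BLOOD_RHO, c_b = .BLOOD_C) {
  layers <- mesh$geom$layers
  keys <- paste(mesh$region, mesh$layer)
  uk <- unique(keys)
  lut <- lapply(uk, function(kk) {
    parts <- strsplit(kk, " ", fixed = TRUE)[[1]]
    properties_for(parts[1], stage, enclosing_layer = parts[2],
                   layers = layers, rho_b = rho_b, c_b = c_b)
  })
  names(lut) <- uk
  idx <- match(keys, uk)
  k <- vapply(lut, `[[`, numeric(1), "k")[idx]
  rhoc <- (vapply(lut, `[[`, numeric(1), "rho") *
           vapply(lut, `[[`, numeric(1), "c"))[idx]
  wb <- vapply(lut, `[[`, numeric(1), "omega_b")[idx]
  wbc <- wb * rho_b * c_b
  Tb <- vapply(lut, `[[`, numeric(1), "T_b")[idx]
  Tb[wb == 0] <- 0    # perfusion term vanishes; avoid NA propagation
  q <- vapply(lut, `[[`, numeric(1), "q_met")[idx]
  data.frame(k = k, rhoc = rhoc, wbc = wbc, T_b = Tb, q_met = q)
}

# P1 element matrices on all triangles at once.  Returns triplet lists for
# sparse assembly.
.p1_gradients <- function(mesh) {
  p <- mesh$nodes; tri <- mesh$tri
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  # gradients of the barycentric basis functions
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * area)
  c_ <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * area)
  list(area = area, b = b, c = c_)
}

.assemble_sparse <- function(i, j, v, n) {
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n), symmetric = FALSE)
}

#' Assemble the discrete bioheat system
#'
#' Builds the sparse finite-element operators for the Pennes equation on the
#' mesh: conduction stiffness, perfusion reaction, capacity (mass), skin
#' Robin boundary operator, and the volumetric and boundary load vectors.
#'
#' @param mesh a `heel_mesh`
#' @param coef per-element coefficients from [element_coefficients()]
#' @param h_inf convective film coefficient on the skin, W/(m^2 K)
#' @param T_inf ambient temperature, degrees C
#' @param T_core core temperature imposed at the muscle-bone interface, C
#' @param lump logical; use lumped (row-sum) mass matrices instead of the
#'   consistent ones
#' @return a `bioheat_system` list with components `K_cond`, `K_perf`,
#'   `K_robin`, `M`, `f_vol`, `f_robin`, node bookkeeping and the boundary
#'   data
#' @export
assemble_system <- function(mesh, coef, h_inf = 12, T_inf = 22,
                            T_core = 37, lump = FALSE) {
  n <- nrow(mesh$nodes)
  tri <- mesh$tri
  g <- .p1_gradients(mesh)
  area <- g$area
  ntri <- nrow(tri)

  ii <- jj <- integer(9 * ntri)
  vk <- vm <- vp <- numeric(9 * ntri)
  idx <- 0L
  mloc_cons <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12, 3, 3)
  for (a in 1:3) for (bb in 1:3) {
    rng <- (idx + 1):(idx + ntri)
    ii[rng] <- tri[, a]; jj[rng] <- tri[, bb]
    vk[rng] <- coef$k * area * (g$b[, a] * g$b[, bb] + g$c[, a] * g$c[, bb])
    mw <- if (lump) (if (a == bb) 1 / 3 else 0) else mloc_cons[a, bb]
    vm[rng] <- coef$rhoc * area * mw
    vp[rng] <- coef$wbc * area * mw
    idx <- idx + ntri
  }
  K_cond <- Matrix::drop0(.assemble_sparse(ii, jj, vk, n))
  M <- Matrix::drop0(.assemble_sparse(ii, jj, vm, n))
  K_perf <- Matrix::drop0(.assemble_sparse(ii, jj, vp, n))

  # volumetric loads: metabolic heat + perfusion supply term
  fe <- (coef$q_met + coef$wbc * coef$T_b) * area / 3
  f_vol <- numeric(n)
  acc <- rowsum(rep(fe, 3), c(tri))
  f_vol[as.integer(rownames(acc))] <- acc[, 1]

  # Robin operator on skin edges
  se <- mesh$edges$skin
  elen <- sqrt((mesh$nodes[se[, 1], 1] - mesh$nodes[se[, 2], 1])^2 +
               (mesh$nodes[se[, 1], 2] - mesh$nodes[se[, 2], 2])^2)
  nskin <- nrow(se)
  if (lump) {
    ei <- c(se[, 1], se[, 2]); ej <- ei
    ev <- rep(h_inf * elen / 2, 2)
  } else {
    ei <- c(se[, 1], se[, 2], se[, 1], se[, 2])
    ej <- c(se[, 1], se[, 2], se[, 2], se[, 1])
    ev <- c(rep(h_inf * elen / 3, 2), rep(h_inf * elen / 6, 2))
  }
  K_robin <- .assemble_sparse(ei, ej, ev, n)
  f_robin <- numeric(n)
  add <- h_inf * T_inf * elen / 2
  for (r in seq_len(nskin)) {
    f_robin[se[r, 1]] <- f_robin[se[r, 1]] + add[r]
    f_robin[se[r, 2]] <- f_robin[se[r, 2]] + add[r]
  }

  structure(list(K_cond = K_cond, K_perf = K_perf, K_robin = K_robin, M = M,
                 f_vol = f_vol, f_robin = f_robin,
                 n = n, mesh = mesh,
                 h_inf = h_inf, T_inf = T_inf, T_core = T_core),
            class = "bioheat_system")
}

# Solve A x = b with Dirichlet values fixed on `dnodes`.
.solve_constrained <- function(A, b, dnodes, dvals, n) {
  free <- setdiff(seq_len(n), dnodes)
  x <- numeric(n)
  x[dnodes] <- dvals
  rhs <- b[free] - as.numeric(A[free, dnodes, drop = FALSE] %*% dvals)
  x[free] <- as.numeric(Matrix::solve(A[free, free], rhs))
  x
}

#' Steady-state temperature field
#'
#' Solves the steady Pennes problem with the convective skin boundary, fixed
#' core temperature at the muscle-bone interface and zero flux on the flat
#' top.
#'
#' @param sys a `bioheat_system`
#' @return numeric vector of nodal temperatures (degrees C)
#' @export
solve_steady <- function(sys) {
  A <- sys$K_cond + sys$K_perf + sys$K_robin
  b <- sys$f_vol + sys$f_robin
  dn <- sys$mesh$bone_nodes
  T <- .solve_constrained(A, b, dn, rep(sys$T_core, length(dn)), sys$n)
  if (!all(is.finite(T))) stop("steady solve produced non-finite temperatures")
  T
}

#' Steady energy balance
#'
#' Checks the discrete balance between volumetric heat input (metabolic plus
#' net perfusion exchange), convective loss through the skin, and the
#' reaction flux through the fixed-temperature muscle-bone interface.
#'
#' @param sys a `bioheat_system`
#' @param T nodal temperature field
#' @return list with `Q_volume` (net volumetric input), `Q_robin` (convective
#'   loss through the skin), `Q_dirichlet` (conductive inflow through the
#'   fixed-temperature interface), all W per metre of out-of-plane depth,
#'   and the relative imbalance `|Q_volume + Q_dirichlet - Q_robin| / scale`
#' @export
energy_balance <- function(sys, T) {
  Q_vol <- sum(sys$f_vol) - sum(sys$K_perf %*% T)
  Q_robin <- sum(sys$K_robin %*% T) - sum(sys$f_robin)
  A <- sys$K_cond + sys$K_perf + sys$K_robin
  r <- as.numeric(A %*% T) - (sys$f_vol + sys$f_robin)
  Q_dir <- sum(r[sys$mesh$bone_nodes])
  scale <- max(abs(Q_vol), abs(Q_robin), abs(Q_dir), 1e-12)
  list(Q_volume = Q_vol, Q_robin = Q_robin, Q_dirichlet = Q_dir,
       imbalance = abs(Q_vol + Q_dir - Q_robin) / scale)
}

#' Transient solution by backward Euler
#'
#' Advances the semi-discrete system with unconditionally stable implicit
#' Euler steps. The skin boundary carries either the convective (Robin)
#' condition or a strong Dirichlet condition (`skin_dirichlet`), as during
#' the cooling phase of the thermography protocol; the muscle-bone interface
#' is always held at the core temperature.
#'
#' @param sys a `bioheat_system`
#' @param T0 initial nodal field
#' @param t_end phase duration, s
#' @param dt time step, s (the phase is split into `round(t_end/dt)` steps)
#' @param skin_dirichlet `NULL` for the convective boundary, or the fixed
#'   skin temperature (degrees C)
#' @param save_times times (relative to phase start) at which to record the
#'   skin-node temperatures; the phase end field is always returned
#' @param save_nodes node indices recorded at `save_times` (default: the
#'   skin boundary nodes)
#' @return list with `T_end` (full field), `times` (saved instants), and
#'   `snapshots` (matrix, one row per saved instant over `save_nodes`)
#' @export
solve_transient <- function(sys, T0, t_end, dt, skin_dirichlet = NULL,
                            save_times = numeric(0), save_nodes = NULL) {
  nsteps <- round(t_end / dt)
  if (abs(nsteps * dt - t_end) > 1e-9 * max(1, t_end))
    stop("t_end must be an integer multiple of dt")
  if (is.null(save_nodes)) save_nodes <- sys$mesh$skin_nodes
  n <- sys$n
  robin_active <- is.null(skin_dirichlet)
  K <- sys$K_cond + sys$K_perf + if (robin_active) sys$K_robin else
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
  f <- sys$f_vol + if (robin_active) sys$f_robin else numeric(n)
  A <- sys$M / dt + K
  if (robin_active) {
    dn <- sys$mesh$bone_nodes
    dv <- rep(sys$T_core, length(dn))
  } else {
    skin <- sys$mesh$skin_nodes
    dn <- c(sys$mesh$bone_nodes, setdiff(skin, sys$mesh$bone_nodes))
    dv <- c(rep(sys$T_core, length(sys$mesh$bone_nodes)),
            rep(skin_dirichlet, length(dn) - length(sys$mesh$bone_nodes)))
  }
  free <- setdiff(seq_len(n), dn)
  Aff <- A[free, free]
  Afd <- A[free, dn, drop = FALSE]
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Aff), "CsparseMatrix"),
                         LDL = FALSE)
  Mff <- sys$M[free, free]
  Mfd <- sys$M[free, dn, drop = FALSE]
  T <- T0
  T[dn] <- dv
  bc_fix <- f[free] - as.numeric(Afd %*% dv)
  # M/dt applied to the Dirichlet values of the PREVIOUS step: constant here
  save_steps <- sort(unique(round(save_times / dt)))
  save_steps <- save_steps[save_steps >= 0 & save_steps <= nsteps]
  snaps <- matrix(NA_real_, length(save_steps), length(save_nodes))
  times <- save_steps * dt
  si <- 1L
  if (length(save_steps) && save_steps[1] == 0L) {
    snaps[1, ] <- T[save_nodes]; si <- 2L
  }
  Tf <- T[free]
  Td_prev <- T0[dn]   # field value at the constrained nodes before the jump
  for (step in seq_len(nsteps)) {
    rhs <- as.numeric(Mff %*% Tf) / dt + as.numeric(Mfd %*% Td_prev) / dt + bc_fix
    Tf <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    Td_prev <- dv
    if (si <= length(save_steps) && step == save_steps[si]) {
      T[free] <- Tf
      snaps[si, ] <- T[save_nodes]
      si <- si + 1L
    }
  }
  T[free] <- Tf
  T[dn] <- dv
  list(T_end = T, times = times, snapshots = snaps)
}
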