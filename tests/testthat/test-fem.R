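# single reference triangle wrapped as a minimal mesh object
unit_triangle_mesh <- function() {
  structure(list(
    nodes = cbind(x = c(0, 1, 0), y = c(0, 0, 1)),
    tri = matrix(c(1L, 2L, 3L), 1, 3),
    region = "muscle", layer = "muscle",
    node_t = c(0, 1, 0), node_s = c(0, 0, 1),
    skin_nodes = c(1L, 2L), skin_l = c(0, 1),
    bone_nodes = 3L,
    edges = list(skin = matrix(c(1L, 2L), 1, 2),
                 bone_interface = matrix(integer(0), 0, 2),
                 top_flat = matrix(integer(0), 0, 2)),
    geom = list(layers = heel_layers(), depths = c(0, 1), smax = 1,
                lesion = NULL),
    h_fine = 1, h_coarse = 1), class = "heel_mesh")
}

test_that("stiffness of the reference triangle matches the closed form", {
  m <- unit_triangle_mesh()
  coef <- data.frame(k = 1, rhoc = 1, wbc = 0, T_b = 0, q_met = 0)
  sys <- assemble_system(m, coef, h_inf = 0, T_inf = 0)
  K <- as.matrix(sys$K_cond)
  Kref <- matrix(c(1, -0.5, -0.5, -0.5, 0.5, 0, -0.5, 0, 0.5), 3, 3)
  expect_equal(K, Kref, ignore_attr = TRUE)
  # no perfusion, no Robin: constant vector in the nullspace (zero row sums)
  expect_equal(as.numeric(K %*% rep(1, 3)), rep(0, 3))
  # consistent mass of the reference triangle: area/12 * (1 + delta_ij)
  expect_equal(as.matrix(sys$M),
               0.5 / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3),
               ignore_attr = TRUE)
})

test_that("lumped perfusion adds w rho_b c_b area/3 to each diagonal", {
  m <- unit_triangle_mesh()
  wbc <- 2.7e-3 * 1060 * 3770
  coef <- data.frame(k = 1, rhoc = 1, wbc = wbc, T_b = 37, q_met = 0)
  sys <- assemble_system(m, coef, h_inf = 0, T_inf = 0, lump = TRUE)
  expect_equal(Matrix::diag(sys$K_perf), rep(wbc * 0.5 / 3, 3))
  expect_true(Matrix::isDiagonal(sys$K_perf))
})

test_that("uniform Dirichlet with no sources yields a uniform field", {
  m <- build_strip_mesh(width_mm = 2, dx_mm = 0.5, dy_mm = 0.5,
                        total_depth_mm = 5)
  coef <- element_coefficients(m, "healthy")
  coef$wbc <- 0; coef$q_met <- 0; coef$T_b <- 0
  sys <- assemble_system(m, coef, h_inf = 0, T_inf = 0, T_core = 37)
  expect_equal(solve_steady(sys), rep(37, nrow(m$nodes)), tolerance = 1e-10)
})

test_that("pseudo-1D FEM matches the closed-form multilayer perfusion slab", {
  lay <- heel_layers()
  m <- build_strip_mesh(lay, width_mm = 1, dx_mm = 0.25, dy_mm = 0.1)
  sys <- assemble_system(m, element_coefficients(m, "healthy"),
                         h_inf = 12, T_inf = 22, T_core = 37)
  Tfem <- solve_steady(sys)
  Tref <- slab_steady_temperature(lay, m$node_s, h_inf = 12, T_inf = 22,
                                  T_core = 37)
  expect_lt(max(abs(Tfem - Tref)), 0.01)
  # steady energy balance closes
  eb <- energy_balance(sys, Tfem)
  expect_lt(eb$imbalance, 1e-8)
})

test_that("steady heel solution respects the maximum principle", {
  m <- cached("mesh_isch8",
              build_mesh(heel_geometry(lesion = lesion_spec("ischemia", 8))))
  for (stage in c("healthy", "ischemia", "inflammation")) {
    sys <- assemble_system(m, element_coefficients(m, stage))
    Ts <- solve_steady(sys)
    expect_gt(min(Ts[m$skin_nodes]), 22)
    expect_lt(max(Ts), 37 + 1e-9)
    expect_lt(energy_balance(sys, Ts)$imbalance, 1e-8)
  }
})

test_that("transient stepping holds the steady state fixed", {
  m <- build_strip_mesh(width_mm = 1, dx_mm = 0.25, dy_mm = 0.25)
  sys <- assemble_system(m, element_coefficients(m, "healthy"))
  Ts <- solve_steady(sys)
  out <- solve_transient(sys, Ts, t_end = 10, dt = 0.5,
                         save_nodes = seq_len(nrow(m$nodes)))
  expect_lt(max(abs(out$T_end - Ts)), 1e-8)
})

test_that("step cooling of a deep conducting strip follows the erfc solution", {
  lay <- heel_layers()
  m <- build_strip_mesh(lay["muscle"], width_mm = 2, dx_mm = 0.5,
                        dy_mm = 0.25, total_depth_mm = 40)
  p <- lay$muscle$props
  alpha <- p$k / (p$rho * p$c)
  coef <- element_coefficients(m, "healthy")
  coef$wbc <- 0; coef$q_met <- 0; coef$T_b <- 0
  sys <- assemble_system(m, coef, T_core = 37)
  T0 <- rep(37, nrow(m$nodes))
  out <- solve_transient(sys, T0, t_end = 10, dt = 0.05, skin_dirichlet = 15)
  x <- m$node_s
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  Tref <- 15 + (37 - 15) * erf(x / (2 * sqrt(alpha * 10)))
  mid <- abs(m$nodes[, 1] - 1e-3) < 1e-9
  # relative to the 22 C step amplitude
  expect_lt(max(abs(out$T_end[mid] - Tref[mid])) / 22, 0.02)
})
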