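test_that("the recovery curve starts at the cooling temperature", {
  pair <- pair_300("ischemia", 8)
  pc <- point_curve(pair$healthy)
  expect_equal(pc$T_C[pc$t_s == 0], 15)
  expect_error(point_curve(pair$healthy, l_mm = 1e4), "outside")
})

test_that("profiles of symmetric scenarios are symmetric about the apex", {
  pair <- pair_300("ischemia", 8)
  for (t in list("steady", 210)) {
    pr <- surface_profile(pair$dti, t)
    expect_lt(max(abs(pr$T_C - rev(pr$T_C))), 0.02)
  }
  expect_error(surface_profile(pair$dti, 1e6), "outside")
})

test_that("delta series are antisymmetric and vanish for identical runs", {
  pair <- pair_300("ischemia", 8)
  d0 <- delta_series(pair$healthy, pair$healthy, at = "P")
  expect_equal(max(abs(d0$delta_C)), 0)
  ab <- delta_series(pair$dti, pair$healthy, at = 210)
  ba <- delta_series(pair$healthy, pair$dti, at = 210)
  expect_identical(ab$delta_C, -ba$delta_C)
  # runs on different meshes are refused
  other <- pair_300("ischemia", 6)
  expect_error(delta_series(pair$dti, other$healthy, at = "P"),
               "different meshes")
})

test_that("profile extremum picks the largest magnitude, ties toward small l", {
  df <- data.frame(l_mm = c(10, 20, 30, 40), delta_C = c(0.2, -0.5, 0.1, -0.5))
  ex <- profile_extremum(df)
  expect_equal(ex$l_mm, 20)
  expect_equal(ex$delta_C, -0.5)
})

test_that("the 8 mm ischemia signature peaks beneath the lesion", {
  pair <- pair_300("ischemia", 8)
  dp <- delta_series(pair$dti, pair$healthy, at = 210)
  ex <- profile_extremum(dp)
  expect_lt(ex$delta_C, 0)
  expect_gte(ex$l_mm, 35)
  expect_lte(ex$l_mm, 55)
})

test_that("shallower inflammation lesions give stronger skin signatures", {
  for (t in c(120, 180, 240, 300)) {
    v <- vapply(c(3.8, 6, 8), function(d)
      abs(delta_at_P(pair_300("inflammation", d), t)), numeric(1))
    expect_true(all(diff(v) < 0))
  }
})

test_that("transient imaging more than doubles the steady multilayer signal", {
  pair <- pair_300("multilayer_mild", 3.8)
  steady_max <- max(delta_series(pair$dti, pair$healthy, at = "steady")$delta_C)
  trans_max <- window_extremum(pair$dti, pair$healthy, 0.5, 300, "max")$delta_C
  expect_gt(trans_max / steady_max, 2)
  # early recovery shows a central decrease flanked by warm edges
  pr <- delta_series(pair$dti, pair$healthy, at = 30)
  apex <- apex_index(pair$dti$mesh)
  expect_lt(pr$delta_C[apex], 0)
  expect_gt(max(pr$delta_C), 0)
})

test_that("a healthy-stage lesion is thermally identical to no lesion", {
  # same mesh: stage toggling only touches region properties
  m <- cached("mesh_isch8",
              build_mesh(heel_geometry(lesion = lesion_spec("ischemia", 8))))
  co_h <- element_coefficients(m, "healthy")
  plain <- cached("mesh_plain", build_mesh(heel_geometry(lesion = NULL)))
  # cross-mesh: healthy steady skin temperatures agree to discretisation level
  Th <- solve_steady(assemble_system(m, co_h))
  Tp <- solve_steady(assemble_system(plain, element_coefficients(plain, "healthy")))
  Ti <- stats::approx(plain$skin_l, Tp[plain$skin_nodes],
                      xout = m$skin_l)$y
  expect_lt(max(abs(Th[m$skin_nodes] - Ti)), 0.02)
})

test_that("analysis CSVs round-trip with fixed headers", {
  pair <- pair_300("ischemia", 8)
  f <- tempfile(fileext = ".csv")
  write_analysis_csv(point_curve(pair$dti), f)
  back <- utils::read.csv(f)
  expect_named(back, c("t_s", "T_C"))
  unlink(f)
})
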