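test_that("cooling phase pins the whole skin arc at the cooling temperature", {
  pair <- pair_300("ischemia", 8)
  for (res in list(pair$dti, pair$healthy)) {
    during <- res$skin$times < 0          # cooling stored at negative times
    expect_true(any(during))
    expect_equal(max(abs(res$skin$T[during, ] - 15)), 0)
    # t = 0 snapshot is the end-of-cooling state
    expect_equal(unname(res$skin$T[which(res$skin$times == 0), ]),
                 unname(res$end_cool[res$mesh$skin_nodes]))
  }
})

test_that("healthy recovery at P is monotone and relaxes to the steady state", {
  h <- cached("healthy_long",
              run_scenario("healthy", 8, protocol_config(t_end = 3600))$healthy)
  pc <- point_curve(h)
  rec <- pc[pc$t_s >= 0, ]
  expect_true(all(diff(rec$T_C) > -1e-9))
  sk <- h$mesh$skin_nodes
  # the slow conduction tail leaves ~0.1 C at 30 min; 60 min closes it
  expect_lt(max(abs(h$T_final[sk] - h$steady[sk])), 0.02)
  expect_lt(max(abs(rec$T_C[rec$t_s == 1800] -
                    h$steady[sk[apex_index(h$mesh)]])), 0.2)
  # all snapshots within the physical bounds of the boundary/source data
  expect_gte(min(h$skin$T), 14.9)
  expect_lte(max(h$skin$T), 45)
})

test_that("restarting recovery from the stored end-of-cooling field is exact", {
  pair <- pair_300("ischemia", 8)
  res <- pair$dti
  sys <- assemble_system(res$mesh, element_coefficients(res$mesh, "ischemia"),
                         h_inf = res$cfg$h_inf, T_inf = res$cfg$T_inf,
                         T_core = res$cfg$T_core)
  a <- solve_transient(sys, res$end_cool, t_end = 30, dt = 0.1,
                       save_times = seq(0, 30, 0.5))
  b <- solve_transient(sys, res$end_cool, t_end = 30, dt = 0.1,
                       save_times = seq(0, 30, 0.5))
  expect_identical(a, b)
  # and reproduces the originally stored trajectory
  orig <- res$skin$T[res$skin$times %in% seq(0, 30, 0.5), ]
  expect_equal(unname(a$snapshots), unname(orig), tolerance = 1e-12)
})

test_that("the scenario suite covers ten scenarios and shares baselines", {
  suite <- cached("suite_steady",
                  run_study_suite(protocol_config(t_end = 300),
                                  transient = FALSE))
  expect_length(suite, 10)
  expect_setequal(names(suite), study_scenarios()$name)
  expect_null(suite$healthy$dti)
  # the healthy scenario shares its mesh (and baseline) with ischemia_8mm
  expect_identical(suite$healthy$healthy, suite$ischemia_8mm$healthy)
  # distinct lesion geometry implies a distinct baseline
  expect_false(identical(suite$ischemia_8mm$healthy$steady,
                         suite$multilayer_mild_8mm$healthy$steady))
})

test_that("lesion stages separate by sign at the sub-lesion point", {
  # ischemia cools and inflammation warms the sub-lesion skin throughout
  # the five-minute recovery window, at every lesion depth
  tgrid <- seq(30, 300, by = 30)
  for (d in c(3.8, 6, 8)) {
    expect_true(all(delta_at_P(pair_300("ischemia", d), tgrid) < 0))
    expect_true(all(delta_at_P(pair_300("inflammation", d), tgrid) > 0))
  }
})

test_that("severe multilayer inflammation has the largest five-minute response", {
  mags <- c(
    isch = abs(delta_at_P(pair_300("ischemia", 8), 300)),
    infl = abs(delta_at_P(pair_300("inflammation", 8), 300)),
    mild = abs(delta_at_P(pair_300("multilayer_mild", 8), 300)),
    severe = abs(delta_at_P(pair_300("multilayer_severe", 8), 300)),
    mild38 = abs(delta_at_P(pair_300("multilayer_mild", 3.8), 300)))
  expect_equal(names(which.max(mags)), "severe")
})
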