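# The dynamic thermography protocol: steady state with the skin exposed to
# ambient air, one minute of 15 C surface cooling (strong Dirichlet), then
# convective thermal recovery back toward the steady state.  The recovery
# clock starts at the removal of cooling; cooling-phase snapshots are stored
# at negative times.

#' Protocol configuration
#'
#' Parameters of the cool-then-recover dynamic thermography protocol and its
#' time discretisation. Defaults: convective film coefficient 12 W/(m^2 K),
#' ambient 22 C, cooling at 15 C for 60 s, core temperature 37 C, backward
#' Euler steps of 0.1 s for the first 300 s of recovery (and throughout
#' cooling), 1 s thereafter, recovery horizon 1800 s.
#'
#' @param h_inf film coefficient, W/(m^2 K)
#' @param T_inf ambient temperature, C
#' @param T_cool imposed skin temperature during cooling, C
#' @param t_cool cooling duration, s
#' @param T_core muscle-bone interface temperature, C
#' @param t_end recovery horizon, s
#' @param dt_fine,t_fine,dt_coarse time-step schedule (s)
#' @param save_dt_fine,save_dt_coarse skin-snapshot retention intervals (s)
#'   during `[0, t_fine]` and after
#' @return a `protocol_config` list
#' @export
protocol_config <- function(h_inf = 12, T_inf = 22, T_cool = 15, t_cool = 60,
                            T_core = 37, t_end = 1800, dt_fine = 0.1,
                            t_fine = 300, dt_coarse = 1,
                            save_dt_fine = 0.5, save_dt_coarse = 10) {
  stopifnot(h_inf > 0, t_cool > 0, dt_fine > 0, dt_coarse > 0,
            t_cool < t_fine, is.finite(c(T_inf, T_cool, T_core)))
  if (t_end < t_fine) t_fine <- t_end
  structure(list(h_inf = h_inf, T_inf = T_inf, T_cool = T_cool,
                 t_cool = t_cool, T_core = T_core, t_end = t_end,
                 dt_fine = dt_fine, t_fine = t_fine, dt_coarse = dt_coarse,
                 save_dt_fine = save_dt_fine, save_dt_coarse = save_dt_coarse),
            class = "protocol_config")
}

#' Run the thermography protocol on a prebuilt mesh
#'
#' Lower-level entry point used to compare lesion stages on an identical
#' mesh (eliminating discretisation differences from surface temperature
#' differences): the stage only toggles the region properties.
#'
#' @param mesh a `heel_mesh`
#' @param stage lesion stage applied to the lesion-tagged regions
#' @param cfg a [protocol_config()]
#' @param transient if `FALSE`, only the steady state is computed
#' @param rho_b,c_b blood properties
#' @return a `recovery_result`: `steady` (full nodal field), `skin`
#'   (list with `l_mm`, `times` on the recovery clock — cooling at negative
#'   times — and matrix `T`), `end_cool` (field at cooling removal), plus
#'   scenario metadata
#' @export
run_protocol <- function(mesh, stage, cfg = protocol_config(),
                         transient = TRUE, rho_b = .BLOOD_RHO, c_b = .BLOOD_C) {
  coef <- element_coefficients(mesh, stage, rho_b, c_b)
  sys <- assemble_system(mesh, coef, h_inf = cfg$h_inf, T_inf = cfg$T_inf,
                         T_core = cfg$T_core)
  steady <- solve_steady(sys)
  res <- list(mesh = mesh, stage = stage, cfg = cfg, steady = steady,
              depth_mm = if (!is.null(mesh$geom$lesion))
                mesh$geom$lesion$center_depth * 1e3 else NA_real_)
  if (transient) {
    # cooling phase: strong Dirichlet at T_cool on the skin arc
    cool <- solve_transient(sys, steady, t_end = cfg$t_cool, dt = cfg$dt_fine,
                            skin_dirichlet = cfg$T_cool,
                            save_times = seq(0, cfg$t_cool, by = cfg$save_dt_fine))
    # recovery phase 1: fine steps while gradients are steep
    rec1 <- solve_transient(sys, cool$T_end, t_end = cfg$t_fine,
                            dt = cfg$dt_fine,
                            save_times = seq(0, cfg$t_fine, by = cfg$save_dt_fine))
    keep <- cool$times < cfg$t_cool   # recovery t=0 repeats the final state
    times <- c(cool$times[keep] - cfg$t_cool, rec1$times)
    snaps <- rbind(cool$snapshots[keep, , drop = FALSE], rec1$snapshots)
    if (cfg$t_end > cfg$t_fine) {
      rec2 <- solve_transient(sys, rec1$T_end, t_end = cfg$t_end - cfg$t_fine,
                              dt = cfg$dt_coarse,
                              save_times = seq(cfg$save_dt_coarse,
                                               cfg$t_end - cfg$t_fine,
                                               by = cfg$save_dt_coarse))
      times <- c(times, rec2$times + cfg$t_fine)
      snaps <- rbind(snaps, rec2$snapshots)
      T_final <- rec2$T_end
    } else {
      T_final <- rec1$T_end
    }
    res$end_cool <- cool$T_end
    res$T_final <- T_final
    res$skin <- list(l_mm = mesh$skin_l * 1e3, times = times, T = snaps)
  }
  structure(res, class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("recovery_result: stage=%s depth=%s mm, steady skin %.2f-%.2f C\n",
              x$stage, format(x$depth_mm), min(x$steady[x$mesh$skin_nodes]),
              max(x$steady[x$mesh$skin_nodes])))
  if (!is.null(x$skin))
    cat(sprintf("  %d skin snapshots on t in [%.0f, %.0f] s (recovery clock)\n",
                length(x$skin$times), min(x$skin$times), max(x$skin$times)))
  invisible(x)
}

#' Run a lesion scenario (with matched healthy baseline)
#'
#' Builds the default heel geometry with the requested lesion, meshes it,
#' and runs the thermography protocol for the lesion stage and for the
#' healthy baseline on the same mesh.
#'
#' @param stage lesion stage (`"healthy"` gives only the baseline)
#' @param depth_mm lesion centre depth, mm
#' @param cfg protocol configuration
#' @param run_config full run configuration (geometry/mesh/lesion overrides),
#'   see [default_config()]
#' @param transient compute the transient phases (else steady only)
#' @param baseline also run the healthy baseline on the same mesh
#' @return list with elements `dti` (`NULL` when `stage = "healthy"`) and
#'   `healthy`, both `recovery_result`s on the shared mesh
#' @export
run_scenario <- function(stage, depth_mm = 8, cfg = protocol_config(),
                         run_config = default_config(), transient = TRUE,
                         baseline = TRUE) {
  rc <- run_config
  les <- lesion_spec(stage = if (stage == "healthy") "healthy" else stage,
                     depth_mm = depth_mm,
                     d1_mm = rc$lesion$d1_mm, d2_mm = rc$lesion$d2_mm,
                     shell_mm = rc$lesion$shell_mm,
                     offset_mm = rc$lesion$offset_mm)
  layers <- heel_layers(rho_b = rc$tissue$rho_b, c_b = rc$tissue$c_b)
  geom <- heel_geometry(layers, les, a_out_mm = rc$geometry$a_out_mm,
                        b_out_mm = rc$geometry$b_out_mm)
  mesh <- build_mesh(geom, h_fine_mm = rc$mesh$h_fine_mm,
                     h_coarse_mm = rc$mesh$h_coarse_mm)
  out <- list(dti = NULL, healthy = NULL)
  if (stage != "healthy")
    out$dti <- run_protocol(mesh, stage, cfg, transient,
                            rho_b = rc$tissue$rho_b, c_b = rc$tissue$c_b)
  if (baseline || stage == "healthy")
    out$healthy <- run_protocol(mesh, "healthy", cfg, transient,
                                rho_b = rc$tissue$rho_b, c_b = rc$tissue$c_b)
  out
}

#' Scenario set of the reference study
#'
#' The ten scenarios examined by the model: healthy tissue, ischemia and
#' inflammation lesions at 3.8, 6 and 8 mm depth, multilayer lesions
#' (mild shell) at 8 and 3.8 mm, and a severe multilayer lesion at 8 mm.
#'
#' @return data frame with columns `name`, `stage`, `depth_mm`
#' @export
study_scenarios <- function() {
  data.frame(
    name = c("healthy",
             "ischemia_3.8mm", "ischemia_6mm", "ischemia_8mm",
             "inflammation_3.8mm", "inflammation_6mm", "inflammation_8mm",
             "multilayer_mild_8mm", "multilayer_severe_8mm",
             "multilayer_mild_3.8mm"),
    stage = c("healthy", rep("ischemia", 3), rep("inflammation", 3),
              "multilayer_mild", "multilayer_severe", "multilayer_mild"),
    depth_mm = c(8, 3.8, 6, 8, 3.8, 6, 8, 8, 8, 3.8),
    stringsAsFactors = FALSE
  )
}

#' Run the full scenario suite
#'
#' Runs the thermography protocol for every scenario in [study_scenarios()].
#' Healthy baselines are shared: scenarios with an identical mesh (same
#' lesion geometry) reuse one baseline run.
#'
#' @param cfg protocol configuration
#' @param run_config run configuration
#' @param transient compute the transient phases
#' @return named list of scenario results (each a list `dti`/`healthy` as in
#'   [run_scenario()])
#' @export
run_study_suite <- function(cfg = protocol_config(),
                            run_config = default_config(), transient = TRUE) {
  sc <- study_scenarios()
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(sc))
  names(out) <- sc$name
  for (i in seq_len(nrow(sc))) {
    stage <- sc$stage[i]; depth <- sc$depth_mm[i]
    # mesh signature: depth + presence of a shell
    shell <- stage %in% c("multilayer_mild", "multilayer_severe")
    key <- sprintf("d%.3f_s%d", depth, as.integer(shell))
    if (!exists(key, envir = cache)) {
      rc <- run_config
      geom_stage <- if (shell) "multilayer_mild" else
        if (stage == "healthy") "healthy" else stage
      les <- lesion_spec(stage = geom_stage, depth_mm = depth,
                         d1_mm = rc$lesion$d1_mm, d2_mm = rc$lesion$d2_mm,
                         shell_mm = rc$lesion$shell_mm,
                         offset_mm = rc$lesion$offset_mm)
      layers <- heel_layers(rho_b = rc$tissue$rho_b, c_b = rc$tissue$c_b)
      geom <- heel_geometry(layers, les, a_out_mm = rc$geometry$a_out_mm,
                            b_out_mm = rc$geometry$b_out_mm)
      mesh <- build_mesh(geom, h_fine_mm = rc$mesh$h_fine_mm,
                         h_coarse_mm = rc$mesh$h_coarse_mm)
      base <- run_protocol(mesh, "healthy", cfg, transient,
                           rho_b = rc$tissue$rho_b, c_b = rc$tissue$c_b)
      assign(key, list(mesh = mesh, healthy = base), envir = cache)
    }
    ent <- get(key, envir = cache)
    dti <- if (stage == "healthy") NULL else
      run_protocol(ent$mesh, stage, cfg, transient,
                   rho_b = run_config$tissue$rho_b, c_b = run_config$tissue$c_b)
    out[[i]] <- list(dti = dti, healthy = ent$healthy)
  }
  out
}
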