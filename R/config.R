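# Run configuration: defaults reproduce the reference heel model exactly;
# YAML/JSON overrides are validated against the default schema (unknown keys
# rejected, basic unit sanity checks applied).  Lengths in config files are
# millimetres (converted to SI internally); temperatures are degrees Celsius.

#' Default run configuration
#'
#' The full configuration of the heel model: geometry (outer semi-axes),
#' tissue (blood properties), lesion (stage, depth, axes, shell), mesh
#' element sizes, solver time stepping and the thermography protocol.
#'
#' @return a nested named list (`run_config`)
#' @export
default_config <- function() {
  structure(list(
    geometry = list(a_out_mm = 27, b_out_mm = 30),
    tissue = list(rho_b = 1060, c_b = 3770),
    lesion = list(stage = "healthy", depth_mm = 8, d1_mm = 15, d2_mm = 2.5,
                  shell_mm = 1.25, offset_mm = 0),
    mesh = list(h_fine_mm = 1.3, h_coarse_mm = 2.4),
    solver = list(dt_fine = 0.1, t_fine = 300, dt_coarse = 1),
    protocol = list(h_inf = 12, T_inf = 22, T_cool = 15, t_cool = 60,
                    T_core = 37, t_end = 1800),
    output = list(dir = "results"),
    seed = 1L
  ), class = "run_config")
}

.merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("configuration error: unknown key '", key, "'")
    if (is.list(base[[nm]])) {
      if (!is.list(override[[nm]]))
        stop("configuration error: '", key, "' must be a mapping")
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]], key)
    } else {
      v <- override[[nm]]
      if (length(v) != 1) stop("configuration error: '", key, "' must be scalar")
      base[[nm]] <- v
    }
  }
  base
}

.validate_config <- function(cfg) {
  ck <- function(cond, msg) if (!isTRUE(cond)) stop("configuration error: ", msg)
  ck(cfg$geometry$a_out_mm > 0 && cfg$geometry$b_out_mm > 0,
     "outer semi-axes must be positive")
  ck(cfg$geometry$a_out_mm > 1 && cfg$geometry$b_out_mm > 1,
     "outer semi-axes look like metres; config lengths are millimetres")
  ck(cfg$lesion$depth_mm > 0.2,
     "lesion depth looks like metres; config lengths are millimetres")
  ck(cfg$lesion$stage %in% .LESION_STAGES, "unknown lesion stage")
  ck(cfg$mesh$h_fine_mm > 0 && cfg$mesh$h_coarse_mm >= cfg$mesh$h_fine_mm,
     "mesh sizes must satisfy 0 < h_fine <= h_coarse")
  ck(cfg$solver$dt_fine > 0 && cfg$solver$dt_coarse > 0,
     "time steps must be positive")
  ck(cfg$solver$t_fine > cfg$protocol$t_cool,
     "fine-step window must cover the cooling phase")
  ck(cfg$protocol$h_inf > 0, "film coefficient must be positive")
  ck(cfg$protocol$t_end >= cfg$solver$t_fine,
     "t_end must not precede the fine-step window")
  ck(all(is.finite(c(cfg$protocol$T_inf, cfg$protocol$T_cool,
                     cfg$protocol$T_core))), "temperatures must be finite")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file, merges it over the defaults
#' (unknown keys are rejected with their key path) and validates physical
#' sanity. An empty file yields the full default configuration.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`); `NULL` gives defaults
#' @return a validated `run_config`
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration error: no such file: ", path)
    ov <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.null(ov) && length(ov)) cfg <- .merge_config(cfg, ov)
  }
  .validate_config(structure(cfg, class = "run_config"))
}

#' Serialise a run configuration
#'
#' @param cfg a `run_config`
#' @param path optional output file; `NULL` returns the YAML text
#' @return the YAML text, invisibly when written to `path`
#' @export
dump_config <- function(cfg = default_config(), path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Protocol configuration from a run configuration
#' @param cfg a `run_config`
#' @return a [protocol_config()]
#' @export
protocol_from_config <- function(cfg) {
  protocol_config(h_inf = cfg$protocol$h_inf, T_inf = cfg$protocol$T_inf,
                  T_cool = cfg$protocol$T_cool, t_cool = cfg$protocol$t_cool,
                  T_core = cfg$protocol$T_core, t_end = cfg$protocol$t_end,
                  dt_fine = cfg$solver$dt_fine, t_fine = cfg$solver$t_fine,
                  dt_coarse = cfg$solver$dt_coarse)
}

#' Named scenario fixtures
#'
#' Stable named configurations reproducing every scenario of the reference
#' study plus the mesh-refinement check (`mesh_refined`, fine element size
#' halved to 0.65 mm).
#'
#' @return named list of `run_config` objects
#' @export
fixtures <- function() {
  sc <- study_scenarios()
  out <- lapply(seq_len(nrow(sc)), function(i) {
    cfg <- default_config()
    cfg$lesion$stage <- sc$stage[i]
    cfg$lesion$depth_mm <- sc$depth_mm[i]
    cfg
  })
  names(out) <- sc$name
  refined <- default_config()
  refined$mesh$h_fine_mm <- 0.65
  out$mesh_refined <- refined
  out
}
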