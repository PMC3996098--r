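# Layer order from the skin surface inward. Thicknesses in metres.
.LAYER_NAMES <- c("epidermis", "papillary_dermis", "reticular_dermis", "fat", "muscle")
.LAYER_THICKNESS_M <- c(0.46, 1.67, 1.67, 5, 2.5) * 1e-3

# Default blood properties used in the perfusion term (config-overridable).
.BLOOD_RHO <- 1060   # kg/m^3
.BLOOD_C <- 3770     # J/(kg K)

.LESION_STAGES <- c("healthy", "ischemia", "inflammation",
                    "multilayer_mild", "multilayer_severe")

#' Thermophysical properties of a tissue region
#'
#' Container for the coefficients of the Pennes bioheat equation
#' \deqn{\rho c \partial T/\partial t = \nabla\cdot k\nabla T +
#'   \omega_b \rho_b c_b (T_b - T) + q}
#' for one homogeneous tissue region.
#'
#' @param rho tissue density, kg/m^3
#' @param c specific heat, J/(kg K)
#' @param k thermal conductivity, W/(m K)
#' @param omega_b blood perfusion rate, 1/s
#' @param q_met metabolic heat generation, W/m^3
#' @param T_b arterial blood temperature, degrees C (may be `NA` when
#'   `omega_b == 0`, in which case the perfusion term vanishes)
#' @param rho_b blood density, kg/m^3
#' @param c_b blood specific heat, J/(kg K)
#' @return an object of class `material_properties` (a named list)
#' @export
material_properties <- function(rho, c, k, omega_b, q_met, T_b = NA_real_,
                                rho_b = .BLOOD_RHO, c_b = .BLOOD_C) {
  stopifnot(rho > 0, c > 0, k > 0, omega_b >= 0, q_met >= 0,
            rho_b > 0, c_b > 0)
  if (omega_b > 0) {
    if (!is.finite(T_b) || T_b < 30 || T_b > 40)
      stop("arterial blood temperature T_b must lie in [30, 40] C when perfusion is active")
  }
  structure(list(rho = rho, c = c, k = k, omega_b = omega_b,
                 q_met = q_met, T_b = T_b, rho_b = rho_b, c_b = c_b),
            class = "material_properties")
}

# Baseline per-layer properties (healthy tissue).  The epidermis is avascular
# and metabolically inert, so its perfusion and source terms are zero.
.layer_property_table <- function(rho_b = .BLOOD_RHO, c_b = .BLOOD_C) {
  list(
    epidermis        = material_properties(1200, 3589, 0.235, 0,        0,     NA_real_, rho_b, c_b),
    papillary_dermis = material_properties(1200, 3300, 0.445, 0.18e-3,  368.1, 37, rho_b, c_b),
    reticular_dermis = material_properties(1200, 3300, 0.445, 1.26e-3,  368.1, 37, rho_b, c_b),
    fat              = material_properties(1000, 2674, 0.185, 0.08e-3,  368.3, 37, rho_b, c_b),
    muscle           = material_properties(1085, 3600, 0.51,  2.7e-3,   684.2, 37, rho_b, c_b)
  )
}

# Lesion-stage properties: a degenerated ischemic core (reduced conductivity,
# perfusion, metabolism, cooler arterial supply) and a hyperaemic inflamed
# region (raised conductivity, perfusion and metabolic heat generation).
.lesion_property_table <- function(rho_b = .BLOOD_RHO, c_b = .BLOOD_C) {
  list(
    ischemia     = material_properties(1037, 2450, 0.1,   0.405e-3, 342.1,  35, rho_b, c_b),
    inflammation = material_properties(1037, 2450, 0.558, 6.95e-3,  5262.5, 37, rho_b, c_b)
  )
}

#' Default heel layer stack
#'
#' The five soft-tissue layers of the heel model (epidermis, papillary dermis,
#' reticular dermis, fat, muscle), from the skin surface inward, with default
#' thicknesses 0.46, 1.67, 1.67, 5 and 2.5 mm (11.3 mm total; the muscle-bone
#' interface, held at core temperature, lies at that depth).
#'
#' @param thickness_mm optional named numeric vector overriding individual
#'   layer thicknesses (mm)
#' @param props optional named list of `material_properties` overrides
#' @param rho_b,c_b blood density and specific heat used for layers without
#'   an explicit override
#' @return a list of layer specs, each with `name`, `thickness` (m), `props`
#' @export
heel_layers <- function(thickness_mm = NULL, props = NULL,
                        rho_b = .BLOOD_RHO, c_b = .BLOOD_C) {
  th <- .LAYER_THICKNESS_M
  names(th) <- .LAYER_NAMES
  if (!is.null(thickness_mm)) {
    bad <- setdiff(names(thickness_mm), .LAYER_NAMES)
    if (length(bad)) stop("unknown layer name(s): ", paste(bad, collapse = ", "))
    th[names(thickness_mm)] <- thickness_mm * 1e-3
  }
  if (any(th <= 0)) stop("layer thicknesses must be positive")
  tab <- .layer_property_table(rho_b, c_b)
  if (!is.null(props)) {
    bad <- setdiff(names(props), .LAYER_NAMES)
    if (length(bad)) stop("unknown layer name(s) in props: ", paste(bad, collapse = ", "))
    for (nm in names(props)) tab[[nm]] <- props[[nm]]
  }
  layers <- lapply(.LAYER_NAMES, function(nm)
    list(name = nm, thickness = unname(th[[nm]]), props = tab[[nm]]))
  names(layers) <- .LAYER_NAMES
  structure(layers, class = "heel_layers")
}

#' Cumulative layer depths
#'
#' @param layers a `heel_layers` stack
#' @return numeric vector of cumulative depths (m) of the layer interfaces,
#'   starting at 0 (skin surface) and ending at the muscle-bone interface
#' @export
layer_depths <- function(layers) {
  c(0, cumsum(vapply(layers, function(l) l$thickness, numeric(1))))
}

#' Deep tissue injury lesion specification
#'
#' An elliptical lesion embedded in the soft tissue, centred on the symmetry
#' axis at `depth_mm` below the skin surface, with tangential major axis `d1`
#' and normal minor axis `d2`. Multilayer stages carry an inflammation shell
#' of thickness `shell_mm` around the ischemic core; for
#' `multilayer_severe` the inflamed region additionally extends from the core
#' to the skin surface.
#'
#' @param stage one of `"healthy"`, `"ischemia"`, `"inflammation"`,
#'   `"multilayer_mild"`, `"multilayer_severe"`
#' @param depth_mm depth of the lesion centre below the skin surface, mm
#' @param d1_mm,d2_mm major (tangential) and minor (normal) full axes, mm
#' @param shell_mm inflammation shell thickness (multilayer stages only), mm
#' @param offset_mm lateral offset of the lesion centre from the symmetry
#'   axis, mm (0 = centred, the default reading of the model geometry)
#' @return a `lesion_spec` object
#' @export
lesion_spec <- function(stage = "healthy", depth_mm = 8, d1_mm = 15,
                        d2_mm = 2.5, shell_mm = 1.25, offset_mm = 0) {
  stage <- match.arg(stage, .LESION_STAGES)
  stopifnot(depth_mm > 0, d1_mm >= 0, d2_mm >= 0, shell_mm > 0)
  structure(list(stage = stage,
                 center_depth = depth_mm * 1e-3,
                 d1 = d1_mm * 1e-3, d2 = d2_mm * 1e-3,
                 shell_thickness = shell_mm * 1e-3,
                 lateral_offset = offset_mm * 1e-3),
            class = "lesion_spec")
}

#' Properties of a named region under a given lesion stage
#'
#' Maps a region tag to the material properties used in the simulation:
#' layers always use their baseline row; `"lesion_core"` uses the ischemia
#' row for `ischemia` and multilayer stages and the inflammation row for
#' `inflammation`; `"lesion_shell"` (multilayer stages only) uses the
#' inflammation row. For `stage = "healthy"` the lesion is thermally absent:
#' `enclosing_layer` must name the layer whose properties the lesion region
#' inherits.
#'
#' @param region a layer name, `"lesion_core"` or `"lesion_shell"`
#' @param stage lesion stage
#' @param enclosing_layer layer name used for lesion regions when
#'   `stage = "healthy"`
#' @param layers layer stack (source of baseline rows)
#' @param rho_b,c_b blood properties for the lesion rows
#' @return a `material_properties` object
#' @export
properties_for <- function(region, stage = "healthy", enclosing_layer = NULL,
                           layers = heel_layers(), rho_b = .BLOOD_RHO,
                           c_b = .BLOOD_C) {
  stage <- match.arg(stage, .LESION_STAGES)
  if (region %in% names(layers)) return(layers[[region]]$props)
  if (!region %in% c("lesion_core", "lesion_shell"))
    stop("unknown region tag: ", region)
  if (stage == "healthy") {
    # thermal invisibility: lesion regions inherit the enclosing layer
    if (is.null(enclosing_layer) || !enclosing_layer %in% names(layers))
      stop("healthy stage requires the enclosing layer for lesion regions")
    return(layers[[enclosing_layer]]$props)
  }
  if (region == "lesion_shell" && !stage %in% c("multilayer_mild", "multilayer_severe"))
    stop("lesion_shell is only defined for multilayer stages, not ", stage)
  tab <- .lesion_property_table(rho_b, c_b)
  if (region == "lesion_shell") return(tab$inflammation)
  switch(stage,
         ischemia = tab$ischemia,
         inflammation = tab$inflammation,
         multilayer_mild = tab$ischemia,
         multilayer_severe = tab$ischemia)
}

#' Layers intersected by the lesion
#'
#' Returns the names of the layers whose depth band intersects the vertical
#' extent `[depth - d2/2, depth + d2/2]` of the lesion core on the symmetry
#' axis. Errors if the lesion extends above the skin surface or below the
#' muscle-bone interface.
#'
#' @param lesion a `lesion_spec`
#' @param layers a `heel_layers` stack
#' @return character vector of layer names
#' @export
classify_lesion_layers <- function(lesion, layers = heel_layers()) {
  depths <- layer_depths(layers)
  lo <- lesion$center_depth - lesion$d2 / 2
  hi <- lesion$center_depth + lesion$d2 / 2
  if (lo < 0) stop("lesion extends beyond the skin surface")
  if (hi > depths[length(depths)]) stop("lesion extends into the bone")
  hit <- character(0)
  for (i in seq_along(layers)) {
    if (lo < depths[i + 1] && hi > depths[i]) hit <- c(hit, names(layers)[i])
  }
  hit
}
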