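# Deterministic boundary-fitted triangulation of the heel shell.
#
# The domain is meshed in normal-offset coordinates (t, s): columns are the
# inward normal rays of the outer arc at equally spaced arc lengths, and each
# column carries a chain of nodes at depths s.  Chains always contain every
# layer-interface depth plus the exact intersections of the ray with the
# lesion core (and shell) ellipse, so layer interfaces and the lesion outline
# are resolved by element edges.  Adjacent chains are joined by a merge
# triangulation, which stays conforming even when neighbouring chains carry
# different numbers of nodes (e.g. near the lesion tips).  The construction
# is fully deterministic.

.FINE_REGIONS <- c("epidermis", "fat", "muscle", "lesion_core", "lesion_shell")

# Classify a point by region tag, given its column parameter t and depth s.
# Severe multilayer inflammation spans the normal-projection band between
# the core outline and the skin surface in addition to the shell.
.classify_region <- function(geom, ells, x, y, t, s) {
  if (!is.null(ells)) {
    if (.in_ellipse(x, y, ells$core)) return("lesion_core")
    if (!is.null(ells$shell_w)) {
      if (.in_offset_band(x, y, ells$core, ells$shell_w)) return("lesion_shell")
      if (geom$lesion$stage == "multilayer_severe") {
        p0 <- .ellipse_point(t, geom$a_out, geom$b_out)[1, ]
        nrm <- .ellipse_normal(t, geom$a_out, geom$b_out)[1, ]
        cr <- .ray_ellipse_crossings(p0, nrm, ells$core, geom$smax)
        if (length(cr) == 2 && s < cr[1]) return("lesion_shell")
      }
    }
  }
  idx <- findInterval(s, geom$depths, rightmost.closed = TRUE, all.inside = TRUE)
  names(geom$layers)[idx]
}

.layer_of_depth <- function(geom, s) {
  idx <- findInterval(s, geom$depths, rightmost.closed = TRUE, all.inside = TRUE)
  names(geom$layers)[idx]
}

# Refine a sorted vector of mandatory depths so that no gap exceeds the
# region-dependent target spacing ds(mid).
.refine_chain <- function(mandatory, ds_of_mid) {
  out <- mandatory[1]
  for (i in seq_len(length(mandatory) - 1)) {
    s1 <- mandatory[i]; s2 <- mandatory[i + 1]
    n <- max(1L, ceiling((s2 - s1) / ds_of_mid((s1 + s2) / 2) - 1e-9))
    out <- c(out, s1 + (s2 - s1) * seq_len(n) / n)
  }
  out
}

#' Triangulate the heel geometry
#'
#' Generates a conforming triangular mesh of the soft-tissue shell with
#' per-triangle region tags (layer name, `lesion_core`, `lesion_shell`) and
#' underlying-layer tags, and tagged boundary edges (`skin`, `top_flat`,
#' `bone_interface`). Maximum edge length is `h_fine_mm` in the epidermis,
#' fat, muscle and lesion regions and `h_coarse_mm` in the dermis layers.
#'
#' @param geom a [heel_geometry()]
#' @param h_fine_mm,h_coarse_mm maximum element edge lengths, mm
#' @return a `heel_mesh` object
#' @export
build_mesh <- function(geom, h_fine_mm = 1.3, h_coarse_mm = 2.4) {
  stopifnot(inherits(geom, "heel_geometry"),
            h_fine_mm > 0, h_fine_mm <= h_coarse_mm)
  # target grid spacing h/2 keeps every edge (including hypotenuses) below
  # the region's maximum element size with margin
  hf <- h_fine_mm * 1e-3 / 2
  hc <- h_coarse_mm * 1e-3 / 2
  L <- geom$arc$total
  nint <- ceiling(L / hf)
  if (nint %% 2 == 1) nint <- nint + 1   # place a column exactly at the apex
  lcols <- L * seq(0, nint) / nint
  tcols <- geom$arc$t_of_l(lcols)
  # enforce exact mirror symmetry of the column parameters about the apex
  half <- nint / 2
  tcols[half + 1] <- pi / 2
  tcols[(half + 2):(nint + 1)] <- pi - rev(tcols[1:half])

  ells <- .lesion_ellipses(geom)
  E <- .ellipse_point(tcols, geom$a_out, geom$b_out)
  N <- .ellipse_normal(tcols, geom$a_out, geom$b_out)

  chains <- vector("list", nint + 1)
  for (j in seq_len(nint + 1)) {
    mand <- geom$depths
    cross <- numeric(0)
    core_band <- if (!is.null(ells))
      .ray_ellipse_crossings(E[j, ], N[j, ], ells$core, geom$smax) else numeric(0)
    shell_band <- if (!is.null(ells) && !is.null(ells$shell_w))
      .ray_offset_band_crossings(E[j, ], N[j, ], ells$core, ells$shell_w,
                                 geom$smax) else numeric(0)
    cross <- c(cross, core_band, shell_band)
    mand <- sort(unique(c(mand, cross)))
    mand <- mand[c(TRUE, diff(mand) > 1e-7)]
    ds_of_mid <- function(sm) {
      if (length(core_band) == 2 && sm > core_band[1] && sm < core_band[2]) return(hf)
      if (length(shell_band) == 2 && sm > shell_band[1] && sm < shell_band[2]) return(hf)
      if (.layer_of_depth(geom, sm) %in% c("epidermis", "fat", "muscle")) hf else hc
    }
    chains[[j]] <- .refine_chain(mand, ds_of_mid)
  }

  # assemble node table
  nnode_col <- vapply(chains, length, integer(1))
  offs <- c(0L, cumsum(nnode_col))
  nn <- offs[nint + 2]
  xs <- numeric(nn); ys <- numeric(nn); ts <- numeric(nn); ss <- numeric(nn)
  for (j in seq_len(nint + 1)) {
    s <- chains[[j]]
    idx <- (offs[j] + 1):(offs[j] + length(s))
    xs[idx] <- E[j, 1] - s * N[j, 1]
    ys[idx] <- E[j, 2] - s * N[j, 2]
    ts[idx] <- tcols[j]
    ss[idx] <- s
  }

  # merge triangulation across each column strip
  tris <- vector("list", nint)
  for (j in seq_len(nint)) {
    CL <- (offs[j] + 1):(offs[j] + nnode_col[j])
    CR <- (offs[j + 1] + 1):(offs[j + 1] + nnode_col[j + 1])
    SL <- chains[[j]]; SR <- chains[[j + 1]]
    m <- length(CL); n <- length(CR)
    tcount <- (m - 1) + (n - 1)
    tmat <- matrix(0L, tcount, 3)
    i <- 1L; k <- 1L; r <- 1L
    # on ties the diagonal direction flips at the apex so the triangulation
    # (and hence the discrete solution) is mirror-symmetric
    tie_left <- j <= nint / 2
    while (i < m || k < n) {
      adv_left <- if (i >= m) FALSE else if (k >= n) TRUE else
        if (SL[i + 1] == SR[k + 1]) tie_left else SL[i + 1] < SR[k + 1]
      if (adv_left) {
        tmat[r, ] <- c(CL[i], CR[k], CL[i + 1]); i <- i + 1L
      } else {
        tmat[r, ] <- c(CL[i], CR[k], CR[k + 1]); k <- k + 1L
      }
      r <- r + 1L
    }
    tris[[j]] <- tmat
  }
  tri <- do.call(rbind, tris)

  # canonical positive orientation
  ax <- xs[tri[, 2]] - xs[tri[, 1]]; ay <- ys[tri[, 2]] - ys[tri[, 1]]
  bx <- xs[tri[, 3]] - xs[tri[, 1]]; by <- ys[tri[, 3]] - ys[tri[, 1]]
  neg <- (ax * by - ay * bx) < 0
  tri[neg, c(2, 3)] <- tri[neg, c(3, 2)]

  # region and layer tags from centroids
  cx <- (xs[tri[, 1]] + xs[tri[, 2]] + xs[tri[, 3]]) / 3
  cy <- (ys[tri[, 1]] + ys[tri[, 2]] + ys[tri[, 3]]) / 3
  ct <- (ts[tri[, 1]] + ts[tri[, 2]] + ts[tri[, 3]]) / 3
  cs <- (ss[tri[, 1]] + ss[tri[, 2]] + ss[tri[, 3]]) / 3
  ntri <- nrow(tri)
  region <- character(ntri); layer <- character(ntri)
  for (e in seq_len(ntri)) {
    region[e] <- .classify_region(geom, ells, cx[e], cy[e], ct[e], cs[e])
    layer[e] <- .layer_of_depth(geom, cs[e])
  }

  # boundary edges
  top_idx <- offs[seq_len(nint + 1)] + 1L                      # s = 0 nodes
  bot_idx <- offs[seq_len(nint + 1)] + nnode_col               # s = smax nodes
  skin_edges <- cbind(top_idx[-(nint + 1)], top_idx[-1])
  bone_edges <- cbind(bot_idx[-(nint + 1)], bot_idx[-1])
  left_chain <- (offs[1] + 1):(offs[1] + nnode_col[1])
  right_chain <- (offs[nint + 1] + 1):(offs[nint + 1] + nnode_col[nint + 1])
  flat_edges <- rbind(cbind(left_chain[-length(left_chain)], left_chain[-1]),
                      cbind(right_chain[-length(right_chain)], right_chain[-1]))

  structure(list(
    nodes = cbind(x = xs, y = ys), tri = tri,
    region = region, layer = layer,
    node_t = ts, node_s = ss,
    skin_nodes = top_idx, skin_l = lcols,
    bone_nodes = unique(as.vector(bone_edges)),
    edges = list(skin = skin_edges, bone_interface = bone_edges,
                 top_flat = flat_edges),
    geom = geom, h_fine = h_fine_mm * 1e-3, h_coarse = h_coarse_mm * 1e-3
  ), class = "heel_mesh")
}

#' @export
print.heel_mesh <- function(x, ...) {
  cat(sprintf("heel_mesh: %d nodes, %d triangles, %d skin boundary nodes\n",
              nrow(x$nodes), nrow(x$tri), length(x$skin_nodes)))
  tb <- table(x$region)
  cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Triangle areas of a mesh
#' @param mesh a `heel_mesh`
#' @return numeric vector of element areas (m^2)
#' @export
triangle_areas <- function(mesh) {
  p <- mesh$nodes; tri <- mesh$tri
  ax <- p[tri[, 2], 1] - p[tri[, 1], 1]; ay <- p[tri[, 2], 2] - p[tri[, 1], 2]
  bx <- p[tri[, 3], 1] - p[tri[, 1], 1]; by <- p[tri[, 3], 2] - p[tri[, 1], 2]
  (ax * by - ay * bx) / 2
}

#' Arc-length coordinate of the skin boundary nodes
#'
#' Distance along the heel periphery (mm), measured from the end of the skin
#' arc with the lower x-coordinate. For the symmetric default geometry the
#' apex (symmetry axis) sits at half the total arc length.
#'
#' @param mesh a `heel_mesh`
#' @return data frame with columns `node` (index) and `l_mm`
#' @export
arc_coordinate <- function(mesh) {
  data.frame(node = mesh$skin_nodes, l_mm = mesh$skin_l * 1e3)
}

# Rectangular multilayer strip mesh (width w, layer stack downward from
# y = 0).  Used for one-dimensional verification problems: the sides carry
# the natural zero-flux condition (tagged top_flat), the top edge is tagged
# skin and the bottom bone_interface.  `bands` may override the layer depth
# bands, e.g. a single uniform band for conduction benchmarks.
#' Rectangular multilayer strip mesh
#'
#' Builds a thin rectangular mesh of the layer stack (or an arbitrary depth
#' `total_depth`), for pseudo-one-dimensional verification against closed
#' form solutions: adiabatic sides, `skin` top edge, `bone_interface` bottom.
#'
#' @param layers layer stack; bands are the cumulative layer depths
#' @param width_mm strip width, mm
#' @param dx_mm,dy_mm target element edge lengths, mm
#' @param total_depth_mm optional override of the strip depth (single band)
#' @return a `heel_mesh`-compatible object (flat geometry)
#' @export
build_strip_mesh <- function(layers = heel_layers(), width_mm = 2,
                             dx_mm = 0.5, dy_mm = 0.25,
                             total_depth_mm = NULL) {
  w <- width_mm * 1e-3
  if (is.null(total_depth_mm)) {
    depths <- layer_depths(layers)
  } else {
    depths <- c(0, total_depth_mm * 1e-3)
  }
  smax <- depths[length(depths)]
  dy <- dy_mm * 1e-3
  sv <- depths[1]
  for (i in seq_len(length(depths) - 1)) {
    n <- max(1L, ceiling((depths[i + 1] - depths[i]) / dy))
    sv <- c(sv, depths[i] + (depths[i + 1] - depths[i]) * seq_len(n) / n)
  }
  nx <- max(1L, ceiling(w / (dx_mm * 1e-3)))
  xcols <- w * seq(0, nx) / nx
  nrow_ <- length(sv)
  nn <- (nx + 1) * nrow_
  xs <- rep(xcols, each = nrow_)
  ys <- rep(-sv, nx + 1)
  ss <- rep(sv, nx + 1)
  tris <- vector("list", nx)
  for (j in seq_len(nx)) {
    CL <- ((j - 1) * nrow_ + 1):(j * nrow_)
    CR <- (j * nrow_ + 1):((j + 1) * nrow_)
    tmat <- matrix(0L, 2 * (nrow_ - 1), 3)
    r <- 1L
    for (i in seq_len(nrow_ - 1)) {
      tmat[r, ] <- c(CL[i], CR[i], CL[i + 1]); r <- r + 1L
      tmat[r, ] <- c(CL[i + 1], CR[i], CR[i + 1]); r <- r + 1L
    }
    tris[[j]] <- tmat
  }
  tri <- do.call(rbind, tris)
  ax <- xs[tri[, 2]] - xs[tri[, 1]]; ay <- ys[tri[, 2]] - ys[tri[, 1]]
  bx <- xs[tri[, 3]] - xs[tri[, 1]]; by <- ys[tri[, 3]] - ys[tri[, 1]]
  neg <- (ax * by - ay * bx) < 0
  tri[neg, c(2, 3)] <- tri[neg, c(3, 2)]
  cs <- (ss[tri[, 1]] + ss[tri[, 2]] + ss[tri[, 3]]) / 3
  if (is.null(total_depth_mm)) {
    idx <- findInterval(cs, depths, rightmost.closed = TRUE, all.inside = TRUE)
    layer <- names(layers)[idx]
  } else {
    layer <- rep(names(layers)[1], nrow(tri))
  }
  top_idx <- seq(1L, nn, by = nrow_)
  bot_idx <- seq(nrow_, nn, by = nrow_)
  skin_edges <- cbind(top_idx[-length(top_idx)], top_idx[-1])
  bone_edges <- cbind(bot_idx[-length(bot_idx)], bot_idx[-1])
  left_chain <- 1:nrow_
  right_chain <- (nn - nrow_ + 1):nn
  flat_edges <- rbind(cbind(left_chain[-nrow_], left_chain[-1]),
                      cbind(right_chain[-nrow_], right_chain[-1]))
  structure(list(
    nodes = cbind(x = xs, y = ys), tri = tri,
    region = layer, layer = layer,
    node_t = xs, node_s = ss,
    skin_nodes = top_idx, skin_l = xcols,
    bone_nodes = unique(as.vector(bone_edges)),
    edges = list(skin = skin_edges, bone_interface = bone_edges,
                 top_flat = flat_edges),
    geom = list(layers = layers, depths = depths, smax = smax, lesion = NULL),
    h_fine = dx_mm * 1e-3, h_coarse = dx_mm * 1e-3
  ), class = "heel_mesh")
}

#' Export a mesh in legacy VTK format
#'
#' Writes an ASCII legacy-VTK unstructured grid with the region tag as a
#' cell field and, optionally, a nodal temperature field as point data.
#'
#' @param mesh a `heel_mesh`
#' @param path output file path
#' @param temperature optional per-node temperatures to embed as point data
#' @return `path`, invisibly
#' @export
write_mesh_vtk <- function(mesh, path, temperature = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0", "heel mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  regs <- sort(unique(mesh$region))
  writeLines(c(sprintf("CELL_DATA %d", nt), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, regs) - 1L), con)
  if (!is.null(temperature)) {
    writeLines(c(sprintf("POINT_DATA %d", nn),
                 "SCALARS temperature double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", temperature), con)
  }
  invisible(path)
}
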