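mesh_default <- function() cached("mesh_isch8",
  build_mesh(heel_geometry(lesion = lesion_spec("ischemia", 8))))

test_that("triangles tile the domain exactly and conform", {
  m <- mesh_default()
  A <- triangle_areas(m)
  expect_true(all(A > 0))
  # boundary polygon: skin arc, right flat edge, bone arc, left flat edge
  t_min <- min(m$node_t); t_max <- max(m$node_t)
  left <- which(abs(m$node_t - t_min) < 1e-12)
  right <- which(abs(m$node_t - t_max) < 1e-12)
  left <- left[order(m$node_s[left])]
  right <- right[order(m$node_s[right])]
  bone <- m$bone_nodes  # ordered left-to-right by construction
  loop <- c(m$skin_nodes, right[-1], rev(bone)[-1], rev(left)[-1])
  loop <- loop[!duplicated(loop)]
  px <- m$nodes[loop, 1]; py <- m$nodes[loop, 2]
  shoelace <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  expect_equal(sum(A), shoelace, tolerance = 1e-10)

  # conformity: interior edges shared by exactly two triangles, boundary by one
  ed <- rbind(m$tri[, c(1, 2)], m$tri[, c(2, 3)], m$tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  expect_true(all(cnt <= 2))
  be <- do.call(rbind, m$edges)
  bkey <- paste(pmin(be[, 1], be[, 2]), pmax(be[, 1], be[, 2]))
  expect_setequal(names(cnt)[cnt == 1], bkey)
})

test_that("element sizes respect the per-region bounds", {
  m <- mesh_default()
  p <- m$nodes; tri <- m$tri
  elen <- function(i, j) sqrt((p[tri[, i], 1] - p[tri[, j], 1])^2 +
                              (p[tri[, i], 2] - p[tri[, j], 2])^2)
  maxedge <- pmax(elen(1, 2), elen(2, 3), elen(3, 1))
  fine <- m$region %in% c("epidermis", "fat", "muscle", "lesion_core",
                          "lesion_shell")
  expect_lte(max(maxedge[fine]), m$h_fine * (1 + 1e-9))
  expect_lte(max(maxedge), m$h_coarse * (1 + 1e-9))
  # element count is on the scale of the reference discretisation (~4.9e3)
  expect_gt(nrow(tri), 4932 / 2)
  expect_lt(nrow(tri), 4932 * 2)
})

test_that("lesion tagging is consistent with the lesion ellipse", {
  m <- mesh_default()
  ells <- dtitherm:::.lesion_ellipses(m$geom)
  cx <- rowMeans(matrix(m$nodes[m$tri, 1], ncol = 3))
  cy <- rowMeans(matrix(m$nodes[m$tri, 2], ncol = 3))
  core <- m$region == "lesion_core"
  expect_true(all(dtitherm:::.in_ellipse(cx[core], cy[core], ells$core)))
  # tagged lesion area approximates the ellipse area
  expect_equal(sum(triangle_areas(m)[core]), pi * ells$core$rx * ells$core$ry,
               tolerance = 0.02)
  # underlying layers of the 8 mm core: fat and muscle only
  expect_setequal(unique(m$layer[core]), c("fat", "muscle"))
})

test_that("arc coordinate is strictly increasing, symmetric and complete", {
  m <- mesh_default()
  ac <- arc_coordinate(m)
  expect_true(all(diff(ac$l_mm) > 0))
  expect_equal(min(ac$l_mm), 0)
  expect_equal(max(ac$l_mm), m$geom$arc$total * 1e3)
  # l = 0 starts at the arc end with the lower x-coordinate
  expect_equal(unname(m$nodes[ac$node[1], 1]), -m$geom$a_out)
  # apex maps to half the total arc length
  expect_equal(ac$l_mm[apex_index(m)], m$geom$arc$total * 1e3 / 2,
               tolerance = 1e-9)
  # reversing the node order mirrors the coordinate
  expect_equal(rev(max(ac$l_mm) - ac$l_mm), ac$l_mm, tolerance = 1e-9)
})

test_that("VTK export writes a well-formed legacy file", {
  m <- build_strip_mesh(width_mm = 1, dx_mm = 0.5, dy_mm = 1)
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f, temperature = rep(37, nrow(m$nodes)))
  txt <- readLines(f)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_equal(sum(grepl("^POINTS", txt)), 1)
  expect_equal(as.integer(sub("CELLS (\\d+) .*", "\\1", grep("^CELLS", txt, value = TRUE))),
               nrow(m$tri))
  unlink(f)
})
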