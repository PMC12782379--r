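test_that("mesh files round-trip across formats with duplicate vertices merged", {
  cube <- fixture_cube()
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  obj <- tempfile(fileext = ".obj")
  write_mesh(cube, stl)
  write_mesh(cube, ply)
  write_mesh(cube, obj)
  # binary STL stores 36 vertices; loading must merge them back to 8
  m_stl <- load_mesh(stl)
  expect_equal(nrow(m_stl$vertices), 8)
  expect_equal(nrow(m_stl$faces), 12)
  m_ply <- load_mesh(ply)
  m_obj <- load_mesh(obj)
  sorted <- function(m) m$vertices[do.call(order, as.data.frame(m$vertices)), ]
  expect_equal(sorted(m_stl), sorted(m_ply), tolerance = 1e-6)
  expect_identical(sorted(m_ply), sorted(m_obj))
  # ASCII STL reader
  astl <- tempfile(fileext = ".stl")
  lines <- c("solid cube")
  for (i in seq_len(nrow(cube$faces))) {
    tri <- cube$vertices[cube$faces[i, ], ]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               sprintf("vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid cube"), astl)
  m_astl <- load_mesh(astl)
  expect_equal(nrow(m_astl$vertices), 8)
})

test_that("degenerate mesh files are rejected with a format error", {
  empty <- tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(load_mesh(empty), "unreadable or empty")
  expect_error(load_mesh(tempfile(fileext = ".stl")), "unreadable or empty")
  expect_error(trimesh(matrix(0, 3, 3), matrix(1L, 4, 3)), "at least 4")
  expect_error(trimesh(matrix(rnorm(12), 4, 3), rbind(c(1, 2, 5), c(1, 2, 3),
                                                      c(1, 3, 4), c(2, 3, 4))),
               "out of range")
})

test_that("surface sampling is seeded, area-uniform and lies on the surface", {
  sp <- fixture_sphere(r = 1, n = 48)
  a <- sample_surface(sp, 2000, seed = 7)
  b <- sample_surface(sp, 2000, seed = 7)
  expect_identical(a$points, b$points)
  expect_identical(a$normals, b$normals)
  # analytic radius of a unit sphere
  pc <- sample_surface(sp, 10000, seed = 1)
  expect_equal(mean(sqrt(rowSums(pc$points^2))), 1, tolerance = 0.02)
  # normals are unit and outward
  expect_equal(max(abs(sqrt(rowSums(pc$normals^2)) - 1)), 0, tolerance = 1e-9)
  radial <- pc$points / sqrt(rowSums(pc$points^2))
  expect_gt(mean(rowSums(pc$normals * radial)), 0.99)
  # per-face counts on a cube follow area proportions (multinomial, 3 SD)
  cube <- fixture_cube()
  n <- 60000
  pts <- sample_surface(cube, n, seed = 3)$points
  on_face <- function(coord, val) sum(abs(pts[, coord] - val) < 1e-12)
  counts <- c(on_face(1, 0), on_face(1, 1), on_face(2, 0), on_face(2, 1),
              on_face(3, 0), on_face(3, 1))
  expect_equal(sum(counts), n)
  p0 <- 1 / 6
  sd3 <- 3 * sqrt(n * p0 * (1 - p0))
  expect_true(all(abs(counts - n * p0) < sd3))
})

test_that("voxel volume matches closed forms and the cubic scaling law", {
  expect_equal(mesh_volume(fixture_cube(), pitch = 0.05), 1, tolerance = 0.02)
  cyl <- fixture_cylinder(r = 20, h = 80, n = 128)
  expect_equal(mesh_volume(cyl, pitch = 0.5), pi * 400 * 80, tolerance = 0.02)
  cone <- fixture_cone(r = 15, h = 60, n = 128)
  expect_equal(mesh_volume(cone, pitch = 0.5), pi * 225 * 60 / 3,
               tolerance = 0.02)
  # scaling a mesh by s multiplies the volume by s^3
  s <- 1.7
  scaled <- trimesh(cyl$vertices * s, cyl$faces)
  expect_equal(mesh_volume(scaled, pitch = 0.5) / mesh_volume(cyl, pitch = 0.5),
               s^3, tolerance = 0.02)
})

test_that("cap_openings closes boundary loops and is the identity on closed meshes", {
  open_cyl <- fixture_cylinder(r = 12, h = 50, caps = FALSE)
  expect_false(is_watertight(open_cyl))
  capped <- cap_openings(open_cyl)
  expect_true(is_watertight(capped))
  expect_equal(mesh_volume(capped, pitch = 0.25), pi * 144 * 50,
               tolerance = 0.02)
  closed <- fixture_cube()
  expect_identical(cap_openings(closed), closed)
  # synthetic socket: proximal opening + olecranon cutout -> 2 capped loops
  limb <- fixture_limb(noise_sd = 0)$mesh
  sock <- derive_socket(limb, socket_design(cutout = TRUE))$mesh
  expect_length(pactr:::boundary_loops(sock), 2)
  capped2 <- cap_openings(sock)
  expect_true(is_watertight(capped2))
  # Euler characteristic of a closed genus-0 surface: V - E + F = 2
  e <- nrow(capped2$faces) * 3 / 2
  expect_equal(nrow(capped2$vertices) - e + nrow(capped2$faces), 2)
})

test_that("planar slices match analytic section areas and chord-close open shells", {
  cyl <- fixture_cylinder(r = 10, h = 40, n = 256)
  s <- slice_area(cyl, 20)
  expect_equal(s$area, pi * 100, tolerance = 0.01)
  cone <- fixture_cone(r = 15, h = 60, n = 256)
  z <- 45
  expect_equal(slice_area(cone, z)$area, pi * (15 * z / 60)^2,
               tolerance = 0.01)
  expect_error(slice_area(cyl, 40.5), "outside")
  # three-quarter shell: open polyline closed by the endpoint chord
  shell <- fixture_cylinder(r = 10, h = 40, n = 256, sector_deg = 270,
                            caps = FALSE)
  sh <- slice_area(shell, 20)
  expect_true(any(sh$open))
  th <- seq(0, 1.5 * pi, length.out = 512)
  oracle <- abs(pactr:::shoelace_area(cbind(10 * cos(th), 10 * sin(th))))
  expect_equal(sh$area, oracle, tolerance = 0.01)
  expect_lt(sh$area, pi * 100)
})

test_that("caliper extents read the frame axes", {
  box <- trimesh(as.matrix(expand.grid(c(0, 30), c(0, 40), c(0, 80))),
                 fixture_cube()$faces)
  expect_equal(measure_extent(box, "x"), 30)
  expect_equal(measure_extent(box, "y"), 40)
  ell <- fixture_cylinder(r = 1, h = 10, n = 256)
  ev <- ell$vertices
  ev[, 1] <- ev[, 1] * 25
  ev[, 2] <- ev[, 2] * 15
  ell <- trimesh(ev, ell$faces)
  expect_equal(measure_extent(ell, "x"), 50, tolerance = 0.01)
  expect_equal(measure_extent(ell, "y"), 30, tolerance = 0.01)
  # extents are frame-dependent: a 45-degree z-rotation changes them
  rot <- trimesh(ell$vertices %*% t(rot_z(pi / 4)), ell$faces)
  expect_gt(measure_extent(rot, "x"), 31)
})
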