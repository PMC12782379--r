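#' Triangle mesh objects
#'
#' A `trimesh` is the package's mesh container: an `n x 3` numeric matrix of
#' vertex coordinates in millimetres and an `m x 3` integer matrix of
#' one-based triangle vertex indices. All limb and socket geometry flows
#' through this type.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle (vertex indices).
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    stop("vertices and faces must have 3 columns", call. = FALSE)
  }
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinate", call. = FALSE)
  if (nrow(vertices) < 4L || nrow(faces) < 4L) {
    stop("a non-degenerate mesh needs at least 4 vertices and 4 faces", call. = FALSE)
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face index out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  ext <- apply(x$vertices, 2, range)
  cat(sprintf("trimesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Point clouds sampled from a surface
#'
#' @param points numeric matrix of 3D points (mm).
#' @param normals optional matrix of per-point outward unit normals.
#' @return An object of class `pointcloud`.
#' @export
pointcloud <- function(points, normals = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 1L) {
    stop("a point cloud needs at least one 3D point", call. = FALSE)
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("normals must be unit length", call. = FALSE)
  }
  structure(list(points = points, normals = normals), class = "pointcloud")
}

face_matrix <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_normals_areas <- function(mesh) {
  fm <- face_matrix(mesh)
  cr <- cross3(fm$b - fm$a, fm$c - fm$a)
  len <- sqrt(rowSums(cr^2))
  list(normals = cr / pmax(len, .Machine$double.xmin), areas = len / 2)
}

#' Load a triangle mesh from STL, PLY or OBJ
#'
#' Reads ASCII/binary STL, ASCII PLY, or OBJ files and merges exactly
#' duplicated vertices (binary STL stores each triangle's vertices
#' independently). Coordinates are taken to be millimetres unless
#' `from_metres = TRUE`.
#'
#' @param path file path; format inferred from the extension.
#' @param from_metres divide-free convenience flag: multiply coordinates by
#'   1000 when the file is in metres.
#' @return A [trimesh].
#' @export
load_mesh <- function(path, from_metres = FALSE) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop(sprintf("unreadable or empty mesh file: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop(sprintf("unsupported mesh format '%s' for %s", ext, path), call. = FALSE)
  )
  if (from_metres) m$vertices <- m$vertices * 1000
  merge_vertices(trimesh(m$vertices, m$faces))
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80) stop(sprintf("truncated STL file: %s", path), call. = FALSE)
  starts_solid <- identical(rawToChar(header[1:5]), "solid")
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + as.numeric(ntri) * 50
  if (!starts_solid || isTRUE(all.equal(expected, file.size(path)))) {
    if (length(ntri) == 0 || ntri < 1) stop(sprintf("empty STL: %s", path), call. = FALSE)
    buf <- readBin(con, "raw", ntri * 50)
    if (length(buf) < ntri * 50) stop(sprintf("truncated STL: %s", path), call. = FALSE)
    # each record: 12 floats (48 bytes) + uint16 attribute
    m <- matrix(buf, nrow = 50)
    vals <- readBin(as.vector(m[1:48, ]), "numeric", n = ntri * 12, size = 4,
                    endian = "little")
    vals <- matrix(vals, ncol = 12, byrow = TRUE)
    verts <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
                   vals[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    return(list(vertices = verts, faces = faces))
  }
  # ASCII STL
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) < 3) stop(sprintf("no vertices in STL: %s", path), call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(f) as.numeric(f[2:4]))
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3 || txt[1] != "ply") stop(sprintf("not a PLY file: %s", path), call. = FALSE)
  endh <- match("end_header", txt)
  hdr <- txt[seq_len(endh)]
  if (any(grepl("^format binary", hdr))) {
    stop(sprintf("binary PLY is not supported: %s", path), call. = FALSE)
  }
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  body <- txt[(endh + 1):length(txt)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(f) as.numeric(f[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(f) {
    k <- as.integer(f[1])
    if (k != 3L) stop("only triangle faces are supported", call. = FALSE)
    as.integer(f[2:4]) + 1L
  }))
  list(vertices = verts, faces = faces)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) < 3 || length(fl) < 1) stop(sprintf("no geometry in OBJ: %s", path), call. = FALSE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(f) as.numeric(f[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(f) {
    ix <- vapply(f[-1], function(tok) as.integer(strsplit(tok, "/")[[1]][1]), 1L)
    if (length(ix) != 3L) stop("only triangle faces are supported", call. = FALSE)
    ix
  }))
  list(vertices = verts, faces = faces)
}

#' Write a triangle mesh to STL (binary), PLY (ASCII) or OBJ
#'
#' The ASCII PLY writer prints coordinates with 17 significant digits so a
#' write/read round trip reproduces double-precision vertices exactly.
#'
#' @param mesh a [trimesh].
#' @param path output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vl <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    flns <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(hdr, vl, flns), path)
  } else if (ext == "obj") {
    vl <- sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    flns <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(vl, flns), path)
  } else if (ext == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(as.raw(rep(0, 80))), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    nrm <- face_normals_areas(mesh)$normals
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    stop(sprintf("unsupported mesh format '%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Merge exactly coincident vertices
#'
#' @param mesh a [trimesh].
#' @return A [trimesh] with duplicate vertices collapsed and faces re-indexed.
#' @export
merge_vertices <- function(mesh) {
  key <- paste(sprintf("%.17g", mesh$vertices[, 1]),
               sprintf("%.17g", mesh$vertices[, 2]),
               sprintf("%.17g", mesh$vertices[, 3]))
  uid <- match(key, key)
  keep <- sort(unique(uid))
  remap <- match(uid, keep)
  trimesh(mesh$vertices[keep, , drop = FALSE],
          matrix(remap[mesh$faces], ncol = 3))
}

#' Sample points area-uniformly on a mesh surface
#'
#' Draws `n` points with probability proportional to triangle area, uniformly
#' within each triangle, and attaches the face's outward normal to each point.
#' Output is deterministic for a given `(mesh, n, seed)`.
#'
#' @param mesh a [trimesh].
#' @param n number of points (default 10000).
#' @param seed integer RNG seed.
#' @return A [pointcloud] with unit normals.
#' @export
sample_surface <- function(mesh, n = 10000, seed = 1) {
  stopifnot(inherits(mesh, "trimesh"), n >= 1)
  na <- face_normals_areas(mesh)
  if (sum(na$areas) <= 0) stop("cannot sample a zero-area mesh", call. = FALSE)
  with_seed(seed, {
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = na$areas)
    r1 <- runif(n)
    r2 <- runif(n)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]
    r2[flip] <- 1 - r2[flip]
    fm <- face_matrix(mesh)
    pts <- fm$a[fi, , drop = FALSE] +
      r1 * (fm$b[fi, , drop = FALSE] - fm$a[fi, , drop = FALSE]) +
      r2 * (fm$c[fi, , drop = FALSE] - fm$a[fi, , drop = FALSE])
    pointcloud(pts, na$normals[fi, , drop = FALSE])
  })
}

directed_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

#' Test whether every edge is shared by exactly two faces
#'
#' @param mesh a [trimesh].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- directed_edges(mesh$faces)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

boundary_loops <- function(mesh) {
  e <- directed_edges(mesh$faces)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bnd <- e[cnt[key] == 1L, , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  nxt <- setNames(bnd[, 2], as.character(bnd[, 1]))
  if (anyDuplicated(bnd[, 1])) {
    stop("boundary is not a set of simple loops (non-manifold rim)", call. = FALSE)
  }
  loops <- list()
  remaining <- setNames(rep(TRUE, nrow(bnd)), as.character(bnd[, 1]))
  for (start in as.character(bnd[, 1])) {
    if (!remaining[[start]]) next
    loop <- integer(0)
    cur <- start
    repeat {
      if (!isTRUE(remaining[[cur]])) stop("open boundary chain", call. = FALSE)
      remaining[[cur]] <- FALSE
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Cap boundary openings with planar patches
#'
#' Finds every boundary loop (edges used by a single face), adds the loop
#' centroid as a new vertex and fans triangles from it, oriented opposite to
#' the rim so the result is watertight. Already-watertight meshes are
#' returned unchanged.
#'
#' @param mesh a [trimesh].
#' @return A watertight [trimesh].
#' @export
cap_openings <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (loop in loops) {
    centroid <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    nl <- length(loop)
    # rim directed edges run u -> v; cap triangles (v, u, centroid) oppose them
    newf <- cbind(loop[c(2:nl, 1)], loop, rep(ci, nl))
    f <- rbind(f, newf)
  }
  out <- trimesh(v, f)
  if (!is_watertight(out)) stop("capping failed to close the mesh", call. = FALSE)
  out
}

#' Solid volume of a mesh by voxelization
#'
#' The mesh is capped watertight if needed, voxelized at the given pitch, and
#' the volume is the count of voxel centres inside the surface (vertical-ray
#' parity test) times the voxel volume.
#'
#' @param mesh a [trimesh].
#' @param pitch voxel edge length in mm (default 0.5).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, pitch = 0.5) {
  stopifnot(inherits(mesh, "trimesh"), pitch > 0)
  if (!is_watertight(mesh)) mesh <- cap_openings(mesh)
  res <- cpp_voxel_volume(mesh$vertices, mesh$faces, pitch)
  if (res$volume <= 0) stop("voxelization produced no interior voxels", call. = FALSE)
  res$volume
}

#' Planar cross-section of a mesh at height z
#'
#' Intersects the mesh with the plane `z = const`, chains the intersection
#' segments into loops, closes any open polyline with a straight chord
#' between its endpoints, and reports the total enclosed (shoelace) area.
#'
#' @param mesh a [trimesh].
#' @param z slicing height in mm, strictly inside the mesh z-extent.
#' @return An object of class `sectionloops`: list with `z`, `loops` (list of
#'   closed 2D polygons), `open` (logical per loop: was it chord-closed), and
#'   `area` in mm^2.
#' @export
slice_area <- function(mesh, z) {
  zr <- range(mesh$vertices[, 3])
  if (z <= zr[1] || z >= zr[2]) {
    stop(sprintf("slice height %.3f outside mesh z-extent [%.3f, %.3f]",
                 z, zr[1], zr[2]), call. = FALSE)
  }
  vz <- mesh$vertices[, 3]
  # nudge the plane off any vertex so every crossing is a clean edge crossing
  if (any(abs(vz - z) < 1e-9)) z <- z + (zr[2] - zr[1]) * 1e-8
  s <- vz - z
  fs <- matrix(s[mesh$faces], ncol = 3)
  lo <- pmin(fs[, 1], fs[, 2], fs[, 3])
  hi <- pmax(fs[, 1], fs[, 2], fs[, 3])
  crossing <- which(lo < 0 & hi > 0)
  segs <- vector("list", length(crossing))
  v <- mesh$vertices
  for (k in seq_along(crossing)) {
    tri <- mesh$faces[crossing[k], ]
    sv <- s[tri]
    pts <- matrix(0, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (sv[e[1]] * sv[e[2]] < 0) {
        t <- sv[e[1]] / (sv[e[1]] - sv[e[2]])
        p <- v[tri[e[1]], 1:2] + t * (v[tri[e[2]], 1:2] - v[tri[e[1]], 1:2])
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) == 2) segs[[k]] <- pts
  }
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (length(segs) == 0) stop("empty cross-section", call. = FALSE)
  loops <- chain_segments(segs)
  areas <- vapply(loops$loops, shoelace_area, 0)
  structure(list(z = z, loops = loops$loops, open = loops$open,
                 area = sum(abs(areas))),
            class = "sectionloops")
}

# Chain unordered 2D segments into polylines by endpoint matching; returns
# closed polygons (open chains closed by the implicit end-to-start chord).
chain_segments <- function(segs, tol = 1e-6) {
  ends <- do.call(rbind, lapply(segs, function(s) rbind(s[1, ], s[2, ])))
  key <- paste(round(ends[, 1] / tol), round(ends[, 2] / tol))
  n <- length(segs)
  used <- rep(FALSE, n)
  # map endpoint key -> segment ids
  seg_of <- split(rep(seq_len(n), each = 2), key)
  loops <- list()
  open <- logical(0)
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    chain <- list(segs[[i]][1, ], segs[[i]][2, ])
    extend_tail <- function(chain) {
      repeat {
        tail_pt <- chain[[length(chain)]]
        k <- paste(round(tail_pt[1] / tol), round(tail_pt[2] / tol))
        cand <- setdiff(seg_of[[k]] %||% integer(0), which(used))
        if (length(cand) == 0) break
        j <- cand[1]
        used[j] <<- TRUE
        d1 <- sum((segs[[j]][1, ] - tail_pt)^2)
        nxt <- if (d1 < tol^2) segs[[j]][2, ] else segs[[j]][1, ]
        chain[[length(chain) + 1L]] <- nxt
      }
      chain
    }
    chain <- extend_tail(chain)       # grow forward from the tail
    chain <- extend_tail(rev(chain))  # then backward from the head
    poly <- do.call(rbind, chain)
    closed <- sum((poly[1, ] - poly[nrow(poly), ])^2) < tol^2
    if (closed) poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) >= 3) {
      loops[[length(loops) + 1L]] <- poly
      open <- c(open, !closed)
    }
  }
  list(loops = loops, open = open)
}

shoelace_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Maximum caliper extent of a mesh along a frame axis
#'
#' @param mesh a [trimesh] in the anatomical frame.
#' @param axis `"x"` (medio-lateral), `"y"` (anterior-posterior) or `"z"`.
#' @return Extent in mm.
#' @export
measure_extent <- function(mesh, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  i <- match(axis, c("x", "y", "z"))
  diff(range(mesh$vertices[, i]))
}
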