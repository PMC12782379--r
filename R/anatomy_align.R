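#' Anatomical landmark sets
#'
#' The three bony landmarks used to align a residual-limb scan: the medial
#' and lateral humeral epicondyles and the olecranon process. Points are 3D
#' coordinates in mm in the scan's own frame.
#'
#' @param medial_epicondyle,lateral_epicondyle,olecranon numeric length-3.
#' @param side `"left"` or `"right"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(medial_epicondyle, lateral_epicondyle, olecranon,
                         side = c("right", "left")) {
  side <- match.arg(side)
  pts <- rbind(medial_epicondyle, lateral_epicondyle, olecranon)
  if (!all(is.finite(pts)) || ncol(pts) != 3) {
    stop("landmarks must be finite 3D points", call. = FALSE)
  }
  d <- as.matrix(stats::dist(pts))
  if (any(d[upper.tri(d)] <= 5)) {
    stop("landmarks closer than 5 mm; cannot define a stable frame", call. = FALSE)
  }
  u <- pts[2, ] - pts[1, ]
  w <- pts[3, ] - pts[1, ]
  cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  if (sqrt(sum(cr^2)) < 1e-6 * sqrt(sum(u^2)) * sqrt(sum(w^2))) {
    stop("collinear landmarks cannot define a frame", call. = FALSE)
  }
  structure(list(medial_epicondyle = as.numeric(medial_epicondyle),
                 lateral_epicondyle = as.numeric(lateral_epicondyle),
                 olecranon = as.numeric(olecranon), side = side),
            class = "landmark_set")
}

#' Read / write landmark JSON sidecars
#'
#' Sidecar format: a JSON object with named points (`medial_epicondyle`,
#' `lateral_epicondyle`, `olecranon`; each an xyz array in mm) and a `side`
#' tag.
#'
#' @param path JSON file path.
#' @return [landmark_set] (read) or `path` invisibly (write).
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(j$medial_epicondyle, j$lateral_epicondyle, j$olecranon, j$side)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set].
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(unclass(lm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

normalize3 <- function(v) v / sqrt(sum(v^2))

#' Rigid transforms
#'
#' A rotation (3x3, det +1) plus translation (mm): `p' = R p + t`.
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation numeric length-3.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x an `n x 3` matrix, [pointcloud] or [trimesh].
#' @param tf a [rigid_transform].
#' @return Object of the same type as `x`.
#' @export
apply_transform <- function(x, tf) {
  if (inherits(x, "trimesh")) {
    return(trimesh(apply_transform(x$vertices, tf), x$faces))
  }
  if (inherits(x, "pointcloud")) {
    nrm <- if (is.null(x$normals)) NULL else x$normals %*% t(tf$rotation)
    return(pointcloud(apply_transform(x$points, tf), nrm))
  }
  sweep(x %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Compose two rigid transforms (`b` after `a`)
#'
#' @param a,b [rigid_transform] objects.
#' @return The [rigid_transform] equivalent to applying `a` then `b`.
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

# Frame axes from the landmark set. x: medio-lateral (positive toward
# lateral), y: anterior-posterior (olecranon posterior, negative y),
# z: distal -> proximal, right-handed for right limbs. For left limbs the
# x axis is reversed so z still points proximally; the subsequent sagittal
# mirror brings the limb into the canonical right-side frame.
frame_axes <- function(lm) {
  origin <- (lm$medial_epicondyle + lm$lateral_epicondyle) / 2
  u <- lm$lateral_epicondyle - lm$medial_epicondyle
  if (lm$side == "left") u <- -u
  xax <- normalize3(u)
  w <- lm$olecranon - origin
  y0 <- w - sum(w * xax) * xax
  if (sqrt(sum(y0^2)) < 1e-9) stop("collinear landmarks", call. = FALSE)
  yax <- -normalize3(y0)
  zax <- c(xax[2] * yax[3] - xax[3] * yax[2],
           xax[3] * yax[1] - xax[1] * yax[3],
           xax[1] * yax[2] - xax[2] * yax[1])
  list(origin = origin, x = xax, y = yax, z = zax)
}

#' Align a limb mesh to the anatomical coordinate frame
#'
#' Places the mesh so the origin is the epicondyle midpoint, x runs
#' medio-laterally (positive lateral), y antero-posteriorly (olecranon on the
#' negative, posterior side) and z along the longitudinal axis increasing
#' distal to proximal. Left limbs are mirrored about the sagittal (x = 0)
#' plane into the canonical right-side frame, with face winding flipped to
#' keep normals outward.
#'
#' @param mesh a [trimesh].
#' @param landmarks a [landmark_set].
#' @return List with `mesh` (aligned), `transform` (the [rigid_transform]
#'   applied before any mirroring), `mirrored` (logical), `landmarks`
#'   (re-expressed in the new frame, side `"right"`), and `frame` (the
#'   canonical frame axes).
#' @export
align_limb <- function(mesh, landmarks) {
  stopifnot(inherits(mesh, "trimesh"), inherits(landmarks, "landmark_set"))
  ax <- frame_axes(landmarks)
  rot <- rbind(ax$x, ax$y, ax$z)
  dimnames(rot) <- NULL
  tf <- rigid_transform(rot, as.numeric(-rot %*% ax$origin))
  v <- apply_transform(mesh$vertices, tf)
  f <- mesh$faces
  lm_pts <- lapply(landmarks[1:3], function(p) as.numeric(apply_transform(rbind(p), tf)))
  mirrored <- landmarks$side == "left"
  if (mirrored) {
    v[, 1] <- -v[, 1]
    f <- f[, c(1, 3, 2)]  # restore outward orientation after reflection
    lm_pts <- lapply(lm_pts, function(p) c(-p[1], p[2], p[3]))
    # reflection swaps the anatomical roles of the epicondyles
    lm_pts <- list(medial_epicondyle = lm_pts$lateral_epicondyle,
                   lateral_epicondyle = lm_pts$medial_epicondyle,
                   olecranon = lm_pts$olecranon)
  }
  out_lm <- landmark_set(lm_pts$medial_epicondyle, lm_pts$lateral_epicondyle,
                         lm_pts$olecranon, side = "right")
  list(mesh = trimesh(v, f), transform = tf, mirrored = mirrored,
       landmarks = out_lm,
       frame = list(origin = c(0, 0, 0), x = c(1, 0, 0), y = c(0, 1, 0),
                    z = c(0, 0, 1)))
}

# Minimal rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- normalize3(p - sum(p * a) * a)
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)
}

#' Register a socket mesh into the limb's anatomical frame
#'
#' Mimics the manual socket registration convention: the longitudinal axis is
#' the socket's principal axis through its centroid and distal tip; the
#' transverse plane (z = 0) is placed at the deepest indent of the proximal
#' trimline (where the epicondyles rest); the sagittal plane is rotated to
#' pass through the olecranon tip or the olecranon obturator centre, on the
#' posterior (negative y) side.
#'
#' @param socket a [trimesh].
#' @param trimline_indent 3D point on the deepest proximal trimline indent.
#' @param obturator_ref 3D point on the olecranon obturator centre or
#'   olecranon tip.
#' @return The registered [trimesh].
#' @export
register_socket_to_limb <- function(socket, trimline_indent, obturator_ref) {
  stopifnot(inherits(socket, "trimesh"))
  for (p in list(trimline_indent, obturator_ref)) {
    d <- min(cpp_nearest(rbind(as.numeric(p)), socket$vertices)$dist)
    if (d > 5) {
      stop(sprintf("registration reference point is %.1f mm from the socket surface", d),
           call. = FALSE)
    }
  }
  v <- socket$vertices
  centroid <- colMeans(v)
  cv <- sweep(v, 2, centroid)
  pca <- eigen(crossprod(cv) / nrow(cv), symmetric = TRUE)
  axis <- pca$vectors[, 1]
  # +z must point proximally, i.e. toward the trimline indent
  if (sum(axis * (as.numeric(trimline_indent) - centroid)) < 0) axis <- -axis
  r1 <- rotation_between(axis, c(0, 0, 1))
  v1 <- cv %*% t(r1)
  ob <- as.numeric(r1 %*% (as.numeric(obturator_ref) - centroid))
  phi <- atan2(ob[2], ob[1])
  r2 <- rotation_about_z(-pi / 2 - phi)
  v2 <- v1 %*% t(r2)
  indent <- as.numeric(r2 %*% (r1 %*% (as.numeric(trimline_indent) - centroid)))
  v2[, 3] <- v2[, 3] - indent[3]
  trimesh(v2, socket$faces)
}

as_points <- function(x) {
  if (inherits(x, "pointcloud")) x$points else as.matrix(x)
}

# Optimal rigid map (rotation + translation) taking p onto q, least squares.
kabsch <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  h <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(rot, cq - as.numeric(rot %*% cp))
}

#' Iterative closest point rigid registration
#'
#' Centroid pre-alignment followed by point-to-point ICP: at each iteration,
#' nearest neighbours of the moving source in the fixed target define
#' correspondences, and the optimal rigid map is found in closed form. The
#' mean squared nearest-neighbour distance is non-increasing across
#' iterations; the loop stops when its relative change drops below `tol`.
#'
#' @param source,target [pointcloud]s or point matrices (>= 3 points).
#' @param max_iter iteration cap (default 100).
#' @param tol relative residual change stopping threshold (default 1e-6).
#' @return List with `transform` (cumulative [rigid_transform] source ->
#'   target), `aligned` (transformed source points), `residual` (final root
#'   mean squared nearest-neighbour distance, mm) and `trace` (per-iteration
#'   residuals).
#' @export
icp_register <- function(source, target, max_iter = 100, tol = 1e-6) {
  p <- as_points(source)
  q <- as_points(target)
  if (nrow(p) < 3 || nrow(q) < 3) stop("ICP needs at least 3 points", call. = FALSE)
  sv <- svd(sweep(p, 2, colMeans(p)))$d
  if (sv[2] < 1e-9 * sv[1]) stop("degenerate (collinear) source cloud", call. = FALSE)
  tf <- rigid_transform(diag(3), colMeans(q) - colMeans(p))
  cur <- apply_transform(p, tf)
  prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    nn <- cpp_nearest(cur, q)
    res <- sqrt(mean(nn$dist^2))
    trace <- c(trace, res)
    if (is.finite(prev) && abs(prev - res) <= tol * max(prev, .Machine$double.eps)) break
    prev <- res
    step <- kabsch(cur, q[nn$index, , drop = FALSE])
    tf <- compose_transform(step, tf)
    cur <- apply_transform(p, tf)
  }
  list(transform = tf, aligned = cur, residual = trace[length(trace)],
       trace = trace)
}
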