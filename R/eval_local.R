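#' Signed surface distances from a predicted socket to its reference
#'
#' Samples both sockets; for each sampled point on the predicted socket the
#' nearest reference sample gives the unsigned distance, and the sign comes
#' from the reference point's outward normal: positive when the predicted
#' point lies outside the reference surface (predicted socket larger),
#' negative when inside (smaller).
#'
#' @param pred,ref co-registered socket [trimesh]s.
#' @param n sample size per mesh.
#' @param seed RNG seed.
#' @return An object of class `signed_distance_field`: `points` (on pred),
#'   `signed` (mm).
#' @export
signed_distances <- function(pred, ref, n = 10000, seed = 1) {
  pc <- sample_surface(pred, n, seed)
  rc <- sample_surface(ref, n, seed)
  nn <- cpp_nearest(pc$points, rc$points)
  q <- rc$points[nn$index, , drop = FALSE]
  nrm <- rc$normals[nn$index, , drop = FALSE]
  side <- sign(rowSums((pc$points - q) * nrm))
  side[side == 0] <- 1
  structure(list(points = pc$points, signed = side * nn$dist),
            class = "signed_distance_field")
}

#' Flag pronounced deviations by mean-split thresholds
#'
#' Positive and negative signed distances are split into two groups; the
#' mean of each group is its threshold, and points beyond their group's
#' threshold (strictly greater positive, strictly smaller negative) are
#' flagged as pronounced. An empty sign group has an undefined (`NA`)
#' threshold and contributes no flags.
#'
#' @param field a [signed_distances()] result.
#' @return List with `flagged` (logical per point), `threshold_pos`,
#'   `threshold_neg` (mm).
#' @export
pronounced_mask <- function(field) {
  s <- field$signed
  if (length(s) == 0) stop("empty signed-distance field", call. = FALSE)
  pos <- s[s > 0]
  neg <- s[s < 0]
  thr_pos <- if (length(pos)) mean(pos) else NA_real_
  thr_neg <- if (length(neg)) mean(neg) else NA_real_
  flagged <- (!is.na(thr_pos) & s > thr_pos) | (!is.na(thr_neg) & s < thr_neg)
  list(flagged = flagged, threshold_pos = thr_pos, threshold_neg = thr_neg)
}

# Standard DBSCAN over 3D points: core points have >= min_pts neighbours
# (self included) within eps; clusters grow from cores; non-core,
# non-reachable points are noise (label 0).
dbscan_cluster <- function(points, eps, min_pts) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  nb <- cpp_radius_neighbors(points, eps)
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Cluster pronounced deviation points into regions
#'
#' Runs DBSCAN separately on inflation (positive) and deflation (negative)
#' flagged points, so each region carries one sign. Noise points are
#' discarded.
#'
#' @param points flagged sample points (matrix).
#' @param signed their signed distances (mm).
#' @param eps DBSCAN radius, mm.
#' @param min_samples DBSCAN core-point threshold.
#' @param participant optional participant id carried on each region.
#' @return List of `deviation_region` objects: `points`, `centroid`, `sign`
#'   (`"inflation"`/`"deflation"`), `size`, `participant`.
#' @export
cluster_deviations <- function(points, signed, eps, min_samples = 20,
                               participant = NA_character_) {
  stopifnot(eps > 0, min_samples >= 1)
  points <- as.matrix(points)
  regions <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) signed > 0 else signed < 0
    if (!any(sel)) next
    pts <- points[sel, , drop = FALSE]
    labels <- dbscan_cluster(pts, eps, min_samples)
    for (cl in setdiff(unique(labels), 0L)) {
      member <- pts[labels == cl, , drop = FALSE]
      regions[[length(regions) + 1L]] <- structure(
        list(points = member, centroid = colMeans(member),
             sign = if (sgn > 0) "inflation" else "deflation",
             size = nrow(member), participant = participant),
        class = "deviation_region")
    }
  }
  regions
}

#' Total surface area of a mesh
#'
#' @param mesh a [trimesh].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_normals_areas(mesh)$areas)

#' Localized deviation analysis for one socket pair
#'
#' Signed distances, mean-split pronounced-deviation flagging, and DBSCAN
#' clustering with the radius set to `dbscan_eps_mult` times the mean surface
#' sample spacing `sqrt(area / n)`, so cluster recovery is invariant to both
#' socket size and sampling density.
#'
#' @param pred,ref co-registered socket [trimesh]s.
#' @param config a [pact_config()].
#' @param seed RNG seed.
#' @param participant id tag for the regions.
#' @return List with `field`, `mask`, `regions` and `eps` (mm).
#' @export
evaluate_local <- function(pred, ref, config = pact_config(), seed = 1,
                           participant = NA_character_) {
  field <- signed_distances(pred, ref, n = config$sample_n, seed = seed)
  mask <- pronounced_mask(field)
  eps <- config$dbscan_eps_mult * sqrt(mesh_area(pred) / config$sample_n)
  regions <- cluster_deviations(field$points[mask$flagged, , drop = FALSE],
                                field$signed[mask$flagged], eps,
                                config$dbscan_min_samples, participant)
  list(field = field, mask = mask, regions = regions, eps = eps)
}

canonical_region_directions <- function() {
  # advisory labels by nearest canonical direction (anatomical frame)
  rbind(
    anterior_distal_trimline = c(-0.05, 0.97, 0.25),
    ap_compression = c(-0.09, -0.53, -0.84),
    distal_tip = c(0, 0, -1),
    supracondylar_compression = c(0, -0.60, 0.80)
  )
}

#' Aggregate per-participant deviation regions into common regions
#'
#' Region centroids are normalized to unit direction vectors from each
#' participant's anatomical origin (abstracting socket scale and radial
#' distance while preserving angular position), pooled across participants,
#' and re-clustered with DBSCAN per sign, using chord distance between unit
#' vectors. Each pooled cluster is summarized by its incidence (number of
#' distinct contributing participants) and the average unit direction vector
#' (mean of member unit vectors, renormalized) with the per-axis standard
#' deviation of the member unit vectors. An advisory anatomical label is
#' attached by nearest canonical direction.
#'
#' @param regions list of `deviation_region`s (all participants pooled).
#' @param eps_norm DBSCAN radius: chord distance between unit direction
#'   vectors (0.25 is about 14 degrees).
#' @param min_samples DBSCAN core threshold at the pooled level.
#' @param origins optional named list/matrix of per-participant anatomical
#'   origins; defaults to the frame origin (0, 0, 0) that aligned meshes
#'   share.
#' @return List of `common_region` objects: `direction` (unit vector),
#'   `direction_sd` (per axis), `incidence`, `participants`, `sign`,
#'   `label`, `members` (member unit vectors).
#' @export
aggregate_regions <- function(regions, eps_norm = 0.25, min_samples = 2,
                              origins = NULL) {
  if (length(regions) == 0) return(list())
  part <- vapply(regions, function(r) r$participant, "")
  if (any(is.na(part) | part == "")) {
    stop("every region must be tagged with a participant id", call. = FALSE)
  }
  cent <- t(vapply(regions, function(r) r$centroid, numeric(3)))
  if (!is.null(origins)) {
    org <- do.call(rbind, lapply(part, function(id) as.numeric(origins[[id]])))
    cent <- cent - org
  }
  units <- t(apply(cent, 1, normalize3))
  signs <- vapply(regions, function(r) r$sign, "")
  out <- list()
  for (sgn in unique(signs)) {
    sel <- which(signs == sgn)
    labels <- dbscan_cluster(units[sel, , drop = FALSE], eps_norm, min_samples)
    for (cl in setdiff(unique(labels), 0L)) {
      idx <- sel[labels == cl]
      u <- units[idx, , drop = FALSE]
      avg <- normalize3(colMeans(u))
      sds <- apply(u, 2, function(x) if (length(x) > 1) sd(x) else 0)
      canon <- canonical_region_directions()
      lab <- rownames(canon)[which.max(canon %*% avg)]
      out[[length(out) + 1L]] <- structure(
        list(direction = avg, direction_sd = sds,
             incidence = length(unique(part[idx])),
             participants = sort(unique(part[idx])), sign = sgn, label = lab,
             members = u),
        class = "common_region")
    }
  }
  out
}

#' Format a common region's direction like a unit-vector table row
#'
#' @param region a `common_region`.
#' @return Character, e.g. `"-0.05 (0.22) x + 0.97 (0.14) y + 0.25 (0.29) z"`.
#' @export
format_unit_vector <- function(region) {
  comp <- sprintf("%+.2f (%.2f)", region$direction, region$direction_sd)
  paste(paste(comp, c("x", "y", "z")), collapse = " ")
}

#' Export a per-vertex colored deviation map as ASCII PLY
#'
#' Colors follow the usual convention: red where the predicted socket is
#' larger than the reference, blue where smaller, white near zero.
#'
#' @param field a [signed_distances()] result.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_deviation_colormap <- function(field, path) {
  s <- field$signed
  m <- max(abs(s), 1e-9)
  t_ <- pmax(pmin(s / m, 1), -1)
  r <- round(255 * ifelse(t_ > 0, 1, 1 + t_))
  b <- round(255 * ifelse(t_ < 0, 1, 1 - t_))
  g <- round(255 * (1 - abs(t_)))
  p <- field$points
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(p)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "element face 0", "property list uchar int vertex_indices",
           "end_header")
  writeLines(c(hdr, sprintf("%.6g %.6g %.6g %d %d %d",
                            p[, 1], p[, 2], p[, 3], r, g, b)), path)
  invisible(path)
}
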