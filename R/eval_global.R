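#' Mean surface deviation after rigid co-registration
#'
#' Samples both sockets, co-registers the predicted cloud to the reference
#' cloud (centroid pre-alignment + point-to-point ICP), then reports the mean
#' nearest-neighbour distance from predicted to reference points.
#'
#' @param pred,ref [trimesh] sockets.
#' @param n surface sample size (default 10000).
#' @param seed RNG seed for sampling.
#' @param config [pact_config()] supplying ICP settings.
#' @return Mean L2 distance in mm.
#' @export
surface_deviation <- function(pred, ref, n = 10000, seed = 1,
                              config = pact_config()) {
  # one seed for both clouds: corresponding surface regions get corresponding
  # samples, so identical sockets measure exactly zero deviation
  pc <- sample_surface(pred, n, seed)$points
  rc <- sample_surface(ref, n, seed)$points
  reg <- icp_register(pc, rc, max_iter = config$icp_max_iter,
                      tol = config$icp_tol)
  mean(cpp_nearest(reg$aligned, rc)$dist)
}

#' Signed and absolute volume difference between two sockets
#'
#' Volumes are estimated by capping and voxelizing both meshes. The
#' magnitude is `100 * |V_ref - V_pred| / V_ref`; the sign is reported so
#' that negative means the predicted socket is smaller than the reference:
#' `signed = 100 * (V_pred - V_ref) / V_ref`.
#'
#' @param ref reference (prosthetist-fabricated) socket [trimesh].
#' @param pred predicted socket [trimesh].
#' @param pitch voxel pitch in mm.
#' @return List with `signed` and `abs` (both %), plus the raw volumes
#'   `v_ref` and `v_pred` in mm^3.
#' @export
volume_difference <- function(ref, pred, pitch = 0.5) {
  v_ref <- mesh_volume(ref, pitch)
  v_pred <- mesh_volume(pred, pitch)
  signed <- 100 * (v_pred - v_ref) / v_ref
  list(signed = signed, abs = abs(signed), v_ref = v_ref, v_pred = v_pred)
}

#' Cross-sectional-area difference profile over 100 stations
#'
#' Slices both sockets perpendicular to the longitudinal axis at equally
#' spaced fractional stations of each mesh's own z-extent, from the distal
#' tip (station ~0%) to the top of the proximal trimline (100%), and reports
#' the percentage area difference `100 * (A_pred - A_ref) / A_ref` per
#' station. Stations where the reference area is below `min_area` are
#' flagged unstable (`NA` delta) since a vanishing denominator inflates the
#' percentage.
#'
#' @param pred,ref socket [trimesh]s registered in one frame.
#' @param stations number of stations (default 100).
#' @param min_area stability threshold on the reference area, mm^2.
#' @return data.frame with columns `station_pct`, `area_pred_mm2`,
#'   `area_ref_mm2`, `delta_pct`, `stable`.
#' @export
csa_profile <- function(pred, ref, stations = 100, min_area = 1) {
  frac <- (seq_len(stations) - 0.5) / stations
  zr_p <- range(pred$vertices[, 3])
  zr_r <- range(ref$vertices[, 3])
  area_at <- function(mesh, zr, f) {
    z <- zr[1] + f * diff(zr)
    tryCatch(slice_area(mesh, z)$area, error = function(e) NA_real_)
  }
  a_pred <- vapply(frac, function(f) area_at(pred, zr_p, f), 0)
  a_ref <- vapply(frac, function(f) area_at(ref, zr_r, f), 0)
  stable <- !is.na(a_ref) & a_ref >= min_area & !is.na(a_pred)
  delta <- ifelse(stable, 100 * (a_pred - a_ref) / a_ref, NA_real_)
  data.frame(station_pct = 100 * frac, area_pred_mm2 = a_pred,
             area_ref_mm2 = a_ref, delta_pct = delta, stable = stable)
}

#' Classify socket fit from the absolute volume difference
#'
#' Clinical volume-fit bands: up to 5% absolute volume difference is a
#' "good" fit, 5-10% "acceptable", beyond that the socket should be
#' replaced. Boundary values fall in the better class.
#'
#' @param v_diff_abs absolute volume difference, % (>= 0).
#' @param bands band edges, % (defaults 5 and 10).
#' @return `"good"`, `"acceptable"` or `"replace"`.
#' @export
classify_fit <- function(v_diff_abs, bands = c(good = 5, acceptable = 10)) {
  if (!is.finite(v_diff_abs) || v_diff_abs < 0) {
    stop("absolute volume difference must be non-negative", call. = FALSE)
  }
  if (v_diff_abs <= bands[[1]]) "good"
  else if (v_diff_abs <= bands[[2]]) "acceptable"
  else "replace"
}

#' Full global comparison of a predicted socket against a reference
#'
#' @param pred,ref socket [trimesh]s in one frame.
#' @param config a [pact_config()].
#' @param seed RNG seed for sampling.
#' @return An object of class `global_metrics`: `mean_l2` (mm),
#'   `v_diff_signed`, `v_diff_abs` (%), `fit_class`, and `csa`
#'   (the station profile data.frame).
#' @export
evaluate_global <- function(pred, ref, config = pact_config(), seed = 1) {
  l2 <- surface_deviation(pred, ref, n = config$sample_n, seed = seed,
                          config = config)
  vd <- volume_difference(ref, pred, pitch = config$pitch)
  csa <- csa_profile(pred, ref, stations = config$slice_stations)
  structure(list(mean_l2 = l2, v_diff_signed = vd$signed, v_diff_abs = vd$abs,
                 v_ref = vd$v_ref, v_pred = vd$v_pred,
                 fit_class = classify_fit(vd$abs, config$fit_bands), csa = csa),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("global metrics: mean L2 %.2f mm; volume diff %+.2f%% (%s fit)\n",
              x$mean_l2, x$v_diff_signed, x$fit_class))
  st <- x$csa$delta_pct[x$csa$stable]
  cat(sprintf("  CSA delta over %d stable stations: mean %+.2f%%, range [%+.1f%%, %+.1f%%]\n",
              sum(x$csa$stable), mean(st), min(st), max(st)))
  invisible(x)
}
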