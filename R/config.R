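#' Run configuration
#'
#' Collects every tunable of the pipeline in one place. Defaults: surface
#' sampling density 10000 points, voxel pitch 0.5 mm, point-to-point ICP with
#' at most 100 iterations and relative tolerance 1e-6, DBSCAN radius 3x the
#' mean surface sample spacing with a 10-point minimum at the participant
#' level (the radius tracks sampling density so cluster recovery does not
#' depend on `sample_n`), pooled-level DBSCAN radius 0.25 in unit-direction
#' (chord) space with a 2-region minimum, 100 slice stations, and
#' good/acceptable fit band edges at 5% and 10% absolute volume difference.
#'
#' @param ... overrides of the named defaults.
#' @return A list of class `pact_config`.
#' @export
pact_config <- function(...) {
  cfg <- list(
    sample_n = 10000L,        # surface sample size per mesh
    seed = 1L,                # base RNG seed for sampling
    pitch = 0.5,              # voxel edge, mm
    icp_max_iter = 100L,
    icp_tol = 1e-6,
    dbscan_eps_mult = 3,      # participant-level eps in multiples of the mean sample spacing
    dbscan_min_samples = 10L,
    dbscan_eps_norm = 0.25,   # pooled-level eps: chord distance between unit direction vectors
    dbscan_min_pooled = 2L,
    slice_stations = 100L,
    fit_bands = c(good = 5, acceptable = 10),  # % absolute volume difference
    symmetric_distance = FALSE,  # symmetrize the retrieval distance
    mirror_left = TRUE           # mirror left limbs into the right-side frame
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  num <- c("sample_n", "pitch", "icp_max_iter", "icp_tol", "dbscan_eps_mult",
           "dbscan_min_samples", "dbscan_eps_norm", "dbscan_min_pooled",
           "slice_stations")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0)) {
      stop(sprintf("config field %s must be positive", f), call. = FALSE)
    }
  }
  if (cfg$slice_stations < 2) stop("slice_stations must be >= 2", call. = FALSE)
  structure(cfg, class = "pact_config")
}
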