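#' Leave-one-out evaluation of socket prediction over a library
#'
#' For every participant, temporarily excludes their prosthetist/reference
#' socket from the library, predicts a socket for their limb from the
#' remaining entries, and compares the prediction against the held-out
#' reference socket with the full global (surface deviation, volume, CSA
#' profile) and local (signed-distance regions) evaluation suite. Regions are
#' pooled across participants into common deviation regions.
#'
#' @param lib a [socket_library] with at least 2 entries.
#' @param config a [pact_config()].
#' @param seed base RNG seed for all sampling.
#' @return An object of class `loo_result`:
#'   * `results`: per-participant data.frame (matched id, scaling factors,
#'     retrieval distance, mean L2, signed/absolute volume difference, fit
#'     class);
#'   * `csa`: per-station data.frame of the cohort mean and SD CSA
#'     difference profile;
#'   * `regions`: all per-participant deviation regions;
#'   * `common_regions`: pooled [aggregate_regions()] output;
#'   * `incidence`: advisory region label by participant count;
#'   * `failed`: ids whose prediction or evaluation failed (with messages).
#' @export
run_loo <- function(lib, config = pact_config(), seed = 1) {
  stopifnot(inherits(lib, "socket_library"))
  ids <- names(lib$entries)
  if (length(ids) < 2) stop("leave-one-out needs at least 2 entries", call. = FALSE)
  rows <- list()
  profiles <- list()
  regions <- list()
  failed <- list()
  for (id in ids) {
    res <- tryCatch({
      entry <- lib$entries[[id]]
      sub <- leave_one_out(lib, id)
      pred <- predict_socket(entry$limb, lib = sub, config = config,
                             aligned = TRUE)
      glob <- evaluate_global(pred$socket, entry$socket, config = config,
                              seed = seed)
      loc <- evaluate_local(pred$socket, entry$socket, config = config,
                            seed = seed, participant = id)
      list(pred = pred, glob = glob, loc = loc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[id]] <- conditionMessage(res)
      next
    }
    rows[[id]] <- data.frame(
      id = id, matched_id = res$pred$matched_id,
      sf_k = res$pred$factors$sf_k, sf_ml = res$pred$factors$sf_ml,
      sf_ap = res$pred$factors$sf_ap, d_l2 = res$pred$d_l2,
      mean_l2 = res$glob$mean_l2, v_diff_signed = res$glob$v_diff_signed,
      v_diff_abs = res$glob$v_diff_abs, fit_class = res$glob$fit_class)
    profiles[[id]] <- res$glob$csa$delta_pct
    regions <- c(regions, res$loc$regions)
  }
  if (length(rows) == 0) stop("every leave-one-out prediction failed", call. = FALSE)
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  prof <- do.call(cbind, profiles)
  csa <- data.frame(
    station_pct = 100 * (seq_len(nrow(prof)) - 0.5) / nrow(prof),
    mean_delta_pct = apply(prof, 1, mean, na.rm = TRUE),
    sd_delta_pct = apply(prof, 1, sd, na.rm = TRUE),
    n_stable = apply(prof, 1, function(x) sum(!is.na(x))))
  common <- aggregate_regions(regions, eps_norm = config$dbscan_eps_norm,
                              min_samples = config$dbscan_min_pooled)
  incidence <- table(vapply(regions, function(r) {
    canon <- canonical_region_directions()
    u <- normalize3(r$centroid)
    rownames(canon)[which.max(canon %*% u)]
  }, ""))
  structure(list(results = results, csa = csa, regions = regions,
                 common_regions = common, incidence = incidence,
                 failed = failed, config = config, seed = seed),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("leave-one-out over %d participants (%d failed)\n",
              nrow(x$results), length(x$failed)))
  cat(sprintf("  mean L2: %.2f +/- %.2f mm\n", mean(x$results$mean_l2),
              sd(x$results$mean_l2)))
  cat(sprintf("  |volume diff|: %.2f +/- %.2f %%\n", mean(x$results$v_diff_abs),
              sd(x$results$v_diff_abs)))
  cat(sprintf("  fit classes: %s\n",
              paste(names(table(x$results$fit_class)),
                    table(x$results$fit_class), collapse = ", ")))
  invisible(x)
}

#' Cohort summary of a leave-one-out run
#'
#' @param x a `loo_result`.
#' @return List with mean/SD of the surface and volume metrics, the scaling
#'   factor table, and region incidence.
#' @export
summarize_loo <- function(x) {
  stopifnot(inherits(x, "loo_result"))
  r <- x$results
  list(
    n = nrow(r),
    mean_l2 = c(mean = mean(r$mean_l2), sd = sd(r$mean_l2)),
    v_diff_abs = c(mean = mean(r$v_diff_abs), sd = sd(r$v_diff_abs)),
    v_diff_signed = c(mean = mean(r$v_diff_signed), sd = sd(r$v_diff_signed)),
    factors = data.frame(
      factor = c("sf_k", "sf_ml", "sf_ap"),
      mean = c(mean(r$sf_k), mean(r$sf_ml), mean(r$sf_ap)),
      sd = c(sd(r$sf_k), sd(r$sf_ml), sd(r$sf_ap)),
      min = c(min(r$sf_k), min(r$sf_ml), min(r$sf_ap)),
      max = c(max(r$sf_k), max(r$sf_ml), max(r$sf_ap))),
    fit_classes = table(r$fit_class),
    incidence = x$incidence,
    failed = names(x$failed)
  )
}
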