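#' Pipeline configuration
#'
#' Every parameter that the field protocol fixes has its published default:
#' the red-edge/red head threshold 0.3 and the 10 cm row buffer. The rest
#' are implementation choices exposed for tuning.
#'
#' @param ndvi_re_threshold head/leaf separation threshold (default 0.3).
#' @param row_buffer_m half-width of the row buffer in metres (default
#'   0.10).
#' @param min_area_plants,min_area_heads minimum component areas in pixels.
#' @param otsu_bins histogram bins for OTSU (default 256).
#' @param eta_min OTSU separability under which an image counts as
#'   single-class (degenerate).
#' @param alignment_mode `"per_flight"` (median homography over
#'   `n_sample_captures` sampled captures, applied flight-wide; the lens
#'   geometry is stable within a flight) or `"per_capture"`.
#' @param n_sample_captures captures sampled in per-flight mode (default 5).
#' @param max_iter,eps ECC iteration cap and correlation-increment
#'   termination threshold.
#' @param kde_bandwidth KDE bandwidth (`NULL` = Silverman's rule-of-thumb).
#' @param kde_bw_floor bandwidth floor (default 0.02).
#' @param min_clusters_for_kde below this many clusters per plot the KDE is
#'   skipped and all clusters count as single heads.
#' @param seed RNG seed recorded with the outputs.
#' @param out_dir optional directory for the CSV/coverage outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ndvi_re_threshold = 0.3,
                            row_buffer_m = 0.10,
                            min_area_plants = 4L,
                            min_area_heads = 10L,
                            otsu_bins = 256L,
                            eta_min = 0.75,
                            alignment_mode = c("per_flight", "per_capture"),
                            n_sample_captures = 5L,
                            max_iter = 200L,
                            eps = 1e-6,
                            kde_bandwidth = NULL,
                            kde_bw_floor = 0.02,
                            min_clusters_for_kde = 4L,
                            seed = 1L,
                            out_dir = NULL) {
  structure(list(ndvi_re_threshold = ndvi_re_threshold,
                 row_buffer_m = row_buffer_m,
                 min_area_plants = as.integer(min_area_plants),
                 min_area_heads = as.integer(min_area_heads),
                 otsu_bins = as.integer(otsu_bins),
                 eta_min = eta_min,
                 alignment_mode = match.arg(alignment_mode),
                 n_sample_captures = as.integer(n_sample_captures),
                 max_iter = as.integer(max_iter), eps = eps,
                 kde_bandwidth = kde_bandwidth,
                 kde_bw_floor = kde_bw_floor,
                 min_clusters_for_kde = as.integer(min_clusters_for_kde),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Reflectance calibration factors from a flight's panel capture
#' @param flight a `uav_flight`.
#' @return Named vector of per-band factors.
#' @export
flight_panel_factors <- function(flight) {
  vapply(.uavstand_bands, function(b) {
    rad <- dn_to_radiance(flight$panel$dn[[b]], flight$panel$meta[[b]])
    panel_factor(rad, flight$panel$reference)
  }, 0)
}

# calibrate one capture's DN bands into an (unaligned) reflectance stack
calibrate_capture <- function(cap, factors) {
  bands <- lapply(.uavstand_bands, function(b) {
    rad <- dn_to_radiance(cap$dn[[b]], cap$meta[[b]])
    suppressWarnings(radiance_to_reflectance(rad, factors[[b]]))
  })
  names(bands) <- .uavstand_bands
  reflectance_stack(bands, capture_id = cap$capture_id)
}

#' Estimate flight-wide band homographies
#'
#' In per-flight mode, homographies are estimated on `n_sample` captures
#' spread evenly through the flight and combined with the element-wise
#' median; the lens-to-lens geometry is stable within a flight.
#'
#' @param flight a `uav_flight`.
#' @param factors per-band panel factors from [flight_panel_factors()].
#' @param config a [pipeline_config()].
#' @return Named list of [band_homography()]s for the non-green bands.
#' @export
flight_homographies <- function(flight, factors,
                                config = pipeline_config()) {
  n <- length(flight$captures)
  idx <- unique(round(seq(1, n, length.out = min(config$n_sample_captures,
                                                 n))))
  per_band <- lapply(setdiff(.uavstand_bands, "green"), function(b) {
    fits <- lapply(idx, function(i) {
      st <- calibrate_capture(flight$captures[[i]], factors)
      estimate_homography(st$bands$green, st$bands[[b]],
                          max_iter = config$max_iter, eps = config$eps,
                          source_band = b)
    })
    ok <- Filter(function(f) f$converged, fits)
    if (!length(ok)) {
      # nothing converged: keep the single best-correlated fit rather than
      # polluting the median with identity fallbacks
      rho <- vapply(fits, `[[`, 0, "correlation")
      ok <- fits[which.max(rho)]
    }
    median_homography(ok)
  })
  names(per_band) <- setdiff(.uavstand_bands, "green")
  per_band
}

#' Run the full pipeline on a flight
#'
#' Calibration, band alignment, reverse calculation of the plot (or row)
#' boundaries into every capture, nadir-capture selection per boundary, and
#' the stage-appropriate detector. Per-plot failures are QC-flagged, not
#' fatal. Reruns with identical inputs and config give identical outputs.
#'
#' @param flight a `uav_flight` (from [generate_flight()] or
#'   [read_flight()]).
#' @param config a [pipeline_config()].
#' @param stage `"plants"` (count per data row, summed per plot) or
#'   `"heads"`; defaults to the flight's own stage.
#' @return List with `counts` (one data.frame row per fully captured
#'   plot), `coverage` (per-plot number of fully containing captures),
#'   `not_captured` (plot ids with no full view), `homographies`,
#'   `panel_factors`, `config`. With `config$out_dir` set, counts and
#'   coverage CSVs are written there.
#' @export
run_pipeline <- function(flight, config = pipeline_config(),
                         stage = NULL) {
  stage <- stage %||% flight$params$stage %||% "plants"
  assert_that(stage %in% c("plants", "heads"), "configuration_error",
              "stage must be 'plants' or 'heads'")
  factors <- flight_panel_factors(flight)
  homs <- flight_homographies(flight, factors, config)

  ## reverse calculation: project every boundary into every capture -------
  boundaries <- if (stage == "heads") {
    flight$layout$plots
  } else {
    lapply(flight$layout$rows, function(r)
      buffer_row(r$line, half_width_m = config$row_buffer_m,
                 plot_id = r$plot_id))
  }
  views <- lapply(boundaries, project_boundary, cameras = flight$cameras,
                  dsm = flight$dsm)
  nadir <- lapply(views, select_nadir)

  ## coverage accounting (per plot over its boundaries) -------------------
  plot_ids <- vapply(boundaries, `[[`, "", "plot_id")
  n_full <- vapply(views, function(vs)
    sum(vapply(vs, `[[`, TRUE, "fully_contained")), 0L)
  cov <- data.frame(plot_id = plot_ids, n_full_views = n_full)
  cov <- stats::aggregate(n_full_views ~ plot_id, cov, min)
  cov$captured <- cov$n_full_views > 0
  not_captured <- cov$plot_id[!cov$captured]

  ## group selected boundaries by capture and process capture-wise --------
  sel <- which(!vapply(nadir, is.null, TRUE))
  caps_needed <- unique(vapply(nadir[sel], `[[`, "", "capture_id"))
  cap_index <- match(caps_needed,
                     vapply(flight$captures, `[[`, "", "capture_id"))
  results <- vector("list", length(nadir))
  for (j in seq_along(caps_needed)) {
    cap <- flight$captures[[cap_index[j]]]
    stack <- align_capture(calibrate_capture(cap, factors), homs)
    for (i in sel[vapply(nadir[sel], `[[`, "", "capture_id") ==
                  caps_needed[j]]) {
      res <- tryCatch({
        img <- extract_plot_image(stack, nadir[[i]])
        if (stage == "plants") {
          pc <- count_plants(img, min_area_px = config$min_area_plants,
                             eta_min = config$eta_min)
          data.frame(plot_id = pc$plot_id, capture_id = pc$capture_id,
                     n_plants = pc$n_plants,
                     qc_flags = paste(pc$qc_flags, collapse = ";"))
        } else {
          hcnt <- count_heads(img,
                              ndvi_re_threshold = config$ndvi_re_threshold,
                              min_area_px = config$min_area_heads,
                              min_clusters_for_kde =
                                config$min_clusters_for_kde,
                              bandwidth = config$kde_bandwidth,
                              bw_floor = config$kde_bw_floor)
          data.frame(plot_id = hcnt$plot_id, capture_id = hcnt$capture_id,
                     n_single = hcnt$n_single, n_double = hcnt$n_double,
                     n_triple = hcnt$n_triple, n_heads = hcnt$n_heads,
                     thresholds = paste(signif(hcnt$thresholds, 6),
                                        collapse = ";"),
                     qc_flags = paste(hcnt$qc_flags, collapse = ";"))
        }
      }, error = function(e) {
        data.frame(plot_id = boundaries[[i]]$plot_id,
                   capture_id = caps_needed[j],
                   qc_flags = paste0("stage_failure:",
                                     conditionMessage(e)))
      })
      results[[i]] <- res
    }
  }
  counts <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(results, function(r) r)))
  if (stage == "plants" && !is.null(counts) && nrow(counts)) {
    # a plot's count is the sum over its data rows
    agg <- stats::aggregate(n_plants ~ plot_id, counts, sum)
    qc <- stats::aggregate(qc_flags ~ plot_id, counts,
                           function(z) paste(z[nzchar(z)], collapse = ";"))
    caps <- stats::aggregate(capture_id ~ plot_id, counts,
                             function(z) paste(unique(z), collapse = ";"))
    counts <- Reduce(function(a, b) merge(a, b, by = "plot_id"),
                     list(agg, caps, qc))
  }
  out <- list(counts = counts, coverage = cov, not_captured = not_captured,
              homographies = homs, panel_factors = factors,
              config = config, stage = stage)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(counts, file.path(config$out_dir,
                                sprintf("counts_%s.csv", stage)),
              row.names = FALSE)
    write.csv(cov, file.path(config$out_dir, "coverage.csv"),
              row.names = FALSE)
    writeLines(c(sprintf("stage: %s", stage),
                 sprintf("plots fully captured: %d / %d",
                         sum(cov$captured), nrow(cov)),
                 sprintf("panel factors: %s",
                         paste(sprintf("%s=%.5g", names(factors), factors),
                               collapse = " "))),
               file.path(config$out_dir, "pipeline_log.txt"))
    write_homographies_csv(homs, file.path(config$out_dir,
                                           "homographies.csv"))
  }
  out
}
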