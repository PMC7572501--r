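#' Process a whole stack through the configured chain
#'
#' Stages run in the canonical order
#' `clahe -> destripe -> unsharp -> segment -> colormap` (a config may
#' select a subset, never a permutation). Every image operation is 2D and
#' per-plane, so plane order and count are preserved and a sub-stack run
#' equals the corresponding sub-range of a full run. A destripe `alpha` of
#' `"auto"` is resolved once per stack by [estimate_stripe_angle()] on up
#' to 16 evenly spaced planes of the stage input. Given the same input and
#' config the result is bit-identical across runs.
#'
#' @param stack an [image_stack()].
#' @param config a `pipeline_config` from [load_config()] or
#'   [pipeline_config()].
#' @param auto_angle_planes cap on the planes sampled for `alpha = "auto"`
#'   (default 16).
#' @return list with `stack` (processed grayscale stack), `report` (run
#'   report: parameter echo, per-plane destripe energies, per-stage wall
#'   seconds, input/output checksums, resolved alpha), and, when the
#'   corresponding stages are configured, `segmentation`
#'   (from [threshold_segment()]) and `rgb` (from [apply_colormap()]).
#' @export
process_stack <- function(stack, config, auto_angle_planes = 16L) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(config, "pipeline_config"))
  bd <- stack$bit_depth
  nz <- dim(stack$planes)[1L]
  report <- list(
    parameters = config$stages,
    input_checksum = digest::digest(stack$planes),
    n_planes = nz,
    timing = list())
  out <- stack
  result <- list()

  for (stage in names(config$stages)) {
    prm <- config$stages[[stage]]
    t0 <- proc.time()[["elapsed"]]
    if (stage == "clahe") {
      cp <- clahe_params(prm$tile_rows, prm$tile_cols, prm$clip_limit,
                         prm$n_bins)
      for (z in seq_len(nz)) {
        lp_log("debug", "clahe", "equalizing", plane = z)
        out$planes[z, , ] <- equalize_clahe(out$planes[z, , ], cp, bd)
      }
    } else if (stage == "destripe") {
      alpha <- prm$alpha
      if (identical(alpha, "auto")) {
        idx <- unique(round(seq(1L, nz,
                                length.out = min(auto_angle_planes, nz))))
        alpha <- as.numeric(estimate_stripe_angle(
          lapply(idx, function(z) out$planes[z, , ])))
        lp_log("info", "destripe",
               sprintf("auto alpha resolved to %.1f deg from %d planes",
                       alpha, length(idx)))
      }
      spec <- pie_filter_spec(alpha_deg = alpha, d1 = prm$d1, d2 = prm$d2,
                              w1 = prm$w1, w2 = prm$w2,
                              edge_sigma = prm$edge_sigma,
                              attenuation = prm$attenuation)
      report$alpha_resolved <- spec$alpha_deg
      e_before <- e_after <- numeric(nz)
      for (z in seq_len(nz)) {
        p <- out$planes[z, , ]
        e_before[z] <- stripe_band_energy(p, spec)
        q <- destripe_plane(p, spec, prm$rescale_mode, bd)
        e_after[z] <- stripe_band_energy(q, spec)
        out$planes[z, , ] <- q
        lp_log("debug", "destripe",
               sprintf("band energy %.3g -> %.3g", e_before[z], e_after[z]),
               plane = z)
      }
      report$per_plane <- data.frame(plane = seq_len(nz),
                                     stripe_energy_before = e_before,
                                     stripe_energy_after = e_after)
    } else if (stage == "unsharp") {
      up <- unsharp_params(prm$sigma, prm$amount, prm$threshold)
      for (z in seq_len(nz))
        out$planes[z, , ] <- unsharp_mask(out$planes[z, , ], up, bd)
    } else if (stage == "segment") {
      if (is.null(prm$scheme))
        stop("segment stage needs a 'scheme' parameter")
      sch <- threshold_scheme(lapply(prm$scheme, as.numeric))
      result$segmentation <- threshold_segment(out, sch)
    } else if (stage == "colormap") {
      dr <- prm$display_range
      if (!identical(dr, "auto")) dr <- as.numeric(dr)
      result$rgb <- apply_colormap(out, prm$map, dr)
    }
    report$timing[[stage]] <- proc.time()[["elapsed"]] - t0
  }

  report$output_checksum <- digest::digest(out$planes)
  result$stack <- out
  result$report <- report
  result
}

#' Serialize a run report as JSON
#' @param report the `report` element of a [process_stack()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", pretty = TRUE)
  invisible(path)
}
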