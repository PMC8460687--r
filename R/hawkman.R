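#' Multi-scale structural-error comparison of two SMLM reconstructions
#'
#' Compares a test super-resolution reconstruction against a reference
#' across a Gaussian scale space.  Both images are first flattened (hot
#' pixels capped at the 98th percentile of the nonzero intensities).  At
#' each integer length scale `s` (a Gaussian blur of FWHM `s`
#' reconstruction pixels) each image is blurred, normalised to maximum 1,
#' and binarised against a Wellner-style adaptive threshold twice: once
#' with the sharpening coefficients (`C_b = 0.7`, `C_a = 0.04`) and once
#' with the structure coefficients (`C_b = 0.85`, `C_a = 0.02`), the latter
#' being skeletonised and re-blurred at the current scale.  Windowed
#' Pearson correlations of the sharpening masks and of the (re-)blurred
#' skeletons are combined into the per-pixel confidence score, and
#' whole-frame correlations summarise each scale.  Finally, the smallest
#' scale at which each pixel reaches 90% confidence gives the artefact
#' scale map.
#'
#' Scales run from one reconstruction pixel up to `max_scale_no`, typically
#' the instrument PSF FWHM in pixels (the smallest separation at which most
#' fitting algorithms localise without bias); raise it for very
#' high-density data.
#'
#' @param test,ref [recon_image]s of identical dimensions and pixel size:
#'   the reconstruction under assessment and the reference (e.g. a
#'   HAWK-preprocessed reconstruction, or a low-density proxy for ground
#'   truth).
#' @param params A [threshold_params]; its `psf_scale_no` sets the
#'   auxiliary threshold window and the default scale range.
#' @param max_scale_no Largest scale number analysed; default
#'   `params$psf_scale_no`.
#' @param confidence_full_threshold Correlation giving full confidence
#'   (default 0.85).
#' @param artefact_threshold Confidence level defining the artefact scale
#'   map (default 0.9).
#' @param keep_maps Keep rendered RGB maps per scale (set `FALSE` to save
#'   memory in batch use; metrics and grids are always kept).
#' @return Object of class `hawkman`: list with `scales` (per-scale
#'   results: masks, structure grids, `s_conf`, local PCCs, global PCCs,
#'   rendered maps), `artefact` (an [artefact_scale_map]), `metrics` (one
#'   row per scale: `scale_no`, `fwhm_nm`, `pcc_sharp`, `pcc_str`,
#'   `mean_conf`), the flattened inputs and the parameters.
#' @examples
#' set.seed(1)
#' img <- recon_image(matrix(runif(32 * 32) > 0.9, 32, 32) * 1.0, 10)
#' res <- run_hawkman(img, img, max_scale_no = 3)
#' summary(res)
#' @export
run_hawkman <- function(test, ref, params = threshold_params(),
                        max_scale_no = params$psf_scale_no,
                        confidence_full_threshold = 0.85,
                        artefact_threshold = 0.9,
                        keep_maps = TRUE) {
  stopifnot(is_recon_image(test), is_recon_image(ref))
  check_same_geometry(test, ref)
  max_scale_no <- as.integer(max_scale_no)
  if (max_scale_no < 1L) stop("'max_scale_no' must be >= 1")

  test_f <- flatten_intensity(test)
  ref_f <- flatten_intensity(ref)
  ps <- test$pixel_size_nm

  scales <- vector("list", max_scale_no)
  conf_stack <- vector("list", max_scale_no)
  metrics <- data.frame(scale_no = integer(), fwhm_nm = double(),
                        pcc_sharp = double(), pcc_str = double(),
                        mean_conf = double())
  combined_last <- NULL

  for (s in seq_len(max_scale_no)) {
    spec <- scale_spec(s, ps, params$psf_scale_no)
    bt <- normalise_max(gaussian_blur_fwhm(test_f, spec))
    br <- normalise_max(gaussian_blur_fwhm(ref_f, spec))

    sharp_test <- binarise(bt, adaptive_threshold(bt, spec, params, "sharpening"))
    sharp_ref  <- binarise(br, adaptive_threshold(br, spec, params, "sharpening"))

    struct_bin_t <- binarise(bt, adaptive_threshold(bt, spec, params, "structure"))
    struct_bin_r <- binarise(br, adaptive_threshold(br, spec, params, "structure"))
    struct_test <- reblur_skeleton(skeletonise(struct_bin_t), spec)
    struct_ref  <- reblur_skeleton(skeletonise(struct_bin_r), spec)

    # the structure grids get one more blur at the current scale before
    # correlation, to become progressively tolerant of sub-scale offsets
    str_cmp_t <- gaussian_blur_fwhm(struct_test, spec)
    str_cmp_r <- gaussian_blur_fwhm(struct_ref, spec)

    lp_sharp <- local_pcc(sharp_test, sharp_ref, s)
    lp_str   <- local_pcc(str_cmp_t, str_cmp_r, s)

    s_conf <- confidence_score(pcc_for_score(lp_sharp), pcc_for_score(lp_str),
                               confidence_full_threshold)

    combined <- bt$pixels + br$pixels
    combined <- combined / max(combined)
    s_conf[combined == 0] <- NA_real_
    conf_stack[[s]] <- s_conf
    combined_last <- combined

    gm <- global_metrics(sharp_test, sharp_ref, struct_test, struct_ref)
    mean_conf <- mean(s_conf, na.rm = TRUE)
    metrics <- rbind(metrics, data.frame(
      scale_no = s, fwhm_nm = spec$fwhm_nm,
      pcc_sharp = gm$pcc_sharp, pcc_str = gm$pcc_str,
      mean_conf = mean_conf))

    scales[[s]] <- list(
      scale = spec,
      sharp_test = sharp_test, sharp_ref = sharp_ref,
      struct_test = struct_test, struct_ref = struct_ref,
      pcc_sharp_local = lp_sharp$pcc, pcc_str_local = lp_str$pcc,
      s_conf = s_conf, combined = combined,
      pcc_sharp_global = gm$pcc_sharp, pcc_str_global = gm$pcc_str,
      maps = if (keep_maps) list(
        sharpening = overlay_map(sharp_test, sharp_ref),
        structure = overlay_map(struct_test, struct_ref),
        confidence = confidence_map(combined, s_conf)) else NULL)
  }

  res <- structure(
    list(scales = scales,
         artefact = artefact_scale_map(conf_stack, combined_last,
                                       artefact_threshold),
         metrics = metrics,
         params = params,
         confidence_full_threshold = confidence_full_threshold,
         test_name = test$name, ref_name = ref$name,
         pixel_size_nm = ps, dim = dim(test$pixels)),
    class = "hawkman")
  res
}

# fold the definedness classification of local_pcc into a score input:
# identical flat windows -> full agreement, empty-vs-empty -> NA (dropped),
# one-sided flatness / flat disagreement -> 0
pcc_for_score <- function(lp) {
  p <- lp$pcc
  p[lp$undefined] <- 0
  p[lp$agree_flat] <- 1
  p[lp$no_evidence] <- NA_real_
  p
}

#' @export
print.hawkman <- function(x, ...) {
  cat(sprintf("<hawkman> '%s' vs '%s': %d x %d px @ %g nm, scales 1..%d\n",
              x$test_name, x$ref_name, x$dim[1], x$dim[2], x$pixel_size_nm,
              nrow(x$metrics)))
  m <- x$metrics
  cat(sprintf("  global PCC sharpening %.3f..%.3f, structure %.3f..%.3f\n",
              min(m$pcc_sharp, na.rm = TRUE), max(m$pcc_sharp, na.rm = TRUE),
              min(m$pcc_str, na.rm = TRUE), max(m$pcc_str, na.rm = TRUE)))
  cat(sprintf("  mean confidence at largest scale: %.3f\n",
              m$mean_conf[nrow(m)]))
  invisible(x)
}

#' @export
summary.hawkman <- function(object, ...) {
  structure(list(metrics = object$metrics,
                 artefact = object$artefact,
                 test_name = object$test_name, ref_name = object$ref_name),
            class = "summary.hawkman")
}

#' @export
print.summary.hawkman <- function(x, ...) {
  cat(sprintf("Multi-scale comparison: '%s' (test) vs '%s' (reference)\n\n",
              x$test_name, x$ref_name))
  df <- x$metrics
  df$pcc_sharp <- round(df$pcc_sharp, 4)
  df$pcc_str <- round(df$pcc_str, 4)
  df$mean_conf <- round(df$mean_conf, 4)
  print(df, row.names = FALSE)
  cat("\n")
  print(x$artefact)
  invisible(x)
}

#' Plot method for hawkman results
#'
#' Displays the sharpening, structure and confidence maps at a chosen scale
#' together with the artefact scale map.
#'
#' @param x A `hawkman` result (run with `keep_maps = TRUE`).
#' @param scale_no Scale to display; default the largest analysed.
#' @param ... Unused.
#' @export
plot.hawkman <- function(x, scale_no = nrow(x$metrics), ...) {
  sc <- x$scales[[scale_no]]
  if (is.null(sc$maps)) stop("maps were not kept; rerun with keep_maps = TRUE")
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(img, title) {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(img) / nrow(img))
    graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
    graphics::title(title)
  }
  show(sc$maps$sharpening, sprintf("sharpening (scale %d)", scale_no))
  show(sc$maps$structure, sprintf("structure (scale %d)", scale_no))
  show(sc$maps$confidence, sprintf("confidence (scale %d)", scale_no))
  show(render_artefact_map(x$artefact), "artefact scale map")
  invisible(x)
}
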