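## Windowed Pearson correlation and the confidence score ---------------------

# smallest-variance floor below which a window is treated as flat
.VAR_TOL <- 1e-13

# odd window side used for the local correlation at a given scale number:
# the largest odd integer <= max(scale_no, 3); a 1-px window has no variance
pcc_window_side <- function(window_px) {
  w <- max(as.integer(window_px), 3L)
  if (w %% 2L == 0L) w - 1L else w
}

#' Windowed Pearson correlation of two images
#'
#' Dense sliding-window Pearson correlation: for each pixel, the textbook
#' correlation of the two images over the centred square window of side
#' equal to the largest odd integer not exceeding `max(window_px, 3)`.  At
#' borders the window is truncated to its in-bounds part.  Windows where
#' either image is flat (zero variance) carry no correlation; they are
#' returned as `NA` in `pcc`, with companion masks identifying how they
#' should be scored (see [confidence_score]).
#'
#' @param a,b Numeric matrices (or logical masks) of identical dimensions.
#' @param window_px Window side request, normally the current scale number.
#' @return List with `pcc` (matrix in `[-1, 1]` with `NA` where undefined),
#'   `undefined` (logical: either window flat), `agree_flat` (logical: both
#'   windows flat at the same nonzero level -- identical content, genuine
#'   agreement), and `no_evidence` (logical: both windows flat at zero,
#'   i.e. nothing in either image to compare).
#' @export
local_pcc <- function(a, b, window_px) {
  if (is.logical(a)) a <- a * 1.0
  if (is.logical(b)) b <- b * 1.0
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  w <- pcc_window_side(window_px)
  nr <- nrow(a); nc <- ncol(a)
  n  <- box_count(nr, nc, w)
  sa <- box_sum(a, w);     sb <- box_sum(b, w)
  saa <- box_sum(a * a, w); sbb <- box_sum(b * b, w)
  sab <- box_sum(a * b, w)
  ma <- sa / n; mb <- sb / n
  va <- saa / n - ma^2
  vb <- sbb / n - mb^2
  va[va < 0] <- 0; vb[vb < 0] <- 0
  cv <- sab / n - ma * mb
  flat_a <- va <= .VAR_TOL
  flat_b <- vb <= .VAR_TOL
  undefined <- flat_a | flat_b
  both_flat_eq <- flat_a & flat_b & abs(ma - mb) <= 1e-9
  # both windows empty: vacuous, no evidence either way
  no_evidence <- both_flat_eq & abs(ma) <= 1e-9
  # both flat at the same nonzero level: the windows are identical
  agree_flat <- both_flat_eq & !no_evidence
  pcc <- matrix(NA_real_, nr, nc)
  ok <- !undefined
  pcc[ok] <- pmax(-1, pmin(1, cv[ok] / sqrt(va[ok] * vb[ok])))
  list(pcc = pcc, undefined = undefined, agree_flat = agree_flat,
       no_evidence = no_evidence)
}

#' Confidence score from sharpening and structure correlations
#'
#' Combines the local sharpening-map and structure-map correlations into a
#' score in `[0, 1]`:
#' `S_conf = 1/2 min(1, PCC_sharp / 0.85) + 1/2 min(1, PCC_str / 0.85)`,
#' with each term clamped below at 0 so the score matches its display range
#' (0 red to 1 cyan).  A correlation of 0.85 in both representations counts
#' as full confidence: the slightly reduced precision typical of a
#' HAWK-style reference and the skeleton re-blurring make a perfect
#' correlation unlikely even for faithful reconstructions.
#'
#' `NA` inputs mark windows where both images were flat at the same level;
#' such terms carry no evidence and are dropped (the score is the mean of
#' the remaining terms, or `NA` if none remain).
#'
#' @param pcc_sharp,pcc_str Correlation values in `[-1, 1]`, vectors or
#'   matrices of the same shape; `NA` for no-evidence windows.
#' @param full_threshold Correlation treated as full confidence (0.85).
#' @return Scores in `[0, 1]` (same shape as the inputs), `NA` where
#'   neither term carries evidence.
#' @export
confidence_score <- function(pcc_sharp, pcc_str, full_threshold = 0.85) {
  term <- function(p) pmax(0, pmin(1, p / full_threshold))
  ts <- term(pcc_sharp)
  tr <- term(pcc_str)
  both <- (ts + tr) / 2
  out <- ifelse(is.na(ts), tr, ifelse(is.na(tr), ts, both))
  if (is.matrix(pcc_sharp)) dim(out) <- dim(pcc_sharp)
  out
}

#' Whole-image Pearson correlations of the per-scale representations
#'
#' The single-number summaries reported per scale: the Pearson correlation
#' between the two binarised sharpening maps (as 0/1 grids) and between the
#' two re-blurred structure grids, each over the full frame (background
#' included).
#'
#' @param sharp_test,sharp_ref Logical sharpening masks.
#' @param struct_test,struct_ref Numeric re-blurred skeleton grids.
#' @return List with `pcc_sharp` and `pcc_str`; `NA` when an image pair has
#'   zero variance (undefined, deliberately not reported as 0).
#' @export
global_metrics <- function(sharp_test, sharp_ref, struct_test, struct_ref) {
  safe_cor <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(pcc_sharp = safe_cor(sharp_test, sharp_ref),
       pcc_str = safe_cor(struct_test, struct_ref))
}

#' Artefact scale map
#'
#' For each pixel, the smallest length scale at which the confidence score
#' reaches the high-confidence level (0.9): the local scale above which the
#' reconstruction can be trusted.  Pixels that never reach it get the
#' sentinel `NA`.
#'
#' @param conf_stack List of per-scale confidence matrices, scales
#'   `1..max_scale_no` in order.
#' @param combined Normalised sum of the two input images (sets the
#'   brightness of the rendered map).
#' @param threshold High-confidence level, default 0.9.
#' @return Object of class `artefact_scale_map`: list with `scale` (integer
#'   matrix, `NA` = never confident), `combined`, `max_scale_no`,
#'   `threshold`.
#' @export
artefact_scale_map <- function(conf_stack, combined, threshold = 0.9) {
  if (!length(conf_stack)) stop("empty confidence stack")
  d <- dim(conf_stack[[1L]])
  sc <- matrix(NA_integer_, d[1], d[2])
  for (s in rev(seq_along(conf_stack))) {
    hit <- !is.na(conf_stack[[s]]) & conf_stack[[s]] >= threshold
    sc[hit] <- s
  }
  structure(list(scale = sc, combined = combined,
                 max_scale_no = length(conf_stack), threshold = threshold),
            class = "artefact_scale_map")
}

#' @export
print.artefact_scale_map <- function(x, ...) {
  n_conf <- sum(!is.na(x$scale))
  cat(sprintf("<artefact_scale_map> %d x %d px, scales 1..%d, threshold %g\n",
              nrow(x$scale), ncol(x$scale), x$max_scale_no, x$threshold))
  cat(sprintf("  %d px reach confidence (median scale %s); %d never do\n",
              n_conf,
              if (n_conf) format(stats::median(x$scale, na.rm = TRUE)) else "-",
              sum(is.na(x$scale))))
  invisible(x)
}
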