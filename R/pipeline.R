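#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the segmentation pipeline. Defaults
#' reproduce the standard recipe: stain separation at `alpha = 1`,
#' `beta = 0.15`; Otsu thresholding of the hematoxylin image; a 3 x 3
#' opening run twice for noise removal; border clearing; sure-foreground at
#' half the maximum distance; components of at least 20 px; level-set
#' refinement with a gentle balloon inflation.
#'
#' @param normalization A [normalization_params()] object.
#' @param se_size,se_iterations Structuring element of the noise-removal
#'   opening.
#' @param fg_fraction Sure-foreground fraction of the distance maximum.
#' @param marker_scope `"component"` (default) thresholds the distance field
#'   per component, `"global"` against the image-wide maximum; see
#'   [extract_markers()].
#' @param min_area Minimum component area (px).
#' @param clear_border_components Remove components touching the frame?
#' @param gac A [gac_params()] object.
#' @param rotations,shifts,scales Augmentation grid: rotation angles
#'   (degrees), a list of `(row, col)` shift fractions, and scale factors.
#' @param train_fraction Training share for [split_counts()].
#' @param seed_method `"peaks"` (default) seeds the contour evolution at
#'   separated local maxima of the distance transform via
#'   [detect_seed_points()]; `"markers"` uses the sure-foreground blobs of
#'   each component via [seed_markers_from_components()].
#' @param use_log_seeds Add LoG blob centers as extra seed candidates (only
#'   with `seed_method = "peaks"`).
#' @param split_merged Partition final objects that absorbed several seeds
#'   by nearest seed (see [split_labels_by_seeds()]).
#' @param verbose Emit per-stage log messages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(normalization = normalization_params(),
                            se_size = 3L, se_iterations = 2L,
                            fg_fraction = 0.7,
                            marker_scope = c("component", "global"),
                            min_area = 20L,
                            clear_border_components = TRUE,
                            gac = gac_params(),
                            rotations = c(0, 90, 180, 270),
                            shifts = list(c(0, 0)),
                            scales = 1,
                            train_fraction = 0.75,
                            seed_method = c("peaks", "markers"),
                            use_log_seeds = TRUE,
                            split_merged = TRUE,
                            verbose = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    config_error("`train_fraction` must be in (0, 1)")
  if (any(scales <= 0)) config_error("scales must be > 0")
  if (fg_fraction <= 0 || fg_fraction >= 1)
    config_error("`fg_fraction` must be in (0, 1)")
  marker_scope <- match.arg(marker_scope)
  structure(list(
    normalization = normalization, se_size = as.integer(se_size),
    se_iterations = as.integer(se_iterations), fg_fraction = fg_fraction,
    marker_scope = marker_scope, min_area = as.integer(min_area),
    clear_border_components = isTRUE(clear_border_components),
    gac = gac, rotations = rotations, shifts = shifts, scales = scales,
    train_fraction = train_fraction, seed_method = match.arg(seed_method),
    use_log_seeds = isTRUE(use_log_seeds),
    split_merged = isTRUE(split_merged),
    verbose = isTRUE(verbose)
  ), class = "pipeline_config")
}

# inverse-mapped affine resampling with reflection padding; exact (weights
# 0/1) for right-angle rotations and integer shifts
warp_image <- function(image, angle_deg = 0, shift = c(0, 0), scale = 1) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  th <- -angle_deg * pi / 180          # inverse rotation
  out_r <- matrix(seq_len(h), h, w)
  out_c <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- out_r - cr - shift[1] * h
  dc <- out_c - cc - shift[2] * w
  src_r <- (cos(th) * dr - sin(th) * dc) / scale + cr
  src_c <- (sin(th) * dr + cos(th) * dc) / scale + cc
  reflect <- function(x, n) {
    # reflect about pixel centers 1..n (period 2n - 2)
    if (n == 1L) return(rep(1, length(x)))
    x <- (x - 1) %% (2 * (n - 1))
    ifelse(x > n - 1, 2 * (n - 1) - x, x) + 1
  }
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  out <- array(0, dim = dim(image))
  for (ch in 1:3) {
    m <- image[, , ch]
    at <- function(ri, ci) {
      ri <- reflect(ri, h); ci <- reflect(ci, w)
      m[cbind(as.vector(round(ri)), as.vector(round(ci)))]
    }
    v <- at(r0, c0) * (1 - fr) * (1 - fc) + at(r0 + 1, c0) * fr * (1 - fc) +
         at(r0, c0 + 1) * (1 - fr) * fc + at(r0 + 1, c0 + 1) * fr * fc
    out[, , ch] <- matrix(v, h, w)
  }
  pmin(pmax(out, 0), 1)
}

#' Deterministic augmentation grid
#'
#' Applies every combination of the configured rotations, shifts and scales
#' about the image center with reflection padding and bilinear resampling
#' (exact for right-angle rotations). The output count is
#' `length(rotations) * length(shifts) * length(scales)` per input image.
#'
#' @param image Numeric H x W x 3 RGB array.
#' @param config A [pipeline_config()] object.
#' @return A list of augmented images, ordered rotation-major, then shift,
#'   then scale.
#' @export
augment <- function(image, config = pipeline_config()) {
  assert_rgb_image(image)
  if (any(config$scales <= 0)) config_error("scales must be > 0")
  out <- list()
  for (rot in config$rotations)
    for (sh in config$shifts)
      for (sc in config$scales)
        out[[length(out) + 1L]] <- warp_image(image, rot, sh, sc)
  out
}

#' Train/test split counts
#'
#' `n_train = floor(n * train_fraction)`, `n_test = n - n_train`; the split
#' always conserves `n`.
#'
#' @param n Total number of images.
#' @param train_fraction Training share in (0, 1).
#' @return A named integer vector `c(n_train, n_test)`.
#' @export
split_counts <- function(n, train_fraction = 0.75) {
  if (n < 0) input_error("`n` must be >= 0")
  if (train_fraction <= 0 || train_fraction >= 1)
    config_error("`train_fraction` must be in (0, 1)")
  n_train <- floor(n * train_fraction)
  c(n_train = as.integer(n_train), n_test = as.integer(n - n_train))
}

stage_log <- function(records, stage, start, summary, verbose) {
  rec <- data.frame(stage = stage,
                    seconds = round(as.numeric(Sys.time()) - start, 3),
                    summary = summary)
  if (verbose) message(sprintf("[%s] %s (%.2fs)", stage, summary, rec$seconds))
  rbind(records, rec)
}

#' Run the full nuclei-segmentation pipeline
#'
#' Stages: stain separation (hematoxylin image) -> grayscale -> Otsu
#' threshold -> opening + border clearing -> distance transform -> marker
#' extraction -> connected components -> seed construction -> geodesic
#' active contours -> contour extraction, optionally followed by evaluation
#' against an instance ground truth. A blank (no-tissue) input returns an
#' empty but well-formed result rather than an error. The pipeline contains
#' no randomness: identical inputs and configuration give bit-identical
#' results.
#'
#' @param image Numeric H x W x 3 RGB array in `[0, 1]`.
#' @param config A [pipeline_config()] object.
#' @param truth Optional integer ground-truth label map for evaluation.
#' @return A list of class `"pipeline_result"` with the per-stage artifacts
#'   (`separation`, `gray`, `mask`, `dist`, `markers`, `components`,
#'   `seeds`, `labels`, `contours`, `u`), `metrics` (when `truth` given) and
#'   a `log` data frame of stage timings.
#' @export
run_pipeline <- function(image, config = pipeline_config(), truth = NULL) {
  assert_rgb_image(image)
  log <- data.frame(stage = character(), seconds = numeric(),
                    summary = character())
  h <- dim(image)[1]; w <- dim(image)[2]
  empty_result <- function(sep) {
    structure(list(
      separation = sep, gray = if (is.null(sep)) NULL else to_gray(sep$h_only),
      mask = matrix(FALSE, h, w), dist = matrix(0, h, w),
      markers = NULL, components = list(),
      seeds = matrix(0L, h, w), labels = matrix(0L, h, w),
      contours = list(), u = NULL,
      metrics = if (is.null(truth)) NULL
                else evaluate_segmentation(matrix(0L, h, w), truth),
      log = log), class = "pipeline_result")
  }

  t0 <- as.numeric(Sys.time())
  sep <- tryCatch(separate_stains(image, config$normalization),
                  nucseg_no_tissue_error = function(e) NULL)
  if (is.null(sep)) return(empty_result(NULL))
  log <- stage_log(log, "normalize", t0,
                   sprintf("max H conc %.2f", sep$max_conc[1]),
                   config$verbose)

  t0 <- as.numeric(Sys.time())
  gray <- to_gray(sep$h_only)
  mask <- binary_threshold(gray, "otsu")
  se <- structuring_element(config$se_size, config$se_iterations)
  mask <- morphology(mask, "open", se)
  if (config$clear_border_components) mask <- clear_borders(mask)
  log <- stage_log(log, "enhance", t0, sprintf("%d fg px", sum(mask)),
                   config$verbose)
  if (!any(mask)) return(empty_result(sep))

  t0 <- as.numeric(Sys.time())
  dist <- distance_transform(mask)
  markers <- extract_markers(mask, dist, config$fg_fraction,
                             scope = config$marker_scope)
  log <- stage_log(log, "markers", t0,
                   sprintf("%d sure-fg px", sum(markers$sure_fg)),
                   config$verbose)

  t0 <- as.numeric(Sys.time())
  labels0 <- label_components(mask, connectivity = 8L)
  comps <- component_masks(labels0, config$min_area, intensity = gray)
  keep <- matrix(FALSE, h, w)
  for (comp in comps) keep <- keep | comp$mask   # drop sub-min_area debris
  seeds <- if (config$seed_method == "peaks") {
    detect_seed_points(keep, dist,
                       gray = if (config$use_log_seeds) gray else NULL)
  } else {
    withCallingHandlers(
      seed_markers_from_components(comps, markers),
      warning = function(wrn) {
        if (!config$verbose) invokeRestart("muffleWarning")
      })
  }
  log <- stage_log(log, "components", t0,
                   sprintf("%d components, %d seeds", length(comps),
                           max(seeds)), config$verbose)
  if (!any(seeds > 0L)) return(empty_result(sep))

  t0 <- as.numeric(Sys.time())
  gac <- run_gac(gray, seeds, config$gac)
  labels <- if (config$split_merged) split_labels_by_seeds(gac$labels, seeds)
            else gac$labels
  log <- stage_log(log, "gac", t0,
                   sprintf("%d objects after %d iters",
                           length(setdiff(unique(as.integer(labels)), 0L)),
                           gac$iterations), config$verbose)

  metrics <- if (is.null(truth)) NULL
             else evaluate_segmentation(labels, truth)
  structure(list(
    separation = sep, gray = gray, mask = mask, dist = dist,
    markers = markers, components = comps, seeds = seeds,
    labels = labels, contours = gac$contours, u = gac$u,
    metrics = metrics, log = log), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  k <- length(setdiff(unique(as.integer(x$labels)), 0L))
  cat(sprintf("pipeline result: %d segmented object(s)\n", k))
  if (!is.null(x$metrics))
    cat(sprintf("  Dice %.3f, IoU %.3f, count error %d, matched Dice %.3f\n",
                x$metrics$dice, x$metrics$iou, x$metrics$count_error,
                x$metrics$matched_dice))
  if (nrow(x$log)) {
    cat("  stages:\n")
    for (i in seq_len(nrow(x$log)))
      cat(sprintf("    %-10s %6.2fs  %s\n", x$log$stage[i], x$log$seconds[i],
                  x$log$summary[i]))
  }
  invisible(x)
}

#' Persist the artifacts of a pipeline run
#'
#' Writes the hematoxylin/eosin renderings, the binary mask, the distance
#' field, the final label map, the contour table (CSV) and the stage log to
#' `dir`.
#'
#' @param result A `"pipeline_result"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$separation)) {
    write_image(result$separation$normalized_he,
                file.path(dir, "normalized_he.png"))
    write_image(result$separation$h_only, file.path(dir, "h_only.png"))
    write_image(result$separation$e_only, file.path(dir, "e_only.png"))
  }
  write_mask(result$mask, file.path(dir, "mask.png"))
  write_field(result$dist, file.path(dir, "distance.tif"))
  write_label_map(result$labels, file.path(dir, "labels.tif"))
  ct <- contour_csv(result$contours)
  utils::write.csv(ct, file.path(dir, "contours.csv"), row.names = FALSE)
  utils::write.csv(result$log, file.path(dir, "stages.csv"),
                   row.names = FALSE)
  invisible(dir)
}

contour_csv <- function(contours) {
  if (!length(contours))
    return(data.frame(contour_id = integer(), vertex_index = integer(),
                      row = numeric(), col = numeric()))
  do.call(rbind, lapply(seq_along(contours), function(i)
    data.frame(contour_id = i,
               vertex_index = seq_len(nrow(contours[[i]])),
               row = contours[[i]][, 1], col = contours[[i]][, 2])))
}
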