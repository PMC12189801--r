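#' Laplacian-of-Gaussian kernel
#'
#' Discrete LoG weights
#' `w(x, y) = ((x^2 + y^2 - 2 sigma^2) / sigma^4) * exp(-(x^2 + y^2) / (2 sigma^2))`
#' on the square `[-radius, radius]^2`. The center weight is `-2 / sigma^2`,
#' the zero crossing lies on the circle `x^2 + y^2 = 2 sigma^2`, and the
#' weights sum to (numerically) zero once the support covers the kernel's
#' tails, which a radius of at least `ceiling(3 sigma)` guarantees to the
#' tolerance used here.
#'
#' @param sigma Kernel width in pixels (`> 0`).
#' @param radius Integer half-size; must be at least `ceiling(3 * sigma)`.
#' @return A list of class `"log_kernel"` with `sigma`, `radius` and the
#'   `(2 radius + 1)^2` weight matrix `weights`.
#' @export
log_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) config_error("`sigma` must be > 0")
  radius <- as.integer(radius)
  if (radius < ceiling(3 * sigma))
    config_error("`radius` must be at least ceiling(3 * sigma)")
  x <- -radius:radius
  r2 <- outer(x^2, x^2, `+`)
  w <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  structure(list(sigma = sigma, radius = radius, weights = w),
            class = "log_kernel")
}

#' Multi-scale LoG blob detection
#'
#' Convolves the image with the LoG kernel at each scale and reports the
#' local extrema over position and scale that exceed `threshold`. The
#' kernel's `1/sigma^4` amplitude makes the responses of [log_kernel()]
#' scale-comparable as they stand (it equals `2 pi sigma^2` times the
#' unit-mass LoG, i.e. the usual `sigma^2` scale normalization up to a
#' constant), and each truncated kernel is recentered to zero mean so a
#' constant background contributes nothing at any scale. Dark blobs on a
#' bright background produce positive responses; `polarity = "bright"`
#' negates the response to detect bright blobs instead.
#'
#' @param gray Numeric matrix.
#' @param sigmas Increasing vector of scales (pixels).
#' @param polarity `"dark"` or `"bright"`.
#' @param threshold Minimum normalized response.
#' @return A data frame with columns `row`, `col`, `sigma`, `response`
#'   (possibly zero rows).
#' @export
detect_blobs <- function(gray, sigmas = c(2, 3, 4, 6),
                         polarity = c("dark", "bright"), threshold = 0.5) {
  assert_gray(gray)
  polarity <- match.arg(polarity)
  if (!length(sigmas) || is.unsorted(sigmas, strictly = TRUE))
    config_error("`sigmas` must be nonempty and strictly increasing")
  sgn <- if (polarity == "dark") 1 else -1
  resp <- lapply(sigmas, function(s) {
    k <- log_kernel(s)
    w <- k$weights - mean(k$weights)      # kill DC of the truncated kernel
    r <- EBImage::filter2(gray, w, boundary = "replicate")
    sgn * matrix(as.numeric(r), nrow(gray), ncol(gray))
  })
  h <- nrow(gray); w <- ncol(gray)
  shift_max <- function(m) {
    # max over the 3 x 3 spatial neighborhood (excluding nothing)
    p <- matrix(-Inf, h + 2L, w + 2L)
    p[2:(h + 1L), 2:(w + 1L)] <- m
    out <- matrix(-Inf, h, w)
    for (dr in -1:1) for (dc in -1:1)
      out <- pmax(out, p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
    out
  }
  nb_max <- lapply(resp, shift_max)
  hits <- list()
  for (i in seq_along(sigmas)) {
    m <- resp[[i]]
    best <- nb_max[[i]]
    if (i > 1L) best <- pmax(best, nb_max[[i - 1L]])
    if (i < length(sigmas)) best <- pmax(best, nb_max[[i + 1L]])
    is_peak <- m >= best & m > threshold
    if (any(is_peak)) {
      idx <- which(is_peak, arr.ind = TRUE)
      hits[[length(hits) + 1L]] <- data.frame(
        row = idx[, 1], col = idx[, 2], sigma = sigmas[i],
        response = m[is_peak])
    }
  }
  if (!length(hits))
    return(data.frame(row = integer(), col = integer(),
                      sigma = numeric(), response = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$row, out$col, out$sigma), , drop = FALSE]
}

#' Label connected foreground components
#'
#' Minimum-label propagation: each foreground pixel starts with its row-major
#' index and repeatedly takes the minimum over its (4- or 8-) neighborhood
#' until the labels stabilize; components are then renumbered 1..K in
#' row-major order of their first pixel, so labeling is deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8, suited to blob-like nuclei).
#' @return An integer matrix; 0 is background, components are 1..K.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L))
    config_error("`connectivity` must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(0L, h, w))
  rm_index <- (matrix(seq_len(h), h, w) - 1) * w +
    matrix(seq_len(w), h, w, byrow = TRUE)
  lab <- ifelse(mask, rm_index, Inf)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  repeat {
    p <- matrix(Inf, h + 2L, w + 2L)
    p[2:(h + 1L), 2:(w + 1L)] <- lab
    nb <- lab
    for (o in offs)
      nb <- pmin(nb, p[(2:(h + 1L)) + o[1], (2:(w + 1L)) + o[2]])
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  roots <- sort(unique(lab[mask]))        # ascending == row-major first pixel
  out <- matrix(0L, h, w)
  out[mask] <- match(lab[mask], roots)
  out
}

#' Per-component masks and shape statistics
#'
#' Splits a label map into one mask per component, dropping components
#' smaller than `min_area` (stain debris). Coordinates are 1-based (row 1 is
#' the top of the image); bounding boxes are half-open
#' `[r0, r1) x [c0, c1)`.
#'
#' @param labels Integer label map from [label_components()].
#' @param min_area Minimum component area in pixels.
#' @param intensity Optional numeric matrix from which per-component mean
#'   intensity is computed.
#' @return A list with one element per retained component: `mask` (logical
#'   matrix) and `stats` (one-row data frame with `label`, `area`,
#'   `centroid_r`, `centroid_c`, `r0`, `c0`, `r1`, `c1`, `mean_intensity`).
#' @export
component_masks <- function(labels, min_area = 20L, intensity = NULL) {
  if (!is.matrix(labels)) input_error("`labels` must be a matrix")
  ks <- setdiff(sort(unique(as.integer(labels))), 0L)
  out <- list()
  for (k in ks) {
    m <- labels == k
    area <- sum(m)
    if (area < min_area) next
    idx <- which(m, arr.ind = TRUE)
    out[[length(out) + 1L]] <- list(
      mask = m,
      stats = data.frame(
        label = k, area = area,
        centroid_r = mean(idx[, 1]), centroid_c = mean(idx[, 2]),
        r0 = min(idx[, 1]), c0 = min(idx[, 2]),
        r1 = max(idx[, 1]) + 1L, c1 = max(idx[, 2]) + 1L,
        mean_intensity = if (is.null(intensity)) NA_real_
                         else mean(intensity[m])
      )
    )
  }
  out
}

#' Flatten component statistics into one table
#'
#' @param components Output of [component_masks()].
#' @return A data frame with one row per component.
#' @export
component_table <- function(components) {
  if (!length(components))
    return(data.frame(label = integer(), area = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      r0 = integer(), c0 = integer(), r1 = integer(),
                      c1 = integer(), mean_intensity = numeric()))
  do.call(rbind, lapply(components, `[[`, "stats"))
}

#' Derive level-set seeds from components and markers
#'
#' Intersects every component with the sure-foreground markers: a component
#' holding m >= 2 disjoint sure-foreground blobs contributes m separate seed
#' labels, which is how two nuclei merged into one thresholded component
#' receive separate seeds. A component whose intersection is empty (typically
#' a nucleus too small to clear the global distance threshold) falls back to
#' the peak of its own distance transform as a single-pixel seed, with a
#' warning.
#'
#' @param components Output of [component_masks()].
#' @param markers A `"marker_set"` from [extract_markers()].
#' @return An integer seed label map; seeds are pairwise disjoint and, apart
#'   from fallback pixels, contained in `markers$sure_fg`.
#' @export
seed_markers_from_components <- function(components, markers) {
  if (!inherits(markers, "marker_set"))
    input_error("`markers` must come from extract_markers()")
  shape <- dim(markers$sure_fg)
  seeds <- matrix(0L, shape[1], shape[2])
  nxt <- 0L
  for (comp in components) {
    inter <- comp$mask & markers$sure_fg
    if (any(inter)) {
      blobs <- label_components(inter, connectivity = 8L)
      k <- max(blobs)
      seeds[blobs > 0L] <- blobs[blobs > 0L] + nxt
      nxt <- nxt + k
    } else {
      warning(sprintf(
        "component %d has no sure-foreground overlap; using distance peak",
        comp$stats$label))
      d <- distance_transform(comp$mask)
      peak <- which.max(d)              # first max in column-major order
      nxt <- nxt + 1L
      seeds[peak] <- nxt
    }
  }
  seeds
}

#' Detect nucleus seed points from the distance transform (plus LoG)
#'
#' Finds separated local maxima of the Gaussian-smoothed distance transform
#' (one per convex core; the saddle over the neck between touching nuclei
#' does not suppress either peak), optionally merged with dark LoG blob
#' centers, which can recover a deeply overlapped nucleus that has lost its
#' own distance peak but still forms an intensity blob. Candidates closer
#' together than `min_sep` are deduplicated, keeping the higher-scoring one
#' (distance peaks outrank LoG blobs); surviving points become small disk
#' seeds clipped to the mask, labeled 1..K in row-major order of their
#' centers.
#'
#' @param mask Logical foreground mask.
#' @param dist Distance transform of `mask`.
#' @param gray Optional grayscale image; when given, LoG blobs are added as
#'   candidates.
#' @param smooth Gaussian sd (px) applied to the distance field before peak
#'   picking.
#' @param min_dist Minimum distance-transform value at a candidate
#'   (suppresses peaks in thin debris).
#' @param min_sep Minimum separation between seeds (px).
#' @param seed_radius Radius of the disk stamped around each seed point.
#' @param log_sigmas,log_threshold Scales and response threshold of the LoG
#'   detector (see [detect_blobs()]).
#' @return An integer seed label map.
#' @export
detect_seed_points <- function(mask, dist = distance_transform(mask),
                               gray = NULL, smooth = 1.5, min_dist = 3,
                               min_sep = 7, seed_radius = 3,
                               log_sigmas = c(3, 4, 5, 6, 7, 8, 10),
                               log_threshold = 2) {
  assert_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  ds <- if (smooth > 0) gaussian_blur(dist, smooth) else dist
  h <- nrow(ds); w <- ncol(ds)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- ds
  nb <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) if (dr || dc)
    nb <- pmax(nb, p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
  pk <- which(ds > nb & dist >= min_dist, arr.ind = TRUE)
  score <- ds[pk]
  if (!is.null(gray)) {
    bl <- detect_blobs(gray, sigmas = log_sigmas, polarity = "dark",
                       threshold = log_threshold)
    if (nrow(bl)) {
      at <- as.matrix(bl[, c("row", "col")])
      keep <- dist[at] >= min_dist
      pk <- rbind(pk, at[keep, , drop = FALSE])
      score <- c(score, ds[at[keep, , drop = FALSE]] - 1e-9)
    }
  }
  if (!nrow(pk)) return(matrix(0L, h, w))
  ord <- order(-score, pk[, 1], pk[, 2])
  pk <- pk[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i] || i == nrow(pk)) next
    for (j in (i + 1L):nrow(pk)) {
      if (keep[j] &&
          (pk[i, 1] - pk[j, 1])^2 + (pk[i, 2] - pk[j, 2])^2 < min_sep^2)
        keep[j] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE]   # row-major labeling
  seeds <- matrix(0L, h, w)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(pk))) {
    disk <- (rr - pk[i, 1])^2 + (cc - pk[i, 2])^2 <= seed_radius^2
    seeds[disk & mask & seeds == 0L] <- i
  }
  seeds
}

#' Split label-map components that contain several seeds
#'
#' A labeled region holding two or more distinct seed regions is partitioned
#' by nearest seed (Euclidean distance to the seed regions; ties to the
#' lower seed label), so objects that met during a contour evolution are
#' reported as separate instances. Regions with at most one seed are
#' returned unchanged.
#'
#' @param labels Integer label map (e.g. from [run_gac()]).
#' @param seeds Integer seed label map.
#' @return An integer label map relabeled 1..K deterministically.
#' @export
split_labels_by_seeds <- function(labels, seeds) {
  if (!identical(dim(labels), dim(seeds)))
    input_error("`labels` and `seeds` must have the same shape")
  ks <- setdiff(sort(unique(as.integer(seeds))), 0L)
  sd_maps <- lapply(ks, function(k) distance_transform(!(seeds == k)))
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  for (lb in setdiff(sort(unique(as.integer(labels))), 0L)) {
    m <- labels == lb
    present <- ks[vapply(ks, function(k) any(seeds[m] == k), logical(1))]
    if (length(present) >= 2L) {
      dstack <- vapply(match(present, ks), function(i) sd_maps[[i]][m],
                       numeric(sum(m)))
      pick <- present[max.col(-dstack, ties.method = "first")]
      for (k in present) {
        nxt <- nxt + 1L
        idx <- which(m)[pick == k]
        out[idx] <- nxt
      }
    } else {
      nxt <- nxt + 1L
      out[m] <- nxt
    }
  }
  out
}
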