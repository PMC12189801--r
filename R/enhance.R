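#' Luminance grayscale conversion
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image Numeric H x W x 3 RGB array in `[0, 1]`.
#' @return Numeric H x W matrix in `[0, 1]`.
#' @export
to_gray <- function(image) {
  assert_rgb_image(image)
  g <- 0.299 * image[, , 1, drop = FALSE] +
    0.587 * image[, , 2, drop = FALSE] +
    0.114 * image[, , 3, drop = FALSE]
  matrix(g, dim(image)[1], dim(image)[2])
}

#' Structuring element for binary morphology
#'
#' @param size Odd side length of the full square footprint (default 3).
#' @param iterations How many times the elementary operation is repeated.
#' @param footprint Optional explicit odd-sized logical matrix overriding the
#'   square; must contain its center.
#' @return A list of class `"structuring_element"`.
#' @export
structuring_element <- function(size = 3L, iterations = 1L, footprint = NULL) {
  if (is.null(footprint)) {
    if (size %% 2L != 1L || size < 1L)
      config_error("`size` must be a positive odd integer")
    footprint <- matrix(TRUE, size, size)
  }
  if (!is.matrix(footprint) || any(dim(footprint) %% 2L != 1L))
    config_error("`footprint` must have odd dimensions")
  footprint <- footprint != 0
  ctr <- (dim(footprint) + 1L) %/% 2L
  if (!footprint[ctr[1], ctr[2]])
    config_error("`footprint` must contain its center")
  if (iterations < 1L) config_error("`iterations` must be >= 1")
  structure(list(footprint = footprint, iterations = as.integer(iterations)),
            class = "structuring_element")
}

#' Otsu's threshold on a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over the 256 candidate
#' cuts; ties go to the lowest cut. Returns the upper edge of the chosen bin
#' so that `gray < threshold` captures the lower class.
#'
#' @param gray Numeric matrix with values in `[0, 1]`.
#' @return The threshold in `[0, 1]`, or `NA` for a constant image.
#' @export
otsu_threshold <- function(gray) {
  assert_gray(gray)
  if (max(gray) - min(gray) < .Machine$double.eps) return(NA_real_)
  bins <- pmin(floor(as.vector(gray) * 256), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  mids <- (0:255 + 0.5) / 256
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[256]
  w1 <- 1 - w0
  between <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu0)^2 / (w0 * w1), -Inf)
  k <- which.max(between[1:255])          # cut after bin k-1 (0-based k-1)
  k / 256
}

#' Threshold a grayscale image into a foreground mask
#'
#' Foreground is the dark class (`gray < t`): on a hematoxylin-channel image
#' the nuclei absorb strongly and appear dark. The Otsu method picks `t` by
#' maximizing between-class variance on a 256-bin histogram.
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param level Threshold for `method = "fixed"`.
#' @return A logical foreground mask. A constant image under Otsu yields an
#'   all-`FALSE` mask with a warning.
#' @export
binary_threshold <- function(gray, method = c("otsu", "fixed"), level = NULL) {
  assert_gray(gray)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(level)) config_error("`level` required for method = \"fixed\"")
    return(gray < level)
  }
  t <- otsu_threshold(gray)
  if (is.na(t)) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  gray < t
}

# Erode/dilate via EBImage with explicit background padding so that pixels
# outside the frame count as background for both operations (EBImage's own
# erode treats the outside as foreground, which would keep border pixels).
morph_once <- function(mask, op, footprint) {
  pad <- (dim(footprint) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L * pad[1], w + 2L * pad[2])
  padded[pad[1] + seq_len(h), pad[2] + seq_len(w)] <- mask
  kern <- footprint * 1
  out <- if (op == "erode") EBImage::erode(padded * 1, kern)
         else EBImage::dilate(padded * 1, kern)
  matrix(as.vector(out) > 0.5, h + 2L * pad[1], w + 2L * pad[2])[
    pad[1] + seq_len(h), pad[2] + seq_len(w)]
}

#' Binary morphology
#'
#' Minkowski erosion and dilation with the structuring element's footprint,
#' repeated `iterations` times; `open` is erosion then dilation, `close`
#' dilation then erosion (each side run `iterations` times). Pixels outside
#' the image count as background for both operations, so foreground touching
#' the frame erodes away.
#'
#' @param mask Logical matrix.
#' @param op One of `"erode"`, `"dilate"`, `"open"`, `"close"`.
#' @param se A [structuring_element()].
#' @return A logical matrix of the same shape.
#' @export
morphology <- function(mask, op = c("erode", "dilate", "open", "close"),
                       se = structuring_element()) {
  assert_mask(mask)
  op <- match.arg(op)
  reps <- function(m, o) {
    for (i in seq_len(se$iterations)) m <- morph_once(m, o, se$footprint)
    m
  }
  switch(op,
    erode  = reps(mask, "erode"),
    dilate = reps(mask, "dilate"),
    open   = reps(reps(mask, "erode"), "dilate"),
    close  = reps(reps(mask, "dilate"), "erode")
  )
}

#' Remove foreground components touching the image border
#'
#' Any 8-connected foreground component with a pixel on the first or last
#' row or column is deleted.
#'
#' @param mask Logical matrix.
#' @return A logical matrix of the same shape.
#' @export
clear_borders <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 8L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  if (length(border)) mask[lab %in% border] <- FALSE
  mask
}

#' Exact Euclidean distance transform
#'
#' Distance from each foreground pixel to the nearest background pixel, in
#' pixel units; zero on background. A mask with no background pixel uses a
#' virtual background ring just outside the frame, so each pixel gets its
#' distance to the nearest image edge plus one.
#'
#' @param mask Logical matrix.
#' @return A numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (all(mask)) {
    r <- matrix(seq_len(h), h, w)
    c <- matrix(seq_len(w), h, w, byrow = TRUE)
    return(pmin(r, h + 1L - r, pmin(c, w + 1L - c)))
  }
  if (!any(mask)) return(matrix(0, h, w))
  d <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), h, w)
}

#' Sure-foreground / sure-background / unknown marker partition
#'
#' The distance-transform ridge marks pixels that surely belong to a nucleus
#' (`dist > fg_fraction * max(dist)`); the complement of a dilation of the
#' mask surely belongs to the background; what remains of the dilated mask is
#' the unknown band between them, where object boundaries will be resolved.
#'
#' @param mask Logical foreground mask.
#' @param dist Distance transform of `mask` (see [distance_transform()]).
#' @param fg_fraction Fraction of the maximum distance defining sure
#'   foreground, in (0, 1).
#' @param bg_se Structuring element for the background-side dilation.
#' @param scope `"global"` thresholds against the maximum distance over the
#'   whole image (the classic recipe); `"component"` thresholds each
#'   8-connected component against its own maximum, which keeps small nuclei
#'   represented and splits touching pairs of any size (the threshold then
#'   sits above the distance saddle of the neck between them).
#' @return A list of class `"marker_set"` with logical matrices `sure_fg`,
#'   `sure_bg` and `unknown`. An empty mask yields empty `sure_fg`/`unknown`
#'   and all-background `sure_bg`.
#' @export
extract_markers <- function(mask, dist = distance_transform(mask),
                            fg_fraction = 0.5,
                            bg_se = structuring_element(3L, iterations = 3L),
                            scope = c("global", "component")) {
  assert_mask(mask)
  scope <- match.arg(scope)
  if (fg_fraction <= 0 || fg_fraction >= 1)
    config_error("`fg_fraction` must be in (0, 1)")
  if (scope == "global" || !any(mask)) {
    sure_fg <- dist > fg_fraction * max(dist)
  } else {
    lab <- label_components(mask, connectivity = 8L)
    peak <- vapply(seq_len(max(lab)), function(k) max(dist[lab == k]),
                   numeric(1))
    thr <- matrix(Inf, nrow(mask), ncol(mask))
    thr[lab > 0L] <- fg_fraction * peak[lab[lab > 0L]]
    sure_fg <- dist > thr
  }
  dilated <- if (any(mask)) morphology(mask, "dilate", bg_se) else mask
  structure(
    list(sure_fg = sure_fg,
         sure_bg = !dilated,
         unknown = dilated & !sure_fg),
    class = "marker_set"
  )
}
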