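#' Stain separation for H&E histology
#'
#' Hematoxylin and eosin absorb light multiplicatively, so stains mix
#' additively in optical-density (base-10 absorbance) space: for a pixel with
#' transmitted intensity `I` per channel, `OD = -log10(I)` and `OD ~ M %*% c`
#' where `M` is the 3 x 2 stain matrix (unit OD color vectors of hematoxylin
#' and eosin as columns) and `c` the two stain concentrations. The stain
#' matrix of a slide is estimated from the tissue OD tuples by singular value
#' decomposition: the tuples are projected onto the plane of the two leading
#' singular directions, and the robust angular extremes of the projections
#' (at the `alpha` and `100 - alpha` percentiles) are taken as the two stain
#' directions. Hematoxylin is the extreme with the larger blue-channel
#' absorbance.
#'
#' @name stain-separation
NULL

#' Parameters for stain estimation and normalization
#'
#' @param alpha Robustness percentile for the angular extremes, in percent.
#'   `alpha = 1` uses the 1st and 99th percentiles of the projection angles.
#' @param beta Transparency threshold in OD units: pixels whose OD exceeds
#'   `beta` in at least one channel count as tissue; near-white pixels below
#'   it are excluded from stain estimation.
#' @param epsilon Intensity floor applied before the logarithm, avoiding
#'   `log(0)` for saturated black pixels.
#' @param reference_stains Optional 3 x 2 reference stain matrix; when given,
#'   normalized output is rendered with these vectors instead of the
#'   image's own estimate.
#' @param reference_max_conc Optional length-2 vector of reference maximum
#'   concentrations (hematoxylin, eosin) used to rescale concentrations.
#' @return A list of class `"normalization_params"`.
#' @export
normalization_params <- function(alpha = 1, beta = 0.15, epsilon = 1e-6,
                                 reference_stains = NULL,
                                 reference_max_conc = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 50)
    config_error("`alpha` must be a percentile in (0, 50)")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    config_error("`beta` must be > 0")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon >= 1)
    config_error("`epsilon` must be in (0, 1)")
  if (!is.null(reference_stains)) assert_stain_matrix(reference_stains)
  if (!is.null(reference_max_conc) &&
      (!is.numeric(reference_max_conc) || length(reference_max_conc) != 2L ||
       any(reference_max_conc <= 0)))
    config_error("`reference_max_conc` must be two positive numbers")
  structure(
    list(alpha = alpha, beta = beta, epsilon = epsilon,
         reference_stains = reference_stains,
         reference_max_conc = reference_max_conc),
    class = "normalization_params"
  )
}

assert_stain_matrix <- function(stains, arg = "stains") {
  if (!is.matrix(stains) || !identical(dim(stains), c(3L, 2L)))
    input_error(sprintf("`%s` must be a 3 x 2 matrix", arg))
  if (any(stains < -1e-12))
    input_error(sprintf("`%s` must have nonnegative entries", arg))
  nrm <- sqrt(colSums(stains^2))
  if (any(abs(nrm - 1) > 1e-6))
    input_error(sprintf("`%s` columns must be unit vectors", arg))
  if (abs(sum(stains[, 1] * stains[, 2])) > 1 - 1e-8)
    degenerate_stain_error("stain vectors are collinear")
  invisible(stains)
}

#' Convert intensities to optical densities
#'
#' `OD = -log10(max(I, epsilon))` per channel. With intensities in `[0, 1]`
#' the result lies in `[0, -log10(epsilon)]`.
#'
#' @param image Numeric H x W x 3 array in `[0, 1]`.
#' @param epsilon Intensity floor in (0, 1).
#' @return Numeric H x W x 3 array of optical densities.
#' @export
rgb_to_od <- function(image, epsilon = 1e-6) {
  assert_rgb_image(image)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
    config_error("`epsilon` must be in (0, 1)")
  -log10(pmax(image, epsilon))
}

#' Convert optical densities back to intensities
#'
#' Inverse of [rgb_to_od()]: `I = 10^(-OD)`, clamped to `[0, 1]`. The round
#' trip is exact for intensities at or above the floor `epsilon`.
#'
#' @param od Numeric array of nonnegative optical densities.
#' @return Array of intensities in `[0, 1]`, same shape as `od`.
#' @export
od_to_rgb <- function(od) {
  if (!all(is.finite(od))) input_error("`od` contains non-finite values")
  if (min(od) < 0) input_error("`od` must be nonnegative")
  pmin(pmax(10^(-od), 0), 1)
}

#' Extract tissue OD tuples for stain estimation
#'
#' Keeps the pixels whose optical density exceeds `beta` in at least one
#' channel, i.e. discards near-transparent background that carries no stain
#' information. Tuples are returned in row-major pixel order (scanning rows
#' top to bottom, columns left to right).
#'
#' @param od Numeric H x W x 3 optical-density array.
#' @param beta Transparency threshold in OD units.
#' @return An N x 3 matrix of OD tuples.
#' @export
tissue_pixels <- function(od, beta = 0.15) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    input_error("`od` must be an H x W x 3 array")
  if (beta <= 0) config_error("`beta` must be > 0")
  h <- dim(od)[1]; w <- dim(od)[2]
  m <- matrix(od, h * w, 3L)            # column-major pixel order
  keep <- m[, 1] > beta | m[, 2] > beta | m[, 3] > beta
  if (!any(keep))
    no_tissue_error("no pixel exceeds the OD threshold `beta`; image is blank")
  # reorder column-major indices into row-major scan order
  idx <- which(keep)
  r <- (idx - 1L) %% h; c <- (idx - 1L) %/% h
  m[idx[order(r * w + c)], , drop = FALSE]
}

#' Estimate the H&E stain matrix from optical densities
#'
#' Implements SVD-plane stain estimation: the tissue OD tuples are projected
#' onto the plane spanned by the two leading right-singular vectors, the
#' angle of each projection is taken with respect to the first direction, and
#' the directions at the `alpha` and `100 - alpha` angle percentiles are
#' back-projected to OD space as the two stain vectors. Each basis vector is
#' sign-flipped so its entry sum is nonnegative before angles are computed;
#' percentiles use linear interpolation between order statistics. The
#' min-angle extreme is provisionally hematoxylin and the max-angle extreme
#' eosin; the columns are swapped if eosin ends up with the larger
#' blue-channel absorbance, since hematoxylin absorbs more blue.
#'
#' @param od Numeric H x W x 3 optical-density array.
#' @param params A [normalization_params()] object.
#' @return A 3 x 2 stain matrix with unit-norm nonnegative columns
#'   (hematoxylin first).
#' @export
estimate_stain_matrix <- function(od, params = normalization_params()) {
  tuples <- tissue_pixels(od, params$beta)
  if (nrow(tuples) < 2L)
    degenerate_stain_error("need at least two tissue pixels")
  sv <- svd(tuples, nu = 0, nv = 3)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-8)
    degenerate_stain_error("tissue OD tuples are collinear; no stain plane")
  basis <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) if (sum(basis[, j]) < 0) basis[, j] <- -basis[, j]
  proj <- tuples %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(params$alpha, 100 - params$alpha) / 100,
                        names = FALSE, type = 7)
  extreme <- function(a) {
    v <- basis %*% c(cos(a), sin(a))
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  }
  h <- extreme(qs[1]); e <- extreme(qs[2])
  m <- cbind(h, e)
  if (m[3, 2] > m[3, 1]) m <- m[, 2:1]   # hematoxylin absorbs more blue
  dimnames(m) <- list(c("r", "g", "b"), c("hematoxylin", "eosin"))
  if (abs(sum(m[, 1] * m[, 2])) > 1 - 1e-8)
    degenerate_stain_error("estimated stain vectors are collinear")
  m
}

#' Solve per-pixel stain concentrations
#'
#' Least-squares inversion of the Beer-Lambert mixture `OD ~ M %*% c` for
#' every pixel, with negative solutions clamped to zero. The solve is exact
#' when the OD lies in the nonnegative span of the stain vectors.
#'
#' @param od Numeric H x W x 3 optical-density array.
#' @param stains 3 x 2 stain matrix.
#' @return Numeric H x W x 2 array of nonnegative concentrations
#'   (hematoxylin, eosin).
#' @export
compute_concentrations <- function(od, stains) {
  assert_stain_matrix(stains)
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    input_error("`od` must be an H x W x 3 array")
  h <- dim(od)[1]; w <- dim(od)[2]
  g <- crossprod(stains)                       # 2 x 2 Gram matrix
  if (abs(det(g)) < 1e-12)
    degenerate_stain_error("stain matrix is singular")
  odm <- t(matrix(od, h * w, 3L))              # 3 x N
  conc <- solve(g, crossprod(stains, odm))     # 2 x N
  conc <- pmax(conc, 0)
  array(t(conc), dim = c(h, w, 2L))
}

robust_max_conc <- function(conc) {
  apply(matrix(conc, ncol = 2L), 2L,
        stats::quantile, probs = 0.99, names = FALSE, type = 7)
}

#' Separate an H&E image into normalized H&E, H-only and E-only renderings
#'
#' Estimates the stain matrix, solves concentrations, rescales them by the
#' ratio of reference to observed robust maximum concentration (99th
#' percentile per stain) when a reference is supplied, and re-renders through
#' the Beer-Lambert law. `h_only` keeps only the hematoxylin channel (the
#' nuclei), `e_only` only eosin; `normalized_he` renders both channels
#' against the reference stain vectors (or the image's own estimate when no
#' reference is given). Downstream nuclei detection operates on `h_only`.
#'
#' @param image Numeric H x W x 3 RGB array in `[0, 1]`.
#' @param params A [normalization_params()] object.
#' @return A list of class `"stain_separation"` with elements
#'   `normalized_he`, `h_only`, `e_only` (RGB arrays), `stains` (the
#'   estimated 3 x 2 matrix), `conc` (H x W x 2 concentrations, unscaled) and
#'   `max_conc` (the per-stain robust maxima).
#' @export
separate_stains <- function(image, params = normalization_params()) {
  assert_rgb_image(image)
  od <- rgb_to_od(image, params$epsilon)
  stains <- estimate_stain_matrix(od, params)
  conc <- compute_concentrations(od, stains)
  max_conc <- robust_max_conc(conc)
  scale <- if (is.null(params$reference_max_conc)) c(1, 1)
           else params$reference_max_conc / pmax(max_conc, 1e-12)
  render_stains <- if (is.null(params$reference_stains)) stains
                   else params$reference_stains
  h <- dim(image)[1]; w <- dim(image)[2]
  cs <- t(matrix(conc, h * w, 2L)) * scale     # 2 x N, rescaled
  render <- function(m2) {
    odm <- m2 %*% cs                           # 3 x N
    od_to_rgb(array(t(odm), dim = c(h, w, 3L)))
  }
  out <- list(
    normalized_he = render(render_stains),
    h_only = render(cbind(render_stains[, 1], 0)),
    e_only = render(cbind(0, render_stains[, 2])),
    stains = stains,
    conc = conc,
    max_conc = max_conc
  )
  class(out) <- "stain_separation"
  out
}

#' @export
print.stain_separation <- function(x, ...) {
  cat("H&E stain separation\n")
  cat(sprintf("  image: %d x %d\n", dim(x$h_only)[1], dim(x$h_only)[2]))
  cat("  stain matrix (OD unit vectors):\n")
  print(round(x$stains, 4))
  cat(sprintf("  robust max concentration: H %.3f, E %.3f\n",
              x$max_conc[1], x$max_conc[2]))
  invisible(x)
}

#' Write / read a stain reference sidecar
#'
#' Stores the stain matrix and robust maximum concentrations of a reference
#' image as YAML so other images can be normalized against it.
#'
#' @param separation A `"stain_separation"` object.
#' @param path Output `.yaml` path.
#' @return `path` invisibly (write); a [normalization_params()] object whose
#'   reference fields are filled in (read).
#' @export
write_stain_reference <- function(separation, path) {
  yaml::write_yaml(list(
    stain_matrix = lapply(1:2, function(j) as.numeric(separation$stains[, j])),
    max_conc = as.numeric(separation$max_conc)
  ), path)
  invisible(path)
}

#' @rdname write_stain_reference
#' @param alpha,beta,epsilon Passed through to [normalization_params()].
#' @export
read_stain_reference <- function(path, alpha = 1, beta = 0.15,
                                 epsilon = 1e-6) {
  y <- yaml::read_yaml(path)
  m <- cbind(as.numeric(y$stain_matrix[[1]]), as.numeric(y$stain_matrix[[2]]))
  normalization_params(alpha = alpha, beta = beta, epsilon = epsilon,
                       reference_stains = m,
                       reference_max_conc = as.numeric(y$max_conc))
}
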