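#' Geodesic active contours on a level set
#'
#' The contour is carried implicitly as the zero level of a signed field `u`
#' (negative inside, positive outside) evolved by
#'
#'   du/dt = g(I) (kappa + v) |grad u| + grad g . grad u
#'
#' where `kappa = div(grad u / |grad u|)` is the curvature of the level set,
#' `v` a constant balloon speed (positive shrinks the contour along the
#' inward normal, negative inflates it), and `g(I) = 1 / (1 + |grad I1|^p)`
#' an edge-stopping factor computed on the Gaussian-smoothed image `I1`:
#' close to 1 in flat regions, small on edges, so the moving front halts on
#' nucleus boundaries while the advection term `grad g . grad u` pulls a
#' front that overshoots an edge back onto it. Because the contour is a
#' level set, splitting and merging need no special handling; fronts grown
#' from distinct seeds meet at shared edges without crossing them.
#'
#' @name geodesic-active-contours
NULL

#' Numerical parameters of the level-set evolution
#'
#' @param v Balloon constant. Positive shrinks, negative expands; the default
#'   -0.5 inflates seeds placed inside nuclei toward their boundaries and
#'   exceeds the curvature of the smallest seed disks, whose fronts would
#'   otherwise collapse under the regularizing term.
#' @param p Exponent of the stopping function (1 or 2).
#' @param smooth_sigma Gaussian sd (pixels) of the pre-smoothing that defines
#'   `I1`.
#' @param edge_gain Intensity scale applied to the image before smoothing,
#'   so gradients are measured in units of `edge_gain` gray levels per
#'   pixel. With `edge_gain = 1` the stopping field of a `[0, 1]` image is
#'   nearly constant and the balloon runs through every edge; very large
#'   gains drive `g` to zero over the whole blurred edge ramp, stalling the
#'   front well before the boundary. The default 40 makes a sharp nucleus
#'   boundary (smoothed gradient around 0.1 intensity units per pixel)
#'   yield `g` near 0.06 while keeping `g` close to 1 in noise-textured
#'   flat regions.
#' @param dt Explicit time step; checked against the CFL bound
#'   `dt * max advective speed <= 0.5`.
#' @param max_iters Maximum number of explicit steps.
#' @param reinit_every Reinitialize `u` to a signed distance function every
#'   this many steps.
#' @param tol Convergence threshold on the mean absolute update within the
#'   narrow band (`|u| < 3`).
#' @param band_tol Half-width (grid units) of the band used for the
#'   convergence test.
#' @param topology `"preserve"` (default) forbids any sign flip that would
#'   8-connect the interiors of two different seeds, leaving a one-pixel
#'   ridge between fronts that meet; this is what keeps touching nuclei
#'   separate even across a weak shared edge, where an unconstrained
#'   balloon would slowly creep through the stopping-function valley and
#'   merge them. `"free"` is the classical evolution in which fronts merge
#'   wherever they meet.
#' @return A list of class `"gac_params"`.
#' @export
gac_params <- function(v = -0.5, p = 2L, smooth_sigma = 2, edge_gain = 40,
                       dt = 0.4, max_iters = 500L, reinit_every = 20L,
                       tol = 1e-4, band_tol = 3,
                       topology = c("preserve", "free")) {
  if (!p %in% c(1L, 2L)) config_error("`p` must be 1 or 2")
  if (dt <= 0) config_error("`dt` must be > 0")
  if (edge_gain <= 0) config_error("`edge_gain` must be > 0")
  if (max_iters < 1L) config_error("`max_iters` must be >= 1")
  if (reinit_every < 1L) config_error("`reinit_every` must be >= 1")
  if (smooth_sigma < 0) config_error("`smooth_sigma` must be >= 0")
  structure(list(v = v, p = as.integer(p), smooth_sigma = smooth_sigma,
                 edge_gain = edge_gain, dt = dt,
                 max_iters = as.integer(max_iters),
                 reinit_every = as.integer(reinit_every), tol = tol,
                 band_tol = band_tol, topology = match.arg(topology)),
            class = "gac_params")
}

# central differences with replicated borders; returns d/drow, d/dcol
central_diff <- function(u) {
  h <- nrow(u); w <- ncol(u)
  up <- u[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- u[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  lf <- u[, c(1L, seq_len(w - 1L)), drop = FALSE]
  rt <- u[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

# one-sided differences with replicated borders (zero gradient at the frame)
onesided_diff <- function(u) {
  h <- nrow(u); w <- ncol(u)
  up <- u[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- u[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  lf <- u[, c(1L, seq_len(w - 1L)), drop = FALSE]
  rt <- u[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  list(bm = u - up, fp = dn - u, bl = u - lf, fr = rt - u)
}

gaussian_blur <- function(gray, sigma) {
  if (sigma <= 0) return(gray)
  size <- 2L * ceiling(3 * sigma) + 1L
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  matrix(as.numeric(EBImage::filter2(gray, brush, boundary = "replicate")),
         nrow(gray), ncol(gray))
}

#' Edge-stopping field g(I) and its gradient
#'
#' `g = 1 / (1 + |grad I1|^p)` with `I1` the Gaussian-smoothed image and the
#' gradient taken by central differences. `g` is 1 wherever the smoothed
#' gradient vanishes and decays toward 0 on strong edges.
#'
#' @param gray Numeric image matrix.
#' @param smooth_sigma Gaussian sd of the pre-smoothing (0 = none).
#' @param p Exponent, 1 or 2.
#' @param gain Intensity scale applied before smoothing (see the
#'   `edge_gain` argument of [gac_params()]); the default 1 leaves the
#'   image in its native units.
#' @return A list of class `"stopping_field"` with `g` (matrix in (0, 1])
#'   and `grad_g` (H x W x 2 array of row-/col-derivatives of `g`).
#' @export
stopping_function <- function(gray, smooth_sigma = 2, p = 2L, gain = 1) {
  assert_gray(gray)
  if (!p %in% c(1L, 2L)) config_error("`p` must be 1 or 2")
  i1 <- gaussian_blur(gain * gray, smooth_sigma)
  d <- central_diff(i1)
  gm <- sqrt(d$dr^2 + d$dc^2)
  g <- 1 / (1 + gm^p)
  dg <- central_diff(g)
  structure(list(g = g, grad_g = array(c(dg$dr, dg$dc),
                                       dim = c(nrow(g), ncol(g), 2L))),
            class = "stopping_field")
}

#' Initialize a level set from seed regions
#'
#' `u` is the signed Euclidean distance to the seed-region boundary:
#' negative inside any seed (distance to the nearest non-seed pixel),
#' positive outside (distance to the nearest seed pixel).
#'
#' @param seeds Integer label map; pixels `> 0` are inside.
#' @return A numeric matrix `u`.
#' @export
init_level_set <- function(seeds) {
  if (!is.matrix(seeds)) input_error("`seeds` must be a matrix")
  inside <- seeds > 0
  if (!any(inside)) input_error("`seeds` has no positive pixel")
  distance_transform(!inside) - distance_transform(inside)
}

#' Curvature of the level sets
#'
#' `div(grad u / |grad u|)` by central differences, with `|grad u|` floored
#' at 1e-8 and the result clamped to `[-1, 1]` (one inverse grid unit) for
#' stability near singular points.
#'
#' @param u Level-set matrix.
#' @return A numeric matrix of curvatures.
#' @export
curvature <- function(u) {
  if (!all(is.finite(u))) input_error("`u` contains non-finite values")
  d1 <- central_diff(u)
  ur <- d1$dr; uc <- d1$dc
  drr <- central_diff(ur)
  dcc <- central_diff(uc)
  urr <- drr$dr; urc <- drr$dc; ucc <- dcc$dc
  den <- (ur^2 + uc^2)^1.5
  k <- (urr * uc^2 - 2 * ur * uc * urc + ucc * ur^2) / pmax(den, 1e-8)
  pmin(pmax(k, -1), 1)
}

# Godunov upwind gradient magnitude for motion u_t = F |grad u|
upwind_grad <- function(os, positive_speed) {
  if (positive_speed)
    sqrt(pmax(os$bm, 0)^2 + pmin(os$fp, 0)^2 +
         pmax(os$bl, 0)^2 + pmin(os$fr, 0)^2)
  else
    sqrt(pmin(os$bm, 0)^2 + pmax(os$fp, 0)^2 +
         pmin(os$bl, 0)^2 + pmax(os$fr, 0)^2)
}

#' One explicit evolution step
#'
#' Advances `u` by `dt * (g (kappa + v) |grad u| + grad g . grad u)`. The
#' curvature (parabolic) term uses central differences; the balloon term
#' uses the Godunov upwind gradient chosen by the sign of `v * g`; the
#' advection term upwinds each component by the sign of the corresponding
#' component of `grad g`. The advective CFL condition
#' `dt * max(g |v| + |grad g|_1) <= 0.5` is checked before stepping.
#'
#' @param u Level-set matrix.
#' @param stop_field A `"stopping_field"` from [stopping_function()] (or
#'   `NULL` for `g == 1`, pure curvature/balloon flow).
#' @param params A [gac_params()] object.
#' @return The updated level-set matrix.
#' @export
evolve_step <- function(u, stop_field = NULL, params = gac_params()) {
  if (!all(is.finite(u))) input_error("`u` contains non-finite values")
  if (is.null(stop_field)) {
    g <- matrix(1, nrow(u), ncol(u))
    ggr <- gc0 <- matrix(0, nrow(u), ncol(u))
  } else {
    g <- stop_field$g
    ggr <- stop_field$grad_g[, , 1]
    gc0 <- stop_field$grad_g[, , 2]
  }
  speed <- max(g) * abs(params$v) + max(abs(ggr) + abs(gc0))
  if (params$dt * speed > 0.5 + 1e-12)
    config_error(sprintf(
      "CFL violated: dt * max advective speed = %.3f > 0.5",
      params$dt * speed))

  d1 <- central_diff(u)
  grad_c <- sqrt(d1$dr^2 + d1$dc^2)
  k <- curvature(u)
  os <- onesided_diff(u)
  # balloon: sign of v selects the upwind stencil (g >= 0 never flips it);
  # u_t = v g |grad u| is u_t + F |grad u| = 0 with F = -v g, and the
  # grad-plus stencil applies where F > 0, i.e. for expansion (v < 0)
  balloon <- params$v * g * upwind_grad(os, positive_speed = params$v < 0)
  # advection grad g . grad u: information comes from the side g increases
  adv <- ifelse(ggr > 0, os$fp, os$bm) * ggr +
         ifelse(gc0 > 0, os$fr, os$bl) * gc0
  u + params$dt * (g * k * grad_c + balloon + adv)
}

#' Reinitialize a level set to a signed distance function
#'
#' Iterates the reinitialization flow `u_t = S(u0) (1 - |grad u|)` (Godunov
#' upwind, smoothed sign `S = u0 / sqrt(u0^2 + 1)`) to steady state, which
#' restores `|grad u| = 1` outward from the zero level. Cells adjacent to
#' the zero crossing are instead relaxed toward the subcell distance
#' interpolated from the input field (`u0 / |grad u0|`), which pins the
#' interface in place across repeated reinitializations. A field that is
#' already a signed distance function is a fixed point. The default
#' iteration count rebuilds the distance field within a band of roughly
#' `iters / 2` pixels around the contour, which is all the evolution needs
#' between reinitializations.
#'
#' @param u Level-set matrix.
#' @param iters Number of reinitialization iterations.
#' @param dt Pseudo-time step (<= 0.5 for stability).
#' @return The reinitialized matrix; returned unchanged with a warning when
#'   `u` has no zero crossing (single-signed field).
#' @export
reinitialize <- function(u, iters = 20L, dt = 0.5) {
  if (!all(is.finite(u))) input_error("`u` contains non-finite values")
  if (all(u > 0) || all(u < 0)) {
    warning("level set has no zero crossing; reinitialization skipped")
    return(u)
  }
  u0 <- u
  s <- u0 / sqrt(u0^2 + 1)
  pos <- s > 0
  # interface cells: sign change to a 4-neighbor in the input field
  os0 <- onesided_diff(u0)
  iface <- (u0 * (u0 - os0$bm) < 0) | (u0 * (u0 + os0$fp) < 0) |
           (u0 * (u0 - os0$bl) < 0) | (u0 * (u0 + os0$fr) < 0) | u0 == 0
  # subcell distance u0 / |grad u0| with the gradient taken as the per-axis
  # maximum of one-sided differences: robust at the ridge of small blobs,
  # where central differences underestimate the slope
  gr <- pmax(abs(os0$bm), abs(os0$fp))
  gc <- pmax(abs(os0$bl), abs(os0$fr))
  target <- u0 / pmax(sqrt(gr^2 + gc^2), 0.5)
  for (i in seq_len(iters)) {
    os <- onesided_diff(u)
    gu <- ifelse(pos, upwind_grad(os, TRUE), upwind_grad(os, FALSE))
    u_new <- u + dt * s * (1 - gu)
    u_new[iface] <- u[iface] - dt * (sign(u0[iface]) * abs(u[iface]) -
                                       target[iface])
    u <- u_new
  }
  u
}

#' Run the geodesic active-contour segmentation
#'
#' Grows one shared level set from all seeds under the stopping field of
#' `gray`, reinitializing every `reinit_every` steps, until the mean
#' absolute update inside the narrow band falls below `tol` or `max_iters`
#' is reached. Final interiors are labeled by 8-connected components and
#' each is renamed to the seed label with which it shares the most area
#' (components that overlap no seed get fresh labels).
#'
#' @param gray Numeric image matrix (typically the hematoxylin-channel
#'   grayscale).
#' @param seeds Integer seed label map.
#' @param params A [gac_params()] object.
#' @return A list of class `"gac_result"` with `labels` (integer matrix),
#'   `contours` (see [extract_contours()]), `u` (final level set) and
#'   `iterations` (steps actually run). If every interior vanishes the
#'   labels are all zero and a warning is raised.
#' @export
run_gac <- function(gray, seeds, params = gac_params()) {
  assert_gray(gray)
  u <- init_level_set(seeds)
  stop_field <- stopping_function(gray, params$smooth_sigma, params$p,
                                  gain = params$edge_gain)
  # honor the CFL bound by shrinking the step rather than erroring: the
  # advective speed depends on the image, not on the configuration
  speed <- max(stop_field$g) * abs(params$v) +
    max(abs(stop_field$grad_g[, , 1]) + abs(stop_field$grad_g[, , 2]))
  if (params$dt * speed > 0.5) {
    dt_new <- 0.5 / speed
    params$max_iters <- as.integer(ceiling(params$max_iters *
                                             params$dt / dt_new))
    params$dt <- dt_new
  }
  owner <- matrix(0L, nrow(u), ncol(u))
  owner[u < 0] <- seeds[u < 0]
  preserve <- params$topology == "preserve"
  iters_run <- 0L
  for (i in seq_len(params$max_iters)) {
    u_new <- evolve_step(u, stop_field, params)
    band <- abs(u) < params$band_tol
    delta <- if (any(band)) mean(abs(u_new[band] - u[band])) else 0
    if (preserve) {
      st <- enforce_seed_identity(u_new, u, owner)
      u <- st$u; owner <- st$owner
    } else {
      u <- u_new
    }
    iters_run <- i
    if (i %% params$reinit_every == 0L && any(u < 0) && any(u > 0)) {
      u_re <- reinitialize(u)
      if (preserve) {
        st <- enforce_seed_identity(u_re, u, owner)
        u <- st$u; owner <- st$owner
      } else {
        u <- u_re
      }
    }
    if (delta < params$tol) break
  }
  inside <- u < 0
  if (!any(inside)) {
    warning("all contours vanished during evolution")
    return(structure(list(labels = matrix(0L, nrow(u), ncol(u)),
                          contours = list(), u = u,
                          iterations = iters_run),
                     class = "gac_result"))
  }
  final <- label_components(inside, connectivity = 8L)
  labels <- match_labels_to_seeds(final, seeds)
  structure(list(labels = labels, contours = extract_contours(u), u = u,
                 iterations = iters_run),
            class = "gac_result")
}

# Seed-identity constraint: every interior pixel belongs to the basin of
# exactly one seed. A pixel whose level-set value turns negative inherits
# the owner of its negative 8-neighbors; if those neighbors disagree (two
# fronts meeting) the flip is vetoed and the pixel pinned slightly
# positive, leaving a one-pixel ridge between the basins. Flips are
# processed in row-major order, so the result is deterministic.
enforce_seed_identity <- function(u_new, u_old, owner) {
  h <- nrow(u_new); w <- ncol(u_new)
  gone <- which(u_new >= 0 & u_old < 0)
  if (length(gone)) owner[gone] <- 0L
  fresh <- which(u_new < 0 & u_old >= 0)
  for (px in fresh) {
    r <- ((px - 1L) %% h) + 1L
    c <- ((px - 1L) %/% h) + 1L
    rs <- max(1L, r - 1L):min(h, r + 1L)
    cs <- max(1L, c - 1L):min(w, c + 1L)
    nb <- owner[rs, cs]
    os <- unique(nb[nb > 0L])
    if (length(os) == 1L) {
      owner[px] <- os
    } else {
      u_new[px] <- 0.5     # veto: meeting point of 0 or >= 2 fronts
    }
  }
  list(u = u_new, owner = owner)
}

# rename final components to the seed label sharing the most area
match_labels_to_seeds <- function(final, seeds) {
  k <- max(final)
  out <- matrix(0L, nrow(final), ncol(final))
  used <- integer(0)
  fresh <- max(seeds)
  for (j in seq_len(k)) {
    m <- final == j
    ov <- seeds[m]
    ov <- ov[ov > 0L]
    lab <- if (length(ov)) {
      tab <- tabulate(ov)
      best <- which.max(tab)
      if (best %in% used) { fresh <- fresh + 1L; fresh } else best
    } else {
      fresh <- fresh + 1L; fresh
    }
    used <- c(used, lab)
    out[m] <- lab
  }
  out
}

#' @export
print.gac_result <- function(x, ...) {
  k <- length(setdiff(unique(as.integer(x$labels)), 0L))
  cat(sprintf("geodesic active-contour result: %d object(s), %d contour(s), %d iteration(s)\n",
              k, length(x$contours), x$iterations))
  invisible(x)
}

#' Extract zero-level contours
#'
#' Marching squares with linear interpolation on the zero level of `u`. The
#' field is padded with a large positive ring so that contours clipped by
#' the frame still close. Each polyline is closed (first vertex repeated
#' last) and oriented with the interior (`u < 0`) on its left.
#'
#' @param u Level-set matrix.
#' @return A list of closed contours, each an M x 2 matrix with columns
#'   `row`, `col` (1-based, fractional).
#' @export
extract_contours <- function(u) {
  if (!all(is.finite(u))) input_error("`u` contains non-finite values")
  h <- nrow(u); w <- ncol(u)
  big <- max(abs(u)) + 1
  p <- matrix(big, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- u
  cl <- grDevices::contourLines(x = 0:(h + 1L), y = 0:(w + 1L), z = p,
                                levels = 0)
  lapply(cl, function(ct) {
    rr <- ct$x; cc <- ct$y
    if (rr[1] != rr[length(rr)] || cc[1] != cc[length(cc)]) {
      rr <- c(rr, rr[1]); cc <- c(cc, cc[1])
    }
    # orient: interior (u < 0) on the left of travel
    mr <- (rr[1] + rr[2]) / 2; mc <- (cc[1] + cc[2]) / 2
    tr <- rr[2] - rr[1]; tc <- cc[2] - cc[1]
    nrm <- sqrt(tr^2 + tc^2)
    # left normal of (tr, tc) in (row, col) coordinates
    lr <- mr - tc / nrm * 0.5; lc <- mc + tr / nrm * 0.5
    if (bilinear_at(p, lr + 1, lc + 1) > 0) { rr <- rev(rr); cc <- rev(cc) }
    cbind(row = rr, col = cc)
  })
}

bilinear_at <- function(m, r, c) {
  r <- min(max(r, 1), nrow(m)); c <- min(max(c, 1), ncol(m))
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nrow(m)); c1 <- min(c0 + 1, ncol(m))
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r1, c0] * fr * (1 - fc) +
    m[r0, c1] * (1 - fr) * fc + m[r1, c1] * fr * fc
}

#' Total length of a contour set
#'
#' @param contours Output of [extract_contours()].
#' @return Summed polyline length in pixel units.
#' @export
contour_length <- function(contours) {
  sum(vapply(contours, function(ct)
    sum(sqrt(diff(ct[, 1])^2 + diff(ct[, 2])^2)), numeric(1)))
}
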