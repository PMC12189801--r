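# Brute-force reference implementations, deliberately naive and independent
# of the package's vectorized/EBImage-backed code paths.

# Euclidean distance transform by exhaustive nearest-background search
edt_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  d <- matrix(0, h, w)
  if (nrow(bg) == 0L) return(d)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j])
      d[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  }
  d
}

# Minkowski erosion/dilation by per-pixel neighborhood scan, out-of-bounds
# treated as background for both operations
morph_oracle <- function(mask, op, footprint) {
  h <- nrow(mask); w <- ncol(mask)
  rad <- (dim(footprint) - 1L) %/% 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- logical(0)
    for (a in -rad[1]:rad[1]) for (b in -rad[2]:rad[2]) {
      if (!footprint[a + rad[1] + 1L, b + rad[2] + 1L]) next
      r <- i + a; c <- j + b
      vals <- c(vals, if (r < 1L || r > h || c < 1L || c > w) FALSE
                      else mask[r, c])
    }
    out[i, j] <- if (op == "erode") all(vals) else any(vals)
  }
  out
}

# connected components by explicit flood fill (stack-based)
flood_fill_oracle <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 8L)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  lab <- matrix(0L, h, w)
  k <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {  # any scan order is fine
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    stack <- list(c(i, j)); lab[i, j] <- k
    while (length(stack)) {
      px <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        r <- px[1] + offs[o, 1]; c <- px[2] + offs[o, 2]
        if (r >= 1L && r <= h && c >= 1L && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# do two label maps define the same partition of the foreground?
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  fg <- a > 0L
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Otsu by trying all 256 cuts on the raw values (class means from the data)
otsu_oracle_mask <- function(gray) {
  v <- as.vector(gray)
  best <- -Inf; best_t <- NA_real_
  for (k in 1:255) {
    t <- k / 256
    lo <- v < t
    if (!any(lo) || all(lo)) next
    bcv <- mean(lo) * (1 - mean(lo)) * (mean(v[lo]) - mean(v[!lo]))^2
    if (bcv > best + 1e-15) { best <- bcv; best_t <- t }
  }
  if (is.na(best_t)) matrix(FALSE, nrow(gray), ncol(gray)) else gray < best_t
}

# quantize a [0,1] image to the 256-bin mid-points so that histogram-based
# and value-based Otsu agree exactly
quantize256 <- function(x) (pmin(floor(x * 256), 255) + 0.5) / 256

angle_deg <- function(a, b) {
  acos(pmin(pmax(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1)) * 180 / pi
}

# deterministic two-overlapping-nuclei scene (circles r = 10, lens depth
# 20% of the radius) rendered through the canonical stain matrix
two_nuclei_fixture <- function(h = 96, w = 120, c1 = 0.85, c2 = 1.10) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  in1 <- (rr - 48)^2 + (cc - 51)^2 <= 100
  in2 <- (rr - 48)^2 + (cc - 69)^2 <= 100
  hc <- c1 * in1 + c2 * in2
  hc[in1 & in2] <- c2
  ec <- ifelse(in1 | in2, 0.05, 0.2)
  m <- default_stain_matrix()
  od <- m %*% rbind(as.vector(hc), as.vector(ec))
  seeds <- matrix(0L, h, w)
  seeds[(rr - 48)^2 + (cc - 48)^2 <= 9] <- 1L
  seeds[(rr - 48)^2 + (cc - 72)^2 <= 9] <- 2L
  truth <- matrix(0L, h, w)
  truth[in1] <- 1L
  truth[in2] <- 2L
  list(image = array(t(10^(-od)), dim = c(h, w, 3L)),
       seeds = seeds, truth = truth, in1 = in1, in2 = in2)
}

# analytic signed distance of a circle, pixel centers at integer coords
circle_sdf <- function(h, center, radius) {
  outer(seq_len(h), seq_len(h),
        function(r, c) sqrt((r - center)^2 + (c - center)^2) - radius)
}

# area enclosed by a closed contour polyline (shoelace)
contour_area <- function(ct) {
  n <- nrow(ct)
  abs(sum(ct[-n, 2] * ct[-1, 1] - ct[-1, 2] * ct[-n, 1]) / 2)
}

random_mask <- function(h, w, p = 0.45, seed) {
  withr::with_seed(seed, matrix(stats::runif(h * w) < p, h, w))
}
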