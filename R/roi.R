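# Circular region-of-interest extraction.
#
# Every slice is standardized by detecting the dominant body circumference
# with a circular Hough transform over an Otsu-thresholded gradient map and
# blacking out everything outside the detected circle. This is the only
# preprocessing the pipeline performs; no lung segmentation is attempted.

#' Circular ROI object
#'
#' @param center Length-2 numeric `(row, col)` center in px (1-based).
#' @param radius Positive radius in px.
#' @param fallback Logical flag: was this circle a fallback rather than a
#'   detection?
#' @return An object of class `circle_roi`.
#' @export
circle_roi <- function(center, radius, fallback = FALSE) {
  center <- as.double(center)
  if (length(center) != 2L || any(!is.finite(center))) {
    stopf("`center` must be (row, col)")
  }
  if (!is.finite(radius) || radius <= 0) stopf("`radius` must be > 0")
  structure(list(center = center, radius = as.double(radius),
                 fallback = isTRUE(fallback)),
            class = "circle_roi")
}

#' @export
print.circle_roi <- function(x, ...) {
  cat(sprintf("<circle_roi> center (%.1f, %.1f), radius %.1f px%s\n",
              x$center[1], x$center[2], x$radius,
              if (x$fallback) " [fallback]" else ""))
  invisible(x)
}

# Otsu's threshold: maximizes between-class variance of a binarized
# histogram. Operates on a 256-bin histogram of `values`.
.otsu_threshold <- function(values, nbins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

# Gradient magnitude by central differences (edges padded with 0 gradient).
.gradient_magnitude <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  gy <- matrix(0, nr, nc)
  gx <- matrix(0, nr, nc)
  if (nr > 2L) gy[2:(nr - 1L), ] <- (px[3:nr, ] - px[1:(nr - 2L), ]) / 2
  if (nc > 2L) gx[, 2:(nc - 1L)] <- (px[, 3:nc] - px[, 1:(nc - 2L)]) / 2
  sqrt(gx^2 + gy^2)
}

#' Detect the body circumference with a circular Hough transform
#'
#' The edge map is the gradient magnitude thresholded at its Otsu level.
#' Each edge pixel votes for candidate centers on circles of every radius in
#' the search range (1-px radius step); the returned circle maximizes the
#' fraction of its perimeter supported by votes. When no candidate reaches
#' the support threshold (e.g. a constant image), the inscribed circle
#' centered on the image is returned with the `fallback` flag set, so the
#' pipeline never aborts on a valid slice.
#'
#' @param image A [ct_image] (or matrix).
#' @param radius_range Length-2 fractions of half the minimum image
#'   dimension delimiting the radius search; default `c(0.6, 1.0)`.
#' @param support_frac Minimum supported fraction of the ideal perimeter
#'   votes for a detection (default 0.25).
#' @param n_angles Number of vote directions per edge pixel.
#' @param max_edges Deterministic cap on the number of edge pixels used.
#' @return A [circle_roi]; `$fallback` tells whether detection succeeded.
#' @export
detect_body_circle <- function(image, radius_range = c(0.6, 1.0),
                               support_frac = 0.25, n_angles = 96L,
                               max_edges = 1500L) {
  image <- as_ct_image(image)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  half_min <- min(nr, nc) / 2
  fallback <- circle_roi(c((nr + 1) / 2, (nc + 1) / 2), half_min,
                         fallback = TRUE)
  if (diff(range(px)) == 0) return(fallback)

  mag <- .gradient_magnitude(px)
  thr <- .otsu_threshold(as.vector(mag))
  edges <- which(mag > thr, arr.ind = TRUE)
  if (nrow(edges) < 8L) return(fallback)
  if (nrow(edges) > max_edges) {
    keep <- round(seq(1L, nrow(edges), length.out = max_edges))
    edges <- edges[keep, , drop = FALSE]
  }

  r_lo <- max(5L, floor(radius_range[1] * half_min))
  r_hi <- max(6L, ceiling(radius_range[2] * half_min))
  theta <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles
  er <- edges[, 1]; ec <- edges[, 2]
  scan_radii <- function(radii) {
    best <- list(score = -Inf, center = NULL, radius = NULL)
    for (R in radii) {
      cy <- round(outer(er, R * cos(theta), `+`))
      cx <- round(outer(ec, R * sin(theta), `+`))
      ok <- cy >= 1L & cy <= nr & cx >= 1L & cx <= nc
      idx <- (cx[ok] - 1L) * nr + cy[ok]
      votes <- tabulate(idx, nbins = nr * nc)
      peak <- which.max(votes)
      # Ideal peak votes: one per sampled direction (or per perimeter pixel
      # if the perimeter is shorter than the direction grid).
      score <- votes[peak] / min(n_angles, 2 * pi * R)
      if (score > best$score) {
        best <- list(score = score,
                     center = c((peak - 1L) %% nr + 1L,
                                (peak - 1L) %/% nr + 1L),
                     radius = R)
      }
    }
    best
  }
  # Coarse radius pass, then 1-px refinement around the coarse winner.
  step <- max(1L, as.integer(round((r_hi - r_lo) / 12)))
  best <- scan_radii(unique(c(seq(r_lo, r_hi, by = step), r_hi)))
  if (step > 1L) {
    fine <- setdiff(max(r_lo, best$radius - step + 1L):
                      min(r_hi, best$radius + step - 1L), best$radius)
    if (length(fine) > 0L) {
      cand <- scan_radii(fine)
      if (cand$score > best$score) best <- cand
    }
  }
  if (best$score < support_frac) return(fallback)
  circle_roi(best$center, best$radius, fallback = FALSE)
}

#' Black out everything outside a circular ROI
#'
#' Pixels at Euclidean distance greater than `roi$radius` from the center
#' are set to 0; interior pixels, shape and spacing are untouched, so the
#' operation is idempotent.
#'
#' @param image A [ct_image] (or matrix).
#' @param roi A [circle_roi].
#' @return A [ct_image] with the exterior blacked out; the ROI is attached
#'   as attribute `"roi"`.
#' @export
apply_roi <- function(image, roi) {
  image <- as_ct_image(image)
  stopifnot(inherits(roi, "circle_roi"))
  px <- image$pixels
  out <- px * roi_mask(dim(px), roi)
  res <- ct_image(out, spacing_mm = image$spacing_mm,
                  source_id = image$source_id)
  attr(res, "roi") <- roi
  res
}

#' Logical mask of pixels inside a circular ROI
#'
#' @param dims Length-2 integer `(rows, cols)`.
#' @param roi A [circle_roi].
#' @return Logical matrix, `TRUE` inside the circle.
#' @export
roi_mask <- function(dims, roi) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (rr - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2
}
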