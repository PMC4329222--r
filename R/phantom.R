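# Synthetic CT phantom: labelled CT-like slices with controllable nodules.
#
# The phantom emulates the geometry the classifier relies on: a bright
# circular body section on a black background, two darker elliptical lung
# fields, and (optionally) one bright round nodule strictly inside a lung
# field. Nodule diameters follow the clinical 2-30 mm range.

#' Phantom generation parameters
#'
#' @param image_size Pixels per side (square slice). Default 128.
#' @param spacing_mm Pixel size in mm (isotropic). Default 0.5 mm, the
#'   spacing of thin-section screening CT.
#' @param body_radius_frac Body-circle radius as a fraction of half the image
#'   width, in (0, 1].
#' @param lung_intensity,body_intensity,background_intensity,nodule_intensity
#'   Gray levels of the four tissue classes. Defaults (60/200/0/230) mimic
#'   the ordering of lung parenchyma, soft tissue, air and solid nodule on a
#'   display-windowed CT.
#' @param nodule_diameter_mm Nodule diameter in mm, within the clinical
#'   2-30 mm nodule range.
#' @param noise_sd Additive Gaussian noise standard deviation; default 2% of
#'   `body_intensity`, enough to give non-degenerate co-occurrence matrices
#'   without burying small nodules.
#' @param seed Integer RNG seed; generation is bitwise reproducible.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 128L, spacing_mm = 0.5,
                           body_radius_frac = 0.9,
                           lung_intensity = 60, body_intensity = 200,
                           background_intensity = 0, nodule_intensity = 230,
                           nodule_diameter_mm = 8, noise_sd = NULL,
                           seed = 1L) {
  if (is.null(noise_sd)) noise_sd <- 0.02 * body_intensity
  image_size <- as.integer(image_size)
  if (image_size < 32L) stopf("`image_size` must be >= 32")
  if (!(body_radius_frac > 0 && body_radius_frac <= 1)) {
    stopf("`body_radius_frac` must be in (0, 1]")
  }
  if (nodule_diameter_mm < 2 || nodule_diameter_mm > 30) {
    stopf("`nodule_diameter_mm` must be in [2, 30]")
  }
  if (spacing_mm <= 0) stopf("`spacing_mm` must be positive")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  ints <- c(lung_intensity, body_intensity, background_intensity,
            nodule_intensity)
  if (!all(is.finite(ints))) stopf("intensities must be finite")
  structure(list(
    image_size = image_size, spacing_mm = spacing_mm,
    body_radius_frac = body_radius_frac,
    lung_intensity = lung_intensity, body_intensity = body_intensity,
    background_intensity = background_intensity,
    nodule_intensity = nodule_intensity,
    nodule_diameter_mm = nodule_diameter_mm,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_params")
}

# Fixed fractional geometry of the two lung fields (axis-aligned ellipses).
# Not randomized, so class differences stay attributable to the nodule.
.LUNG_GEOM <- list(
  center_row_frac = 0.52,
  center_col_frac = c(0.36, 0.64),
  semi_row_frac = 0.22,
  semi_col_frac = 0.13
)

.lung_ellipses <- function(n) {
  lapply(seq_along(.LUNG_GEOM$center_col_frac), function(s) {
    list(center = c(.LUNG_GEOM$center_row_frac * n,
                    .LUNG_GEOM$center_col_frac[s] * n),
         semi = c(.LUNG_GEOM$semi_row_frac * n, .LUNG_GEOM$semi_col_frac * n))
  })
}

#' Generate one labelled phantom slice
#'
#' Deterministic given `(params, with_nodule)`: the nodule location and the
#' noise field both derive from `params$seed`. The nodule is a filled disk of
#' radius `nodule_diameter_mm / (2 * spacing_mm)` px with a 1-px
#' anti-aliased rim, placed at a seeded random location strictly inside a
#' lung field.
#'
#' @param params A [phantom_params] object.
#' @param with_nodule Logical; render a nodule?
#' @return A list with components `image` (a [ct_image]) and `truth` (fields
#'   `has_nodule`, `nodule_center`, `nodule_radius_px`, `body_circle`).
#' @examples
#' p <- phantom_params(seed = 7)
#' s <- generate_slice(p, with_nodule = TRUE)
#' s$truth$nodule_radius_px
#' @export
generate_slice <- function(params, with_nodule = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$image_size
  ctr <- (n + 1) / 2
  r_body <- params$body_radius_frac * n / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)

  img <- matrix(params$background_intensity, n, n)
  body <- (rr - ctr)^2 + (cc - ctr)^2 <= r_body^2
  img[body] <- params$body_intensity
  lungs <- .lung_ellipses(n)
  lung_mask <- matrix(FALSE, n, n)
  for (L in lungs) {
    inside <- ((rr - L$center[1]) / L$semi[1])^2 +
      ((cc - L$center[2]) / L$semi[2])^2 <= 1
    lung_mask <- lung_mask | inside
  }
  img[lung_mask] <- params$lung_intensity

  truth <- list(has_nodule = isTRUE(with_nodule),
                nodule_center = NULL, nodule_radius_px = NULL,
                body_circle = list(center = c(ctr, ctr), radius = r_body))

  with_local_seed(params$seed, {
    if (isTRUE(with_nodule)) {
      r_px <- params$nodule_diameter_mm / (2 * params$spacing_mm)
      if (r_px < 1) {
        stopf("nodule radius %.2f px < 1 px at %.2g mm spacing: unrenderable",
              r_px, params$spacing_mm)
      }
      side <- sample(length(lungs), 1L)
      L <- lungs[[side]]
      # Sample inside the ellipse shrunk so the whole disk (plus AA rim)
      # stays strictly inside the lung field.
      semi <- L$semi - (r_px + 1)
      if (any(semi <= 0)) {
        stopf("nodule (%.1f px radius) too large for the lung fields",
              r_px)
      }
      repeat {
        u <- stats::runif(2, -1, 1)
        if (sum(u^2) <= 1) break
      }
      center <- L$center + u * semi
      dist_nod <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
      cover <- pmin(pmax(r_px + 0.5 - dist_nod, 0), 1)
      sel <- cover > 0
      img[sel] <- img[sel] +
        cover[sel] * (params$nodule_intensity - img[sel])
      truth$nodule_center <- center
      truth$nodule_radius_px <- r_px
    }
    if (params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
    }
  })

  list(image = ct_image(img, spacing_mm = rep(params$spacing_mm, 2),
                        source_id = sprintf("phantom-seed%d-%s", params$seed,
                                            if (isTRUE(with_nodule)) "pos"
                                            else "neg")),
       truth = truth)
}

#' Generate a labelled phantom dataset
#'
#' Produces `n_pos` slices with nodules followed by `n_neg` without; each
#' slice gets its own deterministic seed derived from `params$seed`, so two
#' runs with the same master seed are identical.
#'
#' @param params A [phantom_params]; `params$seed` is the master seed.
#' @param n_pos,n_neg Counts of nodule / nodule-free slices
#'   (`n_pos + n_neg >= 2`).
#' @return An object of class `phantom_set`: list with `slices` (list of
#'   [ct_image]), `labels` (0/1 integer vector), `truths`, `scan_ids` and
#'   `params`.
#' @export
generate_dataset <- function(params, n_pos, n_neg) {
  stopifnot(inherits(params, "phantom_params"))
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (n_pos < 0L || n_neg < 0L || n_pos + n_neg < 2L) {
    stopf("need n_pos + n_neg >= 2 non-negative counts")
  }
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    p_i <- params
    p_i$seed <- derive_seed(params$seed, i)
    out[[i]] <- generate_slice(p_i, with_nodule = labels[i] == 1L)
  }
  structure(list(
    slices = lapply(out, `[[`, "image"),
    labels = labels,
    truths = lapply(out, `[[`, "truth"),
    scan_ids = sprintf("s%03d", seq_along(labels)),
    params = params
  ), class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> %d slices (%d with nodule, %d without), %d px\n",
              length(x$slices), sum(x$labels), sum(x$labels == 0L),
              x$params$image_size))
  invisible(x)
}
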