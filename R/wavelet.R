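# Separable 2-D orthonormal Daubechies wavelet transform.
#
# Periodic ("per") boundary extension is used so the transform is exactly
# orthonormal: perfect reconstruction and Parseval energy conservation hold
# to machine precision, and a constant image has exactly-zero detail bands.
# Odd dimensions are padded to even by edge replication before each level
# and cropped back on reconstruction.

# Orthonormal Daubechies scaling (low-pass) filters; each sums to sqrt(2).
.DB_FILTERS <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.4829629131445341, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  db4 = c(0.2303778133088964, 0.7148465705529154, 0.6308807679298587,
          -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
          0.0328830116668852, -0.0105974017850690)
)

#' Daubechies analysis filters
#'
#' Returns the orthonormal low-pass (scaling) filter `h` and the quadrature
#' mirror high-pass filter `g` (`g_k = (-1)^k h_{L-1-k}`) for the supported
#' families.
#'
#' @param family `"db1"` (Haar), `"db2"` or `"db4"`.
#' @return List with numeric vectors `h` and `g`.
#' @export
daubechies_filter <- function(family = c("db1", "db2", "db4")) {
  family <- match.arg(family)
  h <- .DB_FILTERS[[family]]
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

#' Wavelet decomposition specification
#'
#' @param family Daubechies family: `"db1"`, `"db2"` or `"db4"`.
#' @param levels Decomposition depth `k` (1 or 2 are the supported,
#'   tested depths).
#' @param boundary Boundary extension; only `"periodic"` is implemented (it
#'   preserves orthonormality exactly).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = c("db1", "db2", "db4"), levels = 1L,
                         boundary = "periodic") {
  family <- match.arg(family)
  levels <- as.integer(levels)
  if (levels < 1L) stopf("`levels` must be >= 1")
  boundary <- match.arg(boundary, "periodic")
  structure(list(family = family, levels = levels, boundary = boundary),
            class = "wavelet_spec")
}

# One-level periodized analysis matrices (rows are even shifts of the
# filters), cached per (n, family).
.wavelet_cache <- new.env(parent = emptyenv())

.analysis_matrices <- function(n, family) {
  key <- sprintf("%s-%d", family, n)
  hit <- .wavelet_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- daubechies_filter(family)
  L <- length(f$h)
  stopifnot(n %% 2L == 0L, n >= L)
  H <- matrix(0, n / 2L, n)
  G <- matrix(0, n / 2L, n)
  m <- seq_len(n / 2L)
  for (k in seq_len(L)) {
    cols <- ((2L * (m - 1L) + (k - 1L)) %% n) + 1L
    H[cbind(m, cols)] <- H[cbind(m, cols)] + f$h[k]
    G[cbind(m, cols)] <- G[cbind(m, cols)] + f$g[k]
  }
  out <- list(H = H, G = G)
  .wavelet_cache[[key]] <- out
  out
}

.pad_even <- function(X) {
  orig <- dim(X)
  if (nrow(X) %% 2L == 1L) X <- rbind(X, X[nrow(X), , drop = FALSE])
  if (ncol(X) %% 2L == 1L) X <- cbind(X, X[, ncol(X), drop = FALSE])
  list(X = X, orig = orig)
}

.dwt2_step <- function(X, family) {
  L <- length(.DB_FILTERS[[family]])
  p <- .pad_even(X)
  X <- p$X
  if (min(dim(X)) < L) {
    stopf("image of size %dx%d is smaller than the %s filter support (%d)",
          p$orig[1], p$orig[2], family, L)
  }
  Mr <- .analysis_matrices(nrow(X), family)
  Mc <- .analysis_matrices(ncol(X), family)
  A <- Mr$H %*% X   # low-pass along the row (vertical) direction
  D <- Mr$G %*% X   # high-pass along the row (vertical) direction
  list(LL = A %*% t(Mc$H),
       LH = A %*% t(Mc$G),  # vertical detail (high horizontal frequency)
       HL = D %*% t(Mc$H),  # horizontal detail
       HH = D %*% t(Mc$G),  # diagonal detail
       orig = p$orig)
}

.idwt2_step <- function(LL, LH, HL, HH, family, orig) {
  Mr <- .analysis_matrices(2L * nrow(LL), family)
  Mc <- .analysis_matrices(2L * ncol(LL), family)
  A <- LL %*% Mc$H + LH %*% Mc$G
  D <- HL %*% Mc$H + HH %*% Mc$G
  X <- t(Mr$H) %*% A + t(Mr$G) %*% D
  X[seq_len(orig[1]), seq_len(orig[2]), drop = FALSE]
}

#' Decompose an image into Daubechies wavelet sub-bands
#'
#' Separable 2-D orthonormal DWT with periodic extension; the LL band is
#' recursively decomposed up to `levels`. Sub-band labels follow the usual
#' convention: at depth `k = 1` the set is `LL1, LH1, HL1, HH1`; at `k = 2`
#' it is `LL2, LH2, HL2, HH2, LH1, HL1, HH1`. `LH` holds the vertical
#' detail, `HL` the horizontal and `HH` the diagonal.
#'
#' @param image A [ct_image] or numeric matrix, at least as large as the
#'   filter support.
#' @param family Daubechies family (`"db1"`, `"db2"`, `"db4"`).
#' @param levels Decomposition depth `k` (1 or 2 tested).
#' @return An object of class `subband_set`: list with `bands` (named list
#'   of coefficient matrices), `spec` (a [wavelet_spec]) and `dims`
#'   (per-level pre-padding dimensions used to crop on reconstruction).
#' @examples
#' sb <- decompose(matrix(1:16, 4, 4), "db1", levels = 1)
#' names(sb$bands)
#' @export
decompose <- function(image, family = c("db1", "db2", "db4"), levels = 1L) {
  if (inherits(family, "wavelet_spec")) {
    levels <- family$levels
    family <- family$family
  } else {
    family <- match.arg(family)
  }
  levels <- as.integer(levels)
  X <- if (inherits(image, "ct_image")) image$pixels else as.matrix(image)
  spec <- wavelet_spec(family, levels)
  bands <- list()
  dims <- vector("list", levels)
  cur <- X
  for (j in seq_len(levels)) {
    st <- .dwt2_step(cur, family)
    dims[[j]] <- st$orig
    bands[[paste0("LH", j)]] <- st$LH
    bands[[paste0("HL", j)]] <- st$HL
    bands[[paste0("HH", j)]] <- st$HH
    cur <- st$LL
  }
  bands[[paste0("LL", levels)]] <- cur
  bands <- bands[subband_labels(levels)]
  structure(list(bands = bands, spec = spec, dims = dims),
            class = "subband_set")
}

#' Sub-band labels for a decomposition depth
#'
#' @param levels Depth `k`.
#' @return Character vector: 4 labels for `k = 1`, 7 for `k = 2` (3k + 1 in
#'   general), coarsest first.
#' @export
subband_labels <- function(levels) {
  levels <- as.integer(levels)
  out <- paste0("LL", levels)
  for (j in rev(seq_len(levels))) {
    out <- c(out, paste0(c("LH", "HL", "HH"), j))
  }
  out
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %s, k=%d: %s\n", x$spec$family, x$spec$levels,
              paste(sprintf("%s[%dx%d]", names(x$bands),
                            vapply(x$bands, nrow, integer(1)),
                            vapply(x$bands, ncol, integer(1))),
                    collapse = " ")))
  invisible(x)
}

#' Invert a wavelet decomposition
#'
#' Exact inverse of [decompose()] (used mainly for validation; the texture
#' descriptor works on the coefficients directly).
#'
#' @param subbands A `subband_set` from [decompose()].
#' @return The reconstructed numeric matrix.
#' @export
reconstruct <- function(subbands) {
  stopifnot(inherits(subbands, "subband_set"))
  k <- subbands$spec$levels
  need <- subband_labels(k)
  missing <- setdiff(need, names(subbands$bands))
  if (length(missing) > 0L) {
    stopf("missing sub-band(s): %s", paste(missing, collapse = ", "))
  }
  cur <- subbands$bands[[paste0("LL", k)]]
  for (j in rev(seq_len(k))) {
    cur <- .idwt2_step(cur,
                       subbands$bands[[paste0("LH", j)]],
                       subbands$bands[[paste0("HL", j)]],
                       subbands$bands[[paste0("HH", j)]],
                       subbands$spec$family, subbands$dims[[j]])
  }
  cur
}
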