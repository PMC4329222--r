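# GLCM texture descriptor in the wavelet domain.
#
# Each sub-band is linearly quantized to Ng gray levels (default 8), a
# symmetric normalized gray-level co-occurrence matrix is accumulated at
# each displacement angle (distance d = 1 by default), and 19 scalar
# texture statistics are computed from it. Pixels outside the circular ROI
# are excluded from both quantization and pair counting, so the black
# exterior does not dominate the (0,0) cell; this is switchable via the
# `mask` argument for fidelity experiments.
#
# Index convention: GLCM rows/cols are 1-based gray levels i, j in 1..Ng
# (classic Haralick). Natural logarithms throughout; 0 * log 0 = 0.

#' Canonical GLCM feature names
#'
#' The 19 texture statistics, in the fixed order used throughout the
#' package: autocorrelation, contrast, correlation, cluster prominence,
#' cluster shade, dissimilarity, energy, entropy, homogeneity, maximum
#' probability, sum variance, sum average, variance, sum entropy,
#' difference variance, difference entropy, the two information measures of
#' correlation, and inverse difference moment.
#'
#' @return Character vector of length 19.
#' @export
glcm_feature_names <- function() {
  c("Autc", "Cont", "Corr", "Clpr", "Clsh", "Diss", "Ener", "Ent", "Homo",
    "Mp", "Svar", "Sav", "Var", "Sent", "Diffv", "Diffe", "Imc1", "Imc2",
    "Idm")
}

#' Quantize a coefficient matrix to Ng gray levels
#'
#' Linear min-max binning of the unmasked values into `n_gray` equal-width
#' bins (`0 .. n_gray - 1`); the maximum maps to bin `n_gray - 1`. A
#' constant band maps to all zeros and is flagged degenerate. Masked pixels
#' become `NA` and never enter co-occurrence counts.
#'
#' @param band Numeric matrix (wavelet coefficients or raw intensities).
#' @param mask Optional logical matrix, `TRUE` for valid pixels.
#' @param n_gray Number of gray levels (>= 2); default 8.
#' @return Object of class `quantized_image`: list with integer matrix `q`
#'   (`NA` outside the mask), `n_gray`, `degenerate`.
#' @examples
#' quantize(matrix(0:7, 2, 4))$q
#' @export
quantize <- function(band, mask = NULL, n_gray = 8L) {
  band <- as.matrix(band)
  n_gray <- as.integer(n_gray)
  if (n_gray < 2L) stopf("`n_gray` must be >= 2")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(band), ncol(band))
  if (!identical(dim(mask), dim(band))) stopf("mask/band dimension mismatch")
  vals <- band[mask]
  if (length(vals) == 0L) stopf("no unmasked pixels to quantize")
  lo <- min(vals); hi <- max(vals)
  degenerate <- (hi == lo)
  q <- matrix(NA_integer_, nrow(band), ncol(band))
  if (degenerate) {
    q[mask] <- 0L
  } else {
    bins <- floor((band[mask] - lo) / (hi - lo) * n_gray)
    q[mask] <- as.integer(pmin(bins, n_gray - 1L))
  }
  structure(list(q = q, n_gray = n_gray, degenerate = degenerate),
            class = "quantized_image")
}

# Displacement (d_row, d_col) for each GLCM angle, distance d.
.glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stopf("unsupported GLCM angle %s (use 0, 45, 90, 135)", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray levels at the angle's displacement
#' (0 deg: (0, d); 45: (-d, d); 90: (-d, 0); 135: (-d, -d)), skipping pairs
#' that touch masked or out-of-bounds pixels, symmetrized by accumulating
#' both directions and normalized to sum 1.
#'
#' @param q A [quantize()d][quantize] image (or an integer matrix of gray
#'   levels `0 .. n_gray - 1`).
#' @param angle Displacement angle in degrees: 0, 45, 90 or 135.
#' @param distance Displacement length in pixels (default 1).
#' @param n_gray Gray-level count, required when `q` is a bare matrix.
#' @return Object of class `glcm`: list with `P` (Ng x Ng probability
#'   matrix), `angle`, `distance`, `n_gray`, `symmetric = TRUE`,
#'   `n_pairs` (directed pair count).
#' @export
glcm <- function(q, angle, distance = 1L, n_gray = NULL) {
  if (!inherits(q, "quantized_image")) {
    qm <- as.matrix(q)
    if (is.null(n_gray)) n_gray <- max(qm, na.rm = TRUE) + 1L
    q <- structure(list(q = qm, n_gray = as.integer(n_gray),
                        degenerate = FALSE), class = "quantized_image")
  }
  ng <- q$n_gray
  d <- as.integer(distance)
  off <- .glcm_offset(angle, d)
  m <- q$q
  nr <- nrow(m); nc <- ncol(m)
  r_src <- seq_len(nr)[seq_len(nr) + off[1] >= 1L & seq_len(nr) + off[1] <= nr]
  c_src <- seq_len(nc)[seq_len(nc) + off[2] >= 1L & seq_len(nc) + off[2] <= nc]
  if (length(r_src) == 0L || length(c_src) == 0L) {
    stopf("image too small for displacement (%d, %d)", off[1], off[2])
  }
  v1 <- m[r_src, c_src, drop = FALSE]
  v2 <- m[r_src + off[1], c_src + off[2], drop = FALSE]
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) stopf("zero valid co-occurrence pairs at this displacement")
  counts <- tabulate(v1[ok] * ng + v2[ok] + 1L, nbins = ng * ng)
  C <- matrix(counts, ng, ng, byrow = TRUE)  # row = first pixel level
  C <- C + t(C)
  structure(list(P = C / sum(C), angle = angle, distance = d, n_gray = ng,
                 symmetric = TRUE, n_pairs = sum(ok)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, angle %s, d=%d, %d directed pairs\n",
              x$n_gray, x$angle, x$distance, x$n_pairs))
  print(round(x$P, 4))
  invisible(x)
}

#' Marginal quantities of a GLCM
#'
#' Row/column marginals `px`, `py`, their means and standard deviations,
#' the sum distribution `p_{x+y}(k)` for `k = 2 .. 2 Ng` with its mean
#' `saver`, the difference distribution `p_{x-y}(m)` for `m = 0 .. Ng - 1`
#' with its mean, and the entropy terms `HX`, `HY`, `HXY`, `HXY1`, `HXY2`.
#' All indices are 1-based gray levels.
#'
#' @param g A [glcm].
#' @return Object of class `glcm_marginals`.
#' @export
glcm_marginals <- function(g) {
  stopifnot(inherits(g, "glcm"))
  P <- g$P
  ng <- g$n_gray
  i <- seq_len(ng)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sigma_x <- sqrt(sum((i - mu_x)^2 * px))
  sigma_y <- sqrt(sum((i - mu_y)^2 * py))
  SUM <- outer(i, i, `+`)     # values 2 .. 2Ng
  DIF <- abs(outer(i, i, `-`))
  p_sum <- vapply(2:(2 * ng), function(k) sum(P[SUM == k]), numeric(1))
  p_diff <- vapply(0:(ng - 1), function(m) sum(P[DIF == m]), numeric(1))
  saver <- sum((2:(2 * ng)) * p_sum)
  mu_diff <- sum((0:(ng - 1)) * p_diff)
  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  HXY <- -sum(xlogx(P))
  PXPY <- outer(px, py)
  pos <- P > 0  # p > 0 implies px, py > 0, so log is safe
  HXY1 <- -sum(P[pos] * log(PXPY[pos]))
  HXY2 <- -sum(xlogx(PXPY))
  structure(list(px = px, py = py, mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 p_sum = p_sum, p_diff = p_diff, saver = saver,
                 mu_diff = mu_diff, HX = HX, HY = HY, HXY = HXY,
                 HXY1 = HXY1, HXY2 = HXY2),
            class = "glcm_marginals")
}

#' The 19 GLCM texture features
#'
#' Computes, with 1-based gray-level indices and natural logarithms:
#' \itemize{
#' \item `Autc` = sum i j p(i,j) (autocorrelation)
#' \item `Cont` = sum (i-j)^2 p; `Diss` = sum |i-j| p
#' \item `Corr` = (Autc - mu_x mu_y) / (sigma_x sigma_y); 0 when degenerate
#' \item `Clpr` / `Clsh` = sum (i+j-mu_x-mu_y)^{4 / 3} p
#' \item `Ener` = sqrt(sum p^2); `Mp` = max p; `Ent` = -sum p log p
#' \item `Homo` = sum p / (1 + |i-j|); `Idm` = sum p / (1 + (i-j)^2)
#' \item `Sav` = sum k p_{x+y}(k); `Svar` = sum (k - Sav)^2 p_{x+y}(k);
#'   `Sent` = -sum p_{x+y} log p_{x+y}
#' \item `Var` = sum (i - mu)^2 p with mu the GLCM mean gray level
#' \item `Diffv` = sum (m - mu_{x-y})^2 p_{x-y}(m);
#'   `Diffe` = -sum p_{x-y} log p_{x-y}
#' \item `Imc1` = (HXY - HXY1) / max(HX, HY);
#'   `Imc2` = sqrt(1 - exp(-2 (HXY2 - HXY))); both 0 when degenerate
#' }
#'
#' @param g A [glcm].
#' @param m Optional precomputed [glcm_marginals].
#' @return Named numeric vector of length 19 (order of
#'   [glcm_feature_names()]); every value is finite for every valid GLCM,
#'   including degenerate single-cell ones.
#' @export
compute_features <- function(g, m = glcm_marginals(g)) {
  P <- g$P
  ng <- g$n_gray
  i <- seq_len(ng)
  IJ <- outer(i, i)
  DIF <- outer(i, i, `-`)
  SUM <- outer(i, i, `+`)
  ks <- 2:(2 * ng)
  ms <- 0:(ng - 1)

  autc <- sum(IJ * P)
  corr <- if (m$sigma_x > 0 && m$sigma_y > 0) {
    (autc - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  } else 0
  sav <- sum(ks * m$p_sum)
  imc1 <- if (max(m$HX, m$HY) > 0) (m$HXY - m$HXY1) / max(m$HX, m$HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (m$HXY2 - m$HXY))))

  c(Autc = autc,
    Cont = sum(DIF^2 * P),
    Corr = corr,
    Clpr = sum((SUM - m$mu_x - m$mu_y)^4 * P),
    Clsh = sum((SUM - m$mu_x - m$mu_y)^3 * P),
    Diss = sum(abs(DIF) * P),
    Ener = sqrt(sum(P^2)),
    Ent = -sum(xlogx(P)),
    Homo = sum(P / (1 + abs(DIF))),
    Mp = max(P),
    Svar = sum((ks - sav)^2 * m$p_sum),
    Sav = sav,
    Var = sum((i - m$mu_x)^2 * m$px),
    Sent = -sum(xlogx(m$p_sum)),
    Diffv = sum((ms - m$mu_diff)^2 * m$p_diff),
    Diffe = -sum(xlogx(m$p_diff)),
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + DIF^2)))
}

# Degenerate stand-in: the feature vector of a single-cell GLCM, used when a
# masked sub-band yields no valid co-occurrence pair.
.degenerate_features <- function() {
  f <- c(Autc = 1, Cont = 0, Corr = 0, Clpr = 0, Clsh = 0, Diss = 0,
         Ener = 1, Ent = 0, Homo = 1, Mp = 1, Svar = 0, Sav = 2, Var = 0,
         Sent = 0, Diffv = 0, Diffe = 0, Imc1 = 0, Imc2 = 0, Idm = 1)
  f[glcm_feature_names()]
}

# Shrink a validity mask by one dyadic level: a coefficient is valid when
# its whole 2x2 source block is inside the ROI (conservative).
.shrink_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr %% 2L == 1L) mask <- rbind(mask, FALSE)
  if (nc %% 2L == 1L) mask <- cbind(mask, FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE] &
    mask[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE] &
    mask[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE] &
    mask[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]
  m
}

#' Extract the wavelet-GLCM texture descriptor of a slice
#'
#' For every requested Daubechies family the slice is decomposed to depth
#' `levels`; every sub-band is quantized and a GLCM is accumulated at every
#' requested angle; the 19 texture features of each GLCM are concatenated
#' into one flat named vector. Names follow
#' `<family>.<levels>.<subband>.<angle>.<feature>` in a fixed, documented
#' order, so the descriptor length is
#' `19 * #subbands * #angles * #families` (e.g. 76 for one family, one
#' angle, depth 1; 912 for three families, four angles, depth 1; 1596 for
#' the depth-2 analogue).
#'
#' @param image A [ct_image] or matrix (typically the ROI-masked slice).
#' @param families Character vector of Daubechies families.
#' @param levels Decomposition depth `k` (scalar).
#' @param angles GLCM angles in degrees.
#' @param n_gray Gray levels for quantization (default 8).
#' @param roi Optional [circle_roi]; when given, pixels outside it are
#'   excluded from quantization and pair counting (the mask is shrunk
#'   dyadically to each sub-band's grid).
#' @param distance GLCM displacement length (default 1).
#' @return Named numeric vector. Degenerate sub-bands yield the defined
#'   single-cell feature values rather than an error.
#' @export
extract_descriptor <- function(image, families = c("db1", "db2", "db4"),
                               levels = 1L, angles = c(0, 45, 90, 135),
                               n_gray = 8L, roi = NULL, distance = 1L) {
  image <- as_ct_image(image)
  levels <- as.integer(levels)
  bad <- setdiff(families, names(.DB_FILTERS))
  if (length(bad) > 0L) {
    stopf("unknown wavelet family: %s", paste(bad, collapse = ", "))
  }
  mask0 <- if (is.null(roi)) NULL else roi_mask(dim(image$pixels), roi)
  out <- numeric(0)
  for (fam in families) {
    sb <- decompose(image, fam, levels)
    masks <- NULL
    if (!is.null(mask0)) {
      masks <- vector("list", levels)
      cur <- mask0
      for (j in seq_len(levels)) {
        cur <- .shrink_mask(cur)
        masks[[j]] <- cur
      }
    }
    for (band in subband_labels(levels)) {
      j <- as.integer(sub("^[A-Z]+", "", band))
      bmask <- if (is.null(masks)) NULL else masks[[j]]
      q <- tryCatch(quantize(sb$bands[[band]], mask = bmask, n_gray = n_gray),
                    error = function(e) NULL)
      for (ang in angles) {
        feats <- if (is.null(q)) .degenerate_features() else {
          tryCatch(compute_features(glcm(q, ang, distance = distance)),
                   error = function(e) .degenerate_features())
        }
        names(feats) <- sprintf("%s.%d.%s.%s.%s", fam, levels, band, ang,
                                glcm_feature_names())
        out <- c(out, feats)
      }
    }
  }
  out
}
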