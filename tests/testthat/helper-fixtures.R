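# Fixtures built in code: rendered circles, handcrafted DICOM bytes,
# synthetic selection problems. Everything deterministic.

render_ring <- function(n, center, radius, width = 0.6, value = 100) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  img <- matrix(0, n, n)
  img[abs(d - radius) < width] <- value
  img
}

render_disk <- function(n, center, radius, value = 100) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- matrix(0, n, n)
  img[(rr - center[1])^2 + (cc - center[2])^2 <= radius^2] <- value
  img
}

# Brute-force circle-fit oracle: over a coarse center/radius grid, count
# edge pixels lying within 0.7 px of the candidate circle and return the
# argmax. Independent of the Hough accumulator implementation.
brute_circle_oracle <- function(img, centers_r, centers_c, radii) {
  edges <- which(img > 0, arr.ind = TRUE)
  best <- c(NA, NA, NA); best_n <- -1
  for (cy in centers_r) for (cx in centers_c) {
    d <- sqrt((edges[, 1] - cy)^2 + (edges[, 2] - cx)^2)
    for (R in radii) {
      n_on <- sum(abs(d - R) < 0.7)
      if (n_on > best_n) {
        best_n <- n_on
        best <- c(cy, cx, R)
      }
    }
  }
  best
}

# Brute-force symmetric GLCM by explicit pair enumeration (both directions).
brute_glcm <- function(q, angle, d, ng) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  C <- matrix(0, ng, ng)
  for (r in seq_len(nrow(q))) {
    for (cl in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cl + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
          !is.na(q[r, cl]) && !is.na(q[r2, c2])) {
        i <- q[r, cl] + 1L; j <- q[r2, c2] + 1L
        C[i, j] <- C[i, j] + 1
        C[j, i] <- C[j, i] + 1
      }
    }
  }
  C / sum(C)
}

# 3 informative + 3 pure-noise features; class decided by the sign of the
# informative sum plus small noise.
make_selection_data <- function(seed, n = 80L, delta = 1.5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  info <- sapply(1:3, function(i) (2 * y - 1) * delta + rnorm(n))
  noise <- matrix(rnorm(n * 3), n, 3)
  x <- cbind(info, noise)
  colnames(x) <- c(paste0("inf", 1:3), paste0("noise", 1:3))
  feature_matrix(x, y)
}

# Exhaustive CFS oracle: best merit over all non-empty subsets.
exhaustive_best_merit <- function(fm) {
  feats <- colnames(fm$x)
  best <- -Inf
  for (k in seq_along(feats)) {
    subs <- utils::combn(feats, k)
    for (s in seq_len(ncol(subs))) {
      best <- max(best, cfs_merit(fm, subs[, s]))
    }
  }
  best
}

# Handcrafted minimal DICOM bytes (independent of the package writer).
# Produces a square image of constant `raw_value` with the given rescale.
make_test_dicom <- function(path, n = 4L, raw_value = 1024L, slope = 1,
                            intercept = -1024, spacing = "0.5\\0.5",
                            implicit = FALSE, instance = NULL) {
  u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32 <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L,
                              (x %/% 65536L) %% 256L, x %/% 16777216L))
  pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) c(r, as.raw(0L)) else r
  }
  el_explicit <- function(grp, ele, vr, val) {
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT", "OF")) {
      c(u16(grp), u16(ele), charToRaw(vr), as.raw(c(0, 0)),
        u32(length(val)), val)
    } else {
      c(u16(grp), u16(ele), charToRaw(vr), u16(length(val)), val)
    }
  }
  el_implicit <- function(grp, ele, vr, val) {
    c(u16(grp), u16(ele), u32(length(val)), val)
  }
  el <- if (implicit) el_implicit else el_explicit
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta_body <- el_explicit(0x0002, 0x0010, "UI", pad(ts))
  meta <- c(el_explicit(0x0002, 0x0000, "UL", u32(length(meta_body))),
            meta_body)
  pix <- do.call(c, rep(list(u16(raw_value)), n * n))
  ds <- raw(0)
  if (!is.null(instance)) {
    ds <- c(ds, el(0x0020, 0x0013, "IS", pad(as.character(instance))))
  }
  ds <- c(ds,
          el(0x0028, 0x0010, "US", u16(n)),
          el(0x0028, 0x0011, "US", u16(n)),
          if (!is.null(spacing)) el(0x0028, 0x0030, "DS", pad(spacing)),
          el(0x0028, 0x0100, "US", u16(16L)),
          el(0x0028, 0x0103, "US", u16(0L)),
          el(0x0028, 0x1052, "DS", pad(as.character(intercept))),
          el(0x0028, 0x1053, "DS", pad(as.character(slope))),
          el(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), path)
  invisible(path)
}

# Small well-separated 2-D two-class training set.
make_separable <- function(seed, n_per = 40L, gap = 6) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per, gap / 2), n_per, 2),
             matrix(rnorm(2 * n_per, -gap / 2), n_per, 2))
  colnames(X) <- c("f1", "f2")
  feature_matrix(X, rep(c(1L, 0L), each = n_per))
}
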