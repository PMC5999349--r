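# Brightness and Haralick texture features of the grayscale pixels inside
# a contour.

#' Construct an image patch
#'
#' A grayscale patch covering (at least) the bounding box of a contour,
#' stored as an integer matrix with an origin offset so that patch pixel
#' `[r, c]` has center coordinates `(origin[1] + c - 1, origin[2] + r - 1)`
#' in the contour's pixel frame.
#'
#' @param values Integer matrix of gray values in `[0, max_value]`
#'   (rows = y, columns = x).
#' @param origin Length-2 numeric, pixel coordinates `(x, y)` of the
#'   patch's first pixel center. Default `c(0, 0)`.
#' @param max_value Declared bit-depth ceiling (default 255).
#' @return An `rtdc_patch` object.
#' @export
image_patch <- function(values, origin = c(0, 0), max_value = 255L) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("patch values must be finite", call. = FALSE)
  if (any(values < 0) || any(values > max_value)) {
    stop("patch values outside the declared bit depth", call. = FALSE)
  }
  structure(list(values = values, origin = as.numeric(origin),
                 max_value = as.integer(max_value)),
            class = "rtdc_patch")
}

#' @export
print.rtdc_patch <- function(x, ...) {
  cat(sprintf("<rtdc_patch> %d x %d pixels, origin (%g, %g), max %d\n",
              nrow(x$values), ncol(x$values), x$origin[1L], x$origin[2L],
              x$max_value))
  invisible(x)
}

# Logical mask of patch pixels whose centers lie inside the contour
# (even-odd rule), in patch matrix layout.
patch_mask <- function(patch, ct) {
  assert_contour(ct)
  nr <- nrow(patch$values); nc <- ncol(patch$values)
  px <- patch$origin[1L] + rep(seq_len(nc) - 1L, each = nr)
  py <- patch$origin[2L] + rep(seq_len(nr) - 1L, times = nc)
  matrix(points_in_polygon(px, py, contour_matrix(ct)), nrow = nr, ncol = nc)
}

#' Brightness statistics inside a contour
#'
#' Mean and standard deviation of the raw gray values whose pixel centers
#' lie inside the contour. No background correction is applied.
#'
#' @param patch An [image_patch()].
#' @param ct The [contour()] delimiting the cell.
#' @return Named vector `c(mean, sd)`; `sd` is 0 for a single in-mask pixel.
#' @export
patch_brightness <- function(patch, ct) {
  mask <- patch_mask(patch, ct)
  vals <- patch$values[mask]
  if (length(vals) == 0L) {
    stop("no pixel centers fall inside the contour", call. = FALSE)
  }
  s <- if (length(vals) > 1L) stats::sd(vals) * sqrt((length(vals) - 1) / length(vals)) else 0
  c(mean = mean(vals), sd = s)
}

# Symmetric, normalized gray-level co-occurrence matrix from distance-1
# pixel pairs with both pixels in-mask, accumulated over the 4 unique
# offsets (E, SE, S, SW). Gray values are re-binned to n_levels equal-width
# bins over [0, max_value].
glcm <- function(patch, ct, n_levels = 16L) {
  mask <- patch_mask(patch, ct)
  # bin to 1..n_levels over the declared bit depth
  lev <- pmin(floor(patch$values / (patch$max_value + 1L) * n_levels) + 1L,
              n_levels)
  nr <- nrow(lev); nc <- ncol(lev)
  cm <- matrix(0, n_levels, n_levels)
  offsets <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))  # (dr, dc)
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    # symmetric accumulation
    for (kk in seq_along(ia)) {
      cm[ia[kk], ib[kk]] <- cm[ia[kk], ib[kk]] + 1
      cm[ib[kk], ia[kk]] <- cm[ib[kk], ia[kk]] + 1
    }
  }
  tot <- sum(cm)
  if (tot == 0) {
    stop("contour mask too small: no in-mask neighbor pixel pairs", call. = FALSE)
  }
  cm / tot
}

#' The 13 Haralick texture features
#'
#' Classical texture statistics of the gray-level co-occurrence matrix
#' (GLCM) built from neighboring pixel pairs that both lie inside the
#' contour. Pairs at distance 1 are accumulated symmetrically over the four
#' unique offsets; gray values are re-binned to `n_levels` equal-width bins
#' over the declared bit depth.
#'
#' @inheritParams patch_brightness
#' @param n_levels Number of gray-level bins (default 16).
#' @return Named numeric vector of length 13, in the fixed order:
#'   `asm` (angular second moment), `contrast`, `correlation`,
#'   `variance` (sum of squares), `idm` (inverse difference moment),
#'   `sum_average`, `sum_variance`, `sum_entropy`, `entropy`,
#'   `diff_variance`, `diff_entropy`, `imc1`, `imc2` (information measures
#'   of correlation).
#' @export
patch_haralick <- function(patch, ct, n_levels = 16L) {
  p <- glcm(patch, ct, n_levels = n_levels)
  haralick_from_glcm(p)
}

# Features from a normalized symmetric GLCM. log2; 0*log(0) treated as 0.
haralick_from_glcm <- function(p) {
  g <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(g) * px); mu_y <- sum(seq_len(g) * py)
  sd_x <- sqrt(sum((seq_len(g) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(g) - mu_y)^2 * py))
  xlog <- function(z) ifelse(z > 0, log2(z), 0)

  # p_{x+y}(k), k = 2..2g ; p_{x-y}(k), k = 0..g-1
  pxy_sum <- vapply(2:(2 * g), function(k) sum(p[i + j == k]), numeric(1))
  pxy_diff <- vapply(0:(g - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))

  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  variance <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  ks <- 2:(2 * g)
  sum_average <- sum(ks * pxy_sum)
  sum_entropy <- -sum(pxy_sum * xlog(pxy_sum))
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  entropy <- -sum(p * xlog(p))
  kd <- 0:(g - 1)
  diff_avg <- sum(kd * pxy_diff)
  diff_variance <- sum((kd - diff_avg)^2 * pxy_diff)
  diff_entropy <- -sum(pxy_diff * xlog(pxy_diff))
  # information measures of correlation
  pxpy <- outer(px, py)
  hxy <- entropy
  hxy1 <- -sum(p * xlog(pxpy))
  hxy2 <- -sum(pxpy * xlog(pxpy))
  hx <- -sum(px * xlog(px)); hy <- -sum(py * xlog(py))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}
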