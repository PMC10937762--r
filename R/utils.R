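#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Channel roles understood throughout the package.
CHANNEL_ROLES <- c("nucleus_dye", "neuron_marker", "sting", "effector", "layer_marker")

#' Derive a stream-specific RNG seed from a master seed
#'
#' All stochastic stages split one master seed into independent streams keyed
#' by a label, so that a single `--seed` reproduces the whole analysis while
#' stages stay decoupled (adding fields to one group does not perturb another).
#'
#' @param master integer master seed.
#' @param label character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  v <- utf8ToInt(paste(label, collapse = "/"))
  # order-sensitive polynomial hash, kept exact in doubles (< 2^53)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 7919 + h * 104729) %% 2147483647)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r_src <- max(1, 1 - dr):min(h, h - dr)
  c_src <- max(1, 1 - dc):min(w, w - dc)
  if (length(r_src) == 0L || length(c_src) == 0L) return(out)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

# Integer pixel offsets of a disk (or annulus) around a centre, by Euclidean
# distance measured between pixel centres.
disk_offsets <- function(r_outer, r_inner = -1) {
  r <- ceiling(r_outer)
  dd <- expand.grid(dr = -r:r, dc = -r:r)
  d <- sqrt(dd$dr^2 + dd$dc^2)
  dd[d <= r_outer & d > r_inner, , drop = FALSE]
}

# Count of pixels of a disk/annulus (unclipped).
annulus_area <- function(r_outer, r_inner = -1) nrow(disk_offsets(r_outer, r_inner))

# Linear (column-major) indices of a disk/annulus clipped to an h x w image.
annulus_indices <- function(h, w, row, col, r_outer, r_inner = -1) {
  off <- disk_offsets(r_outer, r_inner)
  rr <- row + off$dr
  cc <- col + off$dc
  keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  rr[keep] + (cc[keep] - 1L) * h
}

# Robust background level of a channel: cells are sparse, so the median is the
# background plateau and the MAD its spread. Large channels are subsampled on
# a regular lattice; the estimate is deterministic.
background_level <- function(channel, k = 2, max_px = 65536L) {
  v <- as.numeric(channel)
  if (length(v) > max_px)
    v <- v[seq.int(1L, length(v), length.out = max_px)]
  stats::median(v) + k * stats::mad(v)
}

# 1-D Otsu threshold on a numeric vector (maximise between-class variance over
# candidate cuts at midpoints of sorted unique values).
otsu_vector <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(suppressWarnings(max(x, -Inf)))
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); total <- w[n_bins]
  m <- cumsum(h * mids); mt <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0[valid] - total * m[-n_bins][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  # well-separated mixtures give a plateau of equally good cuts across the
  # empty gap; take its centre, not its edge, so neither cluster's noise
  # tail crosses the threshold
  best <- which(bcv >= max(bcv) * (1 - 1e-9))
  mean(mids[-n_bins][best])
}

# Separable Gaussian blur (kernel radius 3*sigma, borders renormalised),
# computed as two banded-matrix products so BLAS does the work; the banded
# operators are cached per (size, sigma). Much cheaper than an FFT at these
# kernel sizes.
.blur_cache <- new.env(parent = emptyenv())

blur_operator <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  K <- .blur_cache[[key]]
  if (is.null(K)) {
    r <- max(1L, ceiling(3 * sigma))
    K <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n - abs(d))
      K[cbind(i + max(0, d), i + max(0, -d))] <- stats::dnorm(d, sd = sigma)
    }
    K <- K / rowSums(K)
    .blur_cache[[key]] <- K
  }
  K
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  blur_operator(nrow(m), sigma) %*% m %*% t(blur_operator(ncol(m), sigma))
}

# Significance stars used throughout figure legends in this field.
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
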