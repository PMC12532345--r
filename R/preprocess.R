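#' Average A-scan of a B-scan
#'
#' Lateral mean over all columns, yielding a single axial intensity profile.
#'
#' @param bscan A `bscan` object or a depth x lateral matrix.
#' @return Numeric vector of length `n_depth_pixels`.
#' @export
average_ascan <- function(bscan) {
  img <- if (inherits(bscan, "bscan")) bscan$intensity else bscan
  stopifnot(is.matrix(img))
  rowMeans(img)
}

# 1D Gaussian smoothing with 'reflect' boundary handling
gaussian_smooth1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  r_eff <- min(r, n - 1L)
  pad <- c(x[(r_eff + 1):2], x, x[(n - 1):(n - r_eff)])
  if (r_eff < r) {  # short signal: extend by edge replication beyond reflection
    pad <- c(rep(pad[1], r - r_eff), pad, rep(pad[length(pad)], r - r_eff))
  }
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + n)]
}

#' Multi-channel averaged A-scans from lateral sub-regions
#'
#' Divides a B-scan laterally into `M` contiguous, near-equal sub-regions
#' (remainder columns go to the last block), averages each sub-region
#' laterally into an A-scan, and Gaussian-smooths each along depth. The
#' channels capture lateral variation of the retinal axial structure while
#' keeping the observation small.
#'
#' @param bscan A `bscan` object or depth x lateral matrix.
#' @param M Number of lateral sub-regions (>= 1, <= lateral width).
#' @param smoothing_sigma Gaussian sd in depth pixels (0 = no smoothing).
#' @return An object of class `ascan_channels`: list with `channels`
#'   (M x depth matrix), `M` and `smoothing_sigma`.
#' @export
subregion_channels <- function(bscan, M = 4, smoothing_sigma = 2) {
  img <- if (inherits(bscan, "bscan")) bscan$intensity else bscan
  stopifnot(is.matrix(img), M >= 1)
  nl <- ncol(img)
  if (M > nl) stop("M exceeds the number of lateral A-scans")
  block <- nl %/% M
  ch <- matrix(0, nrow = M, ncol = nrow(img))
  for (m in seq_len(M)) {
    from <- (m - 1L) * block + 1L
    to <- if (m == M) nl else m * block
    prof <- rowMeans(img[, from:to, drop = FALSE])
    ch[m, ] <- gaussian_smooth1d(prof, smoothing_sigma)
  }
  structure(list(channels = ch, M = M, smoothing_sigma = smoothing_sigma),
            class = "ascan_channels")
}

#' Joint normalization of a reference/target A-scan pair
#'
#' Standardizes both arrays by the mean and standard deviation of their
#' concatenation, so that the pair is scale-free while the relative
#' brightness between reference and target — the defocus signal — is
#' preserved. (Normalizing each array separately would erase that signal.)
#'
#' @param a_ref,a_tgt Numeric vectors of equal length.
#' @return List with `ref_norm` and `tgt_norm`.
#' @export
normalize_pair <- function(a_ref, a_tgt) {
  stopifnot(length(a_ref) == length(a_tgt))
  joint <- c(a_ref, a_tgt)
  mu <- mean(joint)
  sd_j <- sqrt(mean((joint - mu)^2))  # population sd: [0,2]/[0,2] -> [-1,1]
  if (!is.finite(sd_j) || sd_j <= .Machine$double.eps)
    stop("degenerate input: joint standard deviation is zero")
  list(ref_norm = (a_ref - mu) / sd_j, tgt_norm = (a_tgt - mu) / sd_j)
}

#' Build the agent observation from reference and target channels
#'
#' Stacks the reference and target channel sets into a `2M x depth`
#' observation, channel order `[ref_1..ref_M, tgt_1..tgt_M]`. Each
#' `(ref_m, tgt_m)` channel pair is jointly normalized via
#' [normalize_pair()] so the observation is scale-free per sub-region while
#' keeping the reference/target brightness contrast.
#'
#' @param ref,tgt `ascan_channels` objects with equal `M` and depth.
#' @return A `2M x depth` numeric matrix.
#' @export
build_observation <- function(ref, tgt) {
  stopifnot(inherits(ref, "ascan_channels"), inherits(tgt, "ascan_channels"),
            ref$M == tgt$M, ncol(ref$channels) == ncol(tgt$channels))
  m <- ref$M
  obs <- matrix(0, nrow = 2L * m, ncol = ncol(ref$channels))
  for (i in seq_len(m)) {
    np <- normalize_pair(ref$channels[i, ], tgt$channels[i, ])
    obs[i, ] <- np$ref_norm
    obs[m + i, ] <- np$tgt_norm
  }
  obs
}
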