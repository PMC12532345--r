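#' Negative Euclidean-distance similarity metric
#'
#' `R_m = -sqrt(mean((e_ref - e_tgt)^2))`: the negative root-mean-square
#' difference between two equal-length profiles. Always <= 0, and 0 iff the
#' profiles are identical.
#'
#' @param e_ref,e_tgt Numeric vectors of equal length.
#' @return Scalar similarity (<= 0).
#' @export
ed_metric <- function(e_ref, e_tgt) {
  stopifnot(length(e_ref) == length(e_tgt), length(e_ref) > 0)
  -sqrt(mean((e_ref - e_tgt)^2))
}

#' Edge detection map of an A-scan
#'
#' Gaussian-smooths the profile, takes the first derivative (central
#' differences), and normalizes absolute values to a maximum of 1. The EDM
#' highlights the leading/trailing edges of the retinal bands, which stay
#' put as focus changes even though band intensities do not.
#'
#' @param ascan Numeric vector (length >= 3).
#' @param sigma Gaussian smoothing sd in pixels.
#' @return An object of class `edm_profile`: list with `edm` (nonnegative,
#'   max 1 unless degenerate), `peaks` (detected peak indices, sorted),
#'   `clusters` (per-cluster summary), `mask_applied` and `degenerate`.
#' @export
compute_edm <- function(ascan, sigma = 3) {
  n <- length(ascan)
  stopifnot(n >= 3, all(is.finite(ascan)))
  sm <- gaussian_smooth1d(ascan, sigma)
  grad <- c(sm[2] - sm[1],
            (sm[3:n] - sm[1:(n - 2)]) / 2,
            sm[n] - sm[n - 1])
  e <- abs(grad)
  mx <- max(e)
  degenerate <- mx <= .Machine$double.eps * max(1, max(abs(ascan)))
  if (!degenerate) e <- e / mx else e <- rep(0, n)
  out <- structure(list(edm = e, peaks = integer(0),
                        clusters = NULL, mask_applied = FALSE,
                        degenerate = degenerate),
                   class = "edm_profile")
  if (!degenerate) out <- detect_edm_peaks(out)
  out
}

# local maxima with prominence; O(n_peaks * n) but profiles are short
find_peaks_prominence <- function(x, min_prominence) {
  n <- length(x)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    h <- x[i]
    # walk left/right to the nearest strictly higher sample (or the edge),
    # tracking the lowest valley on the way
    left_min <- h
    k <- i
    while (k > 1 && x[k] <= h) {
      k <- k - 1L
      left_min <- min(left_min, x[k])
      if (x[k] > h) break
    }
    right_min <- h
    k <- i
    while (k < n && x[k] <= h) {
      k <- k + 1L
      right_min <- min(right_min, x[k])
      if (x[k] > h) break
    }
    keep[j] <- (h - max(left_min, right_min)) >= min_prominence
  }
  idx[keep]
}

# group peaks into clusters separated by >= min_separation pixels
cluster_peaks <- function(x, peaks, min_separation) {
  if (!length(peaks)) return(NULL)
  grp <- cumsum(c(1L, as.integer(diff(peaks) >= min_separation)))
  do.call(rbind, lapply(split(peaks, grp), function(p) {
    best <- p[which.max(x[p])]
    data.frame(center = best, height = x[best],
               from = min(p), to = max(p))
  }))
}

detect_edm_peaks <- function(edmprof, prominence_frac = 0.06,
                             min_separation = 40) {
  e <- edmprof$edm
  pk <- find_peaks_prominence(e, prominence_frac * max(e))
  edmprof$peaks <- sort(pk)
  edmprof$clusters <- cluster_peaks(e, sort(pk), min_separation)
  edmprof
}

#' Mask the inner retina of an EDM
#'
#' If at least two high-intensity peak clusters are present (inner and outer
#' retinal bands), the EDM is zeroed from the window start through the
#' valley between the two strongest clusters, leaving only the outer-retina
#' edges for registration. With fewer than two clusters (e.g., foveal
#' regions with only the outer band bright) the profile passes through
#' unchanged with `mask_applied = FALSE`. Masking is idempotent.
#'
#' @param edmprof An `edm_profile` from [compute_edm()].
#' @param high_threshold Minimum normalized peak height for a cluster to
#'   count as "high intensity". The default admits the inner-band edges even
#'   under the strongest defocus dimming of the training range while staying
#'   far above the noise floor of an averaged A-scan.
#' @return The (possibly masked) `edm_profile`.
#' @export
mask_inner_retina <- function(edmprof, high_threshold = 0.08) {
  stopifnot(inherits(edmprof, "edm_profile"))
  if (edmprof$degenerate) return(edmprof)
  cl <- edmprof$clusters
  if (is.null(cl)) return(edmprof)
  strong <- cl[cl$height >= high_threshold, , drop = FALSE]
  if (nrow(strong) < 2) return(edmprof)
  top2 <- strong[order(-strong$height)[1:2], ]
  inner <- top2[which.min(top2$center), ]
  outer <- top2[which.max(top2$center), ]
  span <- inner$center:outer$center
  valley <- span[which.min(edmprof$edm[span])]
  edmprof$edm[1:valley] <- 0
  mx <- max(edmprof$edm)
  if (mx > 0) edmprof$edm <- edmprof$edm / mx  # keep max-1 normalization
  edmprof$mask_applied <- TRUE
  edmprof <- detect_edm_peaks(edmprof)
  edmprof
}

# metric curve over candidate displacements; displacement d means the target
# sits d pixels deeper than the reference; only the overlap is compared and
# the RMS is normalized by the overlap length
ed_shift_curve <- function(e_ref, e_tgt, Np) {
  n <- length(e_ref)
  stopifnot(length(e_tgt) == n, Np >= 1, Np < n)
  ds <- -Np:Np
  vapply(ds, function(d) {
    i <- max(1L, 1L - d):min(n, n - d)
    ed_metric(e_ref[i], e_tgt[i + d])
  }, numeric(1))
}

#' Focus-robust axial registration of two B-scans
#'
#' Registers a target B-scan to a reference by exhaustive integer pixel-shift
#' search maximizing the negative Euclidean distance between the two
#' (masked) edge detection maps. The pipeline per profile is: lateral
#' average, EDM, peak detection, inner-retina masking. Because the EDM edge
#' locations are invariant to focus while raw intensities are not, and the
#' ambiguous inner-band edges are masked out, the metric curve has a single
#' global peak at the true shift even when the two frames are focused on
#' different retinal bands.
#'
#' @param ref_bscan,tgt_bscan `bscan` objects (or depth x lateral matrices)
#'   with the same depth size.
#' @param Np Search half-range in pixels; default covers +/- 200 um at the
#'   axial pixel pitch.
#' @param edm_sigma Gaussian smoothing sd for the EDM, pixels.
#' @param profile Profile type to register on: `"masked_edm"` (default),
#'   `"edm"` (unmasked), or `"raw"` (jointly normalized average A-scans; for
#'   comparison only — susceptible to inner/outer band confusion).
#' @param params An [oct_params()] object (pixel pitch, default Np).
#' @return An object of class `registration_result`: `shift_pixels`
#'   (positive = target deeper than reference; apply `-shift_pixels` to
#'   correct), `shift_um`, `metric_curve` (length `2*Np+1`, displacement
#'   `-Np..Np`), `best_metric`, `mask_applied` (ref/tgt flags), `Np`,
#'   `profile`.
#' @export
register_axial <- function(ref_bscan, tgt_bscan, Np = NULL, edm_sigma = 3,
                           profile = c("masked_edm", "edm", "raw"),
                           params = oct_params()) {
  profile <- match.arg(profile)
  if (is.null(Np)) Np <- as.integer(ceiling(200 / params$axial_pixel_pitch))
  a_ref <- average_ascan(ref_bscan)
  a_tgt <- average_ascan(tgt_bscan)
  stopifnot(length(a_ref) == length(a_tgt))
  mask_flags <- c(ref = FALSE, tgt = FALSE)
  if (profile == "raw") {
    np <- normalize_pair(a_ref, a_tgt)
    e_ref <- np$ref_norm
    e_tgt <- np$tgt_norm
  } else {
    er <- compute_edm(a_ref, edm_sigma)
    et <- compute_edm(a_tgt, edm_sigma)
    if (er$degenerate && et$degenerate)
      stop("un-registrable frame: both edge maps are degenerate")
    if (profile == "masked_edm") {
      # mask only when BOTH profiles expose two band clusters: masking one
      # side of the pair and not the other would compare an outer-only map
      # against a two-band map and reintroduce the ambiguity
      n_strong <- function(e) {
        if (is.null(e$clusters)) return(0L)
        sum(e$clusters$height >= 0.08)
      }
      if (n_strong(er) >= 2 && n_strong(et) >= 2) {
        er <- mask_inner_retina(er)
        et <- mask_inner_retina(et)
      }
      mask_flags <- c(ref = er$mask_applied, tgt = et$mask_applied)
    }
    e_ref <- er$edm
    e_tgt <- et$edm
  }
  curve <- ed_shift_curve(e_ref, e_tgt, Np)
  ds <- -Np:Np
  best <- max(curve)
  cand <- which(curve >= best - 1e-12)
  d_best <- ds[cand[which.min(abs(ds[cand]))]]
  structure(list(shift_pixels = as.integer(d_best),
                 shift_um = d_best * params$axial_pixel_pitch,
                 metric_curve = curve,
                 best_metric = best,
                 mask_applied = mask_flags,
                 Np = as.integer(Np),
                 profile = profile),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Axial registration (%s): shift %+d px (%+.1f um), best metric %.4f, Np %d\n",
              x$profile, x$shift_pixels, x$shift_um, x$best_metric, x$Np))
  invisible(x)
}

#' Apply an axial shift correction to a B-scan
#'
#' Rolls the image axially by `-shift_pixels` (undoing a measured
#' displacement); rows entering the window are filled with a background
#' estimate (the lower quartile of the image).
#'
#' @param bscan A `bscan` object or depth x lateral matrix.
#' @param shift_pixels Measured displacement from [register_axial()].
#' @return Same type as the input, axially corrected.
#' @export
apply_axial_correction <- function(bscan, shift_pixels) {
  img <- if (inherits(bscan, "bscan")) bscan$intensity else bscan
  k <- as.integer(shift_pixels)
  if (k != 0) {
    n <- nrow(img)
    fill <- stats::quantile(img, 0.25, names = FALSE)
    out <- matrix(fill, nrow = n, ncol = ncol(img))
    if (k > 0 && k < n) out[1:(n - k), ] <- img[(k + 1):n, ]
    if (k < 0 && -k < n) out[(1 - k):n, ] <- img[1:(n + k), ]
    img <- out
  }
  if (inherits(bscan, "bscan")) {
    bscan$intensity <- img
    bscan
  } else img
}
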