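#' Run a closed-loop simulated correction session
#'
#' Simulates an imaging session in which the retina undergoes
#' Ornstein-Uhlenbeck axial motion and accommodative defocus fluctuation,
#' and each frame is corrected independently: axial motion first (masked-EDM
#' pixel-shift registration), then defocus (single-step agent prediction),
#' after which the corrected frame is re-rendered and residuals are
#' recorded. The first frame of the session is the reference by default.
#'
#' @param agent A trained `focus_agent`.
#' @param phantom A [make_phantom()] object (defaults to the agent's
#'   training phantom).
#' @param params An [oct_params()] object (defaults to the agent's).
#' @param ou_motion [ou_params()] for axial motion, um.
#' @param ou_defocus [ou_params()] for defocus, D.
#' @param n_frames Number of frames (100 frames at 40 ms = a 4 s session).
#' @param rng_seed Integer seed for trajectories and rendering noise.
#' @param order `"motion_first"` (the pipeline order) or `"focus_first"`
#'   (for ablation: predicting focus on unregistered frames).
#' @param keep_stacks Keep the raw / motion-corrected / fully corrected
#'   B-scan stacks (lists of matrices) in the result.
#' @return An object of class `correction_session`: `trace` (a
#'   `session_trace` data frame with per-frame applied/corrected/residual
#'   motion and defocus plus reward), and optionally the three stacks.
#' @export
run_session <- function(agent,
                        phantom = NULL,
                        params = NULL,
                        ou_motion = ou_params(stationary_sigma = 53.2),
                        ou_defocus = ou_params(stationary_sigma = 0.27),
                        n_frames = 100,
                        rng_seed = NULL,
                        order = c("motion_first", "focus_first"),
                        keep_stacks = FALSE) {
  stopifnot(inherits(agent, "focus_agent"))
  order <- match.arg(order)
  phantom <- phantom %||% agent$phantom
  params <- params %||% agent$params
  cfg <- agent$config
  if (!is.null(rng_seed)) set.seed(rng_seed)
  motion <- ou_trajectory(ou_motion, n_frames)
  defocus <- ou_trajectory(ou_defocus, n_frames)
  zf_ref <- phantom_mid_zf(phantom, params)
  ref <- render_bscan(phantom, focus_state(zf_ref, 0, 0, params), params)
  ref_avg <- average_ascan(ref)
  rows <- vector("list", n_frames)
  raw_stack <- if (keep_stacks) vector("list", n_frames) else NULL
  motion_stack <- if (keep_stacks) vector("list", n_frames) else NULL
  corr_stack <- if (keep_stacks) vector("list", n_frames) else NULL
  for (i in seq_len(n_frames)) {
    st <- focus_state(zf_ref, defocus[i], motion[i], params)
    tgt <- render_bscan(phantom, st, params)
    row <- data.frame(t = (i - 1) * ou_motion$dt,
                      applied_shift_um = motion[i],
                      applied_defocus_D = defocus[i],
                      corrected_shift_um = NA_real_,
                      corrected_defocus_D = NA_real_,
                      residual_shift_um = NA_real_,
                      residual_defocus_D = NA_real_,
                      reward = NA_real_)
    res <- tryCatch({
      if (order == "motion_first") {
        reg <- register_axial(ref, tgt, params = params)
        tgt_corr <- apply_axial_correction(tgt, reg$shift_pixels)
        pred <- predict(agent, ref, tgt_corr, register = FALSE)
      } else {
        pred <- predict(agent, ref, tgt, register = FALSE)
        reg <- register_axial(ref, tgt, params = params)
        tgt_corr <- apply_axial_correction(tgt, reg$shift_pixels)
      }
      st_new <- focus_state(zf_ref, defocus[i] - pred, motion[i], params)
      final <- apply_axial_correction(
        render_bscan(phantom, st_new, params), reg$shift_pixels)
      list(reg = reg, pred = pred, tgt_corr = tgt_corr, final = final)
    }, error = function(e) {
      warning(sprintf("frame %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      row$corrected_shift_um <- res$reg$shift_um
      row$corrected_defocus_D <- res$pred
      row$residual_shift_um <- motion[i] - res$reg$shift_um
      row$residual_defocus_D <- defocus[i] - res$pred
      row$reward <- reward_focus(ref_avg, average_ascan(res$final), cfg$Nb)
      if (keep_stacks) {
        raw_stack[[i]] <- tgt$intensity
        motion_stack[[i]] <- res$tgt_corr$intensity
        corr_stack[[i]] <- res$final$intensity
      }
    }
    rows[[i]] <- row
  }
  trace <- do.call(rbind, rows)
  class(trace) <- c("session_trace", "data.frame")
  structure(list(trace = trace,
                 raw_stack = raw_stack,
                 motion_corrected_stack = motion_stack,
                 corrected_stack = corr_stack,
                 order = order),
            class = "correction_session")
}

#' Summary statistics of a correction session trace
#'
#' Sample standard deviations (n - 1 denominator) and mean absolute errors
#' of the applied and residual axial motion and defocus.
#'
#' @param trace A `session_trace` data frame (or a `correction_session`).
#' @return A list of summary statistics.
#' @export
session_metrics <- function(trace) {
  if (inherits(trace, "correction_session")) trace <- trace$trace
  ok <- stats::complete.cases(trace)
  tr <- trace[ok, , drop = FALSE]
  list(
    n_frames = nrow(trace), n_corrected = nrow(tr),
    std_applied_shift_um = stats::sd(tr$applied_shift_um),
    std_residual_shift_um = stats::sd(tr$residual_shift_um),
    std_applied_defocus_D = stats::sd(tr$applied_defocus_D),
    std_residual_defocus_D = stats::sd(tr$residual_defocus_D),
    mean_abs_residual_shift_um = mean(abs(tr$residual_shift_um)),
    mean_abs_residual_defocus_D = mean(abs(tr$residual_defocus_D)),
    mean_reward = mean(tr$reward)
  )
}

#' @export
print.correction_session <- function(x, ...) {
  m <- session_metrics(x$trace)
  cat(sprintf("Simulated correction session (%d frames, %s)\n",
              m$n_frames, x$order))
  cat(sprintf("  axial motion: applied sd %.1f um -> residual sd %.2f um\n",
              m$std_applied_shift_um, m$std_residual_shift_um))
  cat(sprintf("  defocus:      applied sd %.3f D -> residual sd %.4f D\n",
              m$std_applied_defocus_D, m$std_residual_defocus_D))
  invisible(x)
}

#' Kymograph of a B-scan stack
#'
#' Reduces each frame to its average A-scan and lays the profiles out as
#' time-ordered columns, a depth-vs-time view of session stability.
#'
#' @param stack List of depth x lateral matrices (or `bscan` objects).
#' @return A depth x time matrix.
#' @export
kymograph <- function(stack) {
  stopifnot(length(stack) >= 1)
  cols <- lapply(stack, average_ascan)
  do.call(cbind, cols)
}

#' Write / read a session trace as CSV
#'
#' Comma-separated with a header row; times in seconds, shifts in um,
#' defocus in diopters.
#'
#' @param trace A `session_trace` data frame.
#' @param path Output file path.
#' @return `write_trace` returns the path invisibly; `read_trace` returns a
#'   `session_trace`.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "correction_session")) trace <- trace$trace
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("session_trace", "data.frame")
  tr
}
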