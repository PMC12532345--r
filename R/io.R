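#' Write / read a B-scan stack as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages, jointly rescaled to `[0, 1]` by
#' the stack maximum (relative intensity only; the scale factor is returned
#' as an attribute on reading back).
#'
#' @param stack List of depth x lateral matrices (or `bscan` objects).
#' @param path Output `.tiff` path.
#' @return `write_bscan_stack` returns the path invisibly;
#'   `read_bscan_stack` returns a list of matrices.
#' @export
write_bscan_stack <- function(stack, path) {
  mats <- lapply(stack, function(x)
    if (inherits(x, "bscan")) x$intensity else x)
  mx <- max(unlist(lapply(mats, max)), 1e-12)
  tiff::writeTIFF(lapply(mats, function(m) m / mx), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_bscan_stack
#' @export
read_bscan_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}

#' Save / load a trained agent checkpoint
#'
#' The checkpoint is a single RDS archive of the weight arrays plus the
#' agent configuration.
#'
#' @param agent A `focus_agent`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_agent` returns the path invisibly; `load_agent` returns
#'   the `focus_agent`.
#' @export
save_agent <- function(agent, path) {
  stopifnot(inherits(agent, "focus_agent"))
  saveRDS(agent, path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  agent <- readRDS(path)
  stopifnot(inherits(agent, "focus_agent"))
  agent
}

#' Read a simulation/agent configuration file
#'
#' Reads a YAML (or JSON) config holding any of the [oct_params()],
#' [ou_params()] (`ou_motion`, `ou_defocus`), [make_phantom()] (`phantom`)
#' and [agent_config()] (`agent`) fields, and constructs the corresponding
#' objects with defaults for missing entries.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return List with `params`, `phantom`, `ou_motion`, `ou_defocus`,
#'   `agent`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(fn, args) do.call(fn, args %||% list())
  list(params = build(oct_params, cfg$params),
       phantom = build(make_phantom, cfg$phantom),
       ou_motion = build(ou_params, cfg$ou_motion),
       ou_defocus = build(ou_params, cfg$ou_defocus),
       agent = build(agent_config, cfg$agent))
}
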