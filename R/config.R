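#' Write / read a pipeline configuration as YAML
#'
#' Serializes the trial timeline, the reference screen geometry and,
#' optionally, per-condition simulation parameters, so that a whole
#' analysis (or simulation) setup can be versioned as one plain-text file.
#'
#' @param path YAML file path.
#' @param timeline A [pl_timeline()].
#' @param reference A [pl_screen()].
#' @param sim_params Optional named list of [sim_params()] per condition.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   list with `timeline`, `reference` and (if present) `sim_params`,
#'   reconstructed as package objects.
#' @export
write_config <- function(path, timeline = pl_timeline(),
                         reference = pl_screen(), sim_params = NULL) {
  cfg <- list(timeline = unclass(timeline),
              reference = unclass(reference))
  if (!is.null(sim_params))
    cfg$sim_params <- lapply(sim_params, function(p) {
      p <- unclass(p)
      p$onset_shift_ms <- as.list(p$onset_shift_ms)
      p
    })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(
    timeline = do.call(pl_timeline, cfg$timeline),
    reference = do.call(pl_screen, cfg$reference)
  )
  if (!is.null(cfg$sim_params))
    out$sim_params <- lapply(cfg$sim_params, function(p) {
      p$onset_shift_ms <- unlist(p$onset_shift_ms)
      do.call(sim_params, p)
    })
  out
}
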