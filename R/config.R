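ks_config_defaults <- function() {
  list(
    params = unclass(ks_params()),
    seed = 1L,
    verbose = TRUE,
    simulate = list(nx = 100L, ny = 100L, t_end = 180, dt = 0.01,
                    snapshot_times = c(0, 2.5, 7.8, 19.2, 46.3, 180),
                    ic = "nine-squares", square_frac = 0.1,
                    trace_positions = NULL, trace_dt = 0.1),
    invert = list(tol = 1e-8, max_iter = 5000L, restart = 50L,
                  frame_dt = 1, floor = 1e-3, smooth_sigma = 0,
                  rescale = TRUE),
    ode4 = list(b_min = 10, b_max = 25, steps = 31L, scan_max = 2,
                n_grid = 10000L),
    phases = list(pos = c(50L, 50L), signal = "v", min_seg = 3L)
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, fills every missing key from the
#' defaults (reference parameter set, `gamma = 0.25`) and rejects unknown
#' keys at any level, listing every violation. An empty file yields the full
#' default configuration.
#'
#' @param path Path to a JSON file (or a file containing only whitespace).
#' @return A validated configuration list of class `ks_run_config` with
#'   blocks `params`, `simulate`, `invert`, `ode4`, `phases` plus top-level
#'   `seed` and `verbose`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (!nzchar(trimws(txt))) list()
         else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  def <- ks_config_defaults()

  problems <- character(0)
  bad_top <- setdiff(names(raw), names(def))
  if (length(bad_top)) {
    problems <- c(problems, paste0("unknown top-level key: ", bad_top))
  }
  for (blk in intersect(names(raw), names(def))) {
    if (is.list(def[[blk]]) && !is.null(names(def[[blk]]))) {
      if (!is.list(raw[[blk]])) {
        problems <- c(problems, paste0(blk, ": expected an object"))
        next
      }
      bad <- setdiff(names(raw[[blk]]), names(def[[blk]]))
      if (length(bad)) {
        problems <- c(problems, paste0("unknown key: ", blk, ".", bad))
      }
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  cfg <- modifyList(def, raw, keep.null = TRUE)
  cfg$params <- tryCatch(do.call(ks_params, cfg$params),
                         error = function(e) stop("params: ", conditionMessage(e)))
  if (cfg$simulate$dt <= 0 || cfg$simulate$t_end <= 0) {
    stop("simulate: dt and t_end must be positive")
  }
  structure(cfg, class = "ks_run_config")
}

#' @rdname load_config
#' @param cfg A `ks_run_config`.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
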