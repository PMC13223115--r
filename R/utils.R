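#' @keywords internal
#' @useDynLib mdpcarto, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Internal validation helper: stop with a classed condition so callers/tests
# can match on error class rather than message text.
stop_mdp <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mdpcarto_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_mdp <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "mdpcarto_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Derive a stage-specific seed from a global pipeline seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed plus the stage name, so any stage can be rerun in isolation and
#' reproduce its output exactly. The derivation is a fixed polynomial hash of
#' the stage name folded into the global seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"synth"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "synth")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- seed %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(if (h == 0) 1 else h)
}

#' Pipeline run configuration
#'
#' Holds the tunable parameters shared across pipeline stages: the
#' neighbourhood radius for alignment scores and surface maps, the number of
#' mediolateral segments, rose-histogram bin width, shell depth scales,
#' permutation replicate count and the global seed.
#'
#' @param neighbourhood_radius_um radius of the 3D neighbourhood ball (micrometres).
#' @param n_segments number of equal-width mediolateral segments.
#' @param rose_bin_deg rose-histogram bin width in degrees; must divide 180.
#' @param shell_scales strictly decreasing scale factors in (0, 1], first 1.0.
#' @param permutation_reps replicates for permutation / Monte-Carlo p-values.
#' @param seed global integer seed.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(neighbourhood_radius_um = 200,
                       n_segments = 6,
                       rose_bin_deg = 15,
                       shell_scales = c(1.0, 0.8, 0.6, 0.4),
                       permutation_reps = 999,
                       seed = 1L) {
  if (neighbourhood_radius_um <= 0)
    stop_mdp("mdp_parameter_error", "neighbourhood_radius_um must be > 0")
  if (n_segments < 1)
    stop_mdp("mdp_parameter_error", "n_segments must be >= 1")
  if (180 %% rose_bin_deg != 0)
    stop_mdp("mdp_parameter_error", "rose_bin_deg must divide 180")
  if (any(shell_scales <= 0) || any(shell_scales > 1) ||
      any(diff(shell_scales) >= 0))
    stop_mdp("mdp_parameter_error",
             "shell_scales must be strictly decreasing in (0, 1]")
  structure(list(
    neighbourhood_radius_um = neighbourhood_radius_um,
    n_segments = as.integer(n_segments),
    rose_bin_deg = rose_bin_deg,
    shell_scales = shell_scales,
    permutation_reps = as.integer(permutation_reps),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

# Short stable hash of a run_config for logging / manifests.
config_hash <- function(cfg) {
  s <- paste(vapply(cfg, function(v) paste(format(v, digits = 12), collapse = ","),
                    character(1)), collapse = ";")
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}

mdp_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}
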