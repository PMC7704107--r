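#' @useDynLib spikematch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif rpois rbinom prcomp mad pchisq sd
#' @importFrom utils read.csv write.csv unzip packageVersion
NULL

# Classed conditions so the CLI can map error types to exit codes.
sm_stop <- function(msg, type = "validation", call. = FALSE) {
  cls <- switch(type,
    validation = "sm_validation_error",
    io         = "sm_io_error",
    parameter  = "sm_parameter_error",
    format     = "sm_format_error",
    "sm_error"
  )
  stop(structure(
    class = c(cls, "sm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this,
# which is what makes generators pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# frames are stored as doubles holding exact integers (0-based)
check_frames <- function(frames, unit = NULL) {
  who <- if (is.null(unit)) "spike train" else sprintf("unit '%s'", unit)
  if (length(frames) == 0L) return(invisible(TRUE))
  if (!is.numeric(frames)) {
    sm_stop(sprintf("%s: spike frames must be numeric", who))
  }
  if (anyNA(frames) || any(!is.finite(frames))) {
    sm_stop(sprintf("%s: spike frames must be finite", who))
  }
  if (any(frames != round(frames))) {
    sm_stop(sprintf("%s: spike frames must be integers", who))
  }
  if (any(frames < 0)) {
    sm_stop(sprintf("%s: spike frames must be non-negative", who))
  }
  d <- diff(frames)
  if (any(d == 0)) {
    sm_stop(sprintf("%s: duplicate spike frame(s), e.g. frame %s",
                    who, format(frames[which(d == 0)[1L]], scientific = FALSE)))
  }
  if (any(d < 0)) {
    sm_stop(sprintf("%s: spike frames must be strictly increasing", who))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
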