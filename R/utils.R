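#' @keywords internal
"_PACKAGE"

# Input validation helpers -----------------------------------------------

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_input("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_input("`%s` must be >= %g", name, lower)
  if (x > upper)
    stop_input("`%s` must be <= %g", name, upper)
  invisible(x)
}

check_time <- function(time) {
  if (length(time) < 2L || any(!is.finite(time)))
    stop_input("`time` must be a finite vector of length >= 2")
  if (any(diff(time) <= 0))
    stop_input("timestamps must be strictly increasing")
  invisible(time)
}

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic routines in the package take an explicit `seed`; none touch
#' the caller's global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Run-length helpers ------------------------------------------------------

# first indices of runs of `value` in a vector (rising edges)
rising_edges <- function(x, value) {
  is_v <- x == value
  which(is_v & !c(FALSE, is_v[-length(is_v)]))
}

#' Keep every k-th frame
#'
#' Block decimation used for conservative inference on autocorrelated
#' frame-wise samples: keeping one frame per `k` reduces serial dependence so
#' that rank-test and correlation p-values are closer to nominal.
#'
#' @param n number of frames (or a vector whose indices to thin).
#' @param k decimation factor (1 = keep all).
#' @return integer indices `seq(1, n, by = k)`.
#' @export
decimate_idx <- function(n, k = 1L) {
  check_scalar(k, "k", lower = 1)
  seq.int(1L, n, by = as.integer(k))
}
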