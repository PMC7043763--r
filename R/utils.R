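# classed error helpers so callers/tests can condition on failure modes

fd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "focidetect_error")))
}

fd_assert_scalar_pos <- function(x, what, class = "fd_value_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    fd_stop(sprintf("%s must be a single positive number", what), class)
  invisible(x)
}

# run `expr` with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# 8-bit view used by rank/percentile/bilateral/entropy filters
quantize8 <- function(pixels) {
  q <- pmax(0, pmin(1, pixels))
  matrix(as.integer(round(q * 255)), nrow = nrow(pixels))
}

#' Gaussian smoothing of an image matrix
#'
#' Separable Gaussian convolution with mirror boundary handling; the kernel
#' is truncated at 4 standard deviations.
#'
#' @param pixels numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the
#'   input unchanged.
#' @return numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(pixels, sigma) {
  if (sigma <= 0) return(pixels)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  cpp_sepconv(pixels, k, k)
}
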