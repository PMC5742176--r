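# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global RNG stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Gaussian smoothing by direct FIR convolution with reflection padding.
# Kernel truncated at +/- 4*sigma; the truncation error is < 1e-4 of mass.
gauss_smooth <- function(x, sigma) {
  stopifnot(sigma > 0)
  n <- length(x)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  if (2L * half + 1L > n)
    stop("Gaussian kernel (", 2L * half + 1L, " taps) longer than series (",
         n, " samples)")
  k <- stats::dnorm(seq.int(-half, half), sd = sigma)
  k <- k / sum(k)
  xp <- c(x[half:1L], x, x[n:(n - half + 1L)])
  out <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop("'", name, "' must be a single number >= ", min)
  invisible(x)
}
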