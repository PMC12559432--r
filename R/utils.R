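#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop2 <- function(...) stop(..., call. = FALSE)

# Clip values into [lo, hi].
clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

check_beta_matrix <- function(beta, allow_na = TRUE) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop2("beta must be a numeric matrix (probes x samples)")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop2("beta must carry probe ids as rownames and sample ids as colnames")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    stop2("beta values must lie in [0, 1]")
  if (!allow_na && anyNA(beta))
    stop2("beta must not contain missing values")
  invisible(beta)
}
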