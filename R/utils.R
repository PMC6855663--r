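#' @importFrom stats lm coef pf pt sd var rnorm rlnorm runif setNames
#' @importFrom utils write.csv read.csv packageVersion tail combn
#' @importFrom mgcv in.out
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores the previous state, so generator functions are pure functions of
#' their (config, seed) arguments and never leak randomness into the caller.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing integer", call. = FALSE)
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

## Derive a reproducible sub-seed for a named module stream from a master seed.
## Kept well below .Machine$integer.max.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 100003L)
}

## Rasterise a closed polygon (n x 2, 0-based pixel-centre x/y) onto a
## height x width grid; returns a logical matrix (row = y + 1, col = x + 1).
rasterizePolygon <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  h <- dim[1]; w <- dim[2]
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  bnd <- poly
  if (any(bnd[1, ] != bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
  inside <- mgcv::in.out(bnd, cbind(xs, ys))
  matrix(inside, nrow = h, ncol = w)
}

## TRUE where hue (in [0,1]) falls in [lo, hi], supporting wrap-around
## windows where lo > hi (e.g. magenta-through-red).
hueIn <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
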