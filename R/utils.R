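# internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent substream seed
#'
#' Expands one global seed into per-pipeline substream seeds through a
#' Lehmer-style counter scheme, so that pipelines seeded from the same run
#' seed draw unrelated random streams and can be re-run independently.
#'
#' @param seed integer master seed.
#' @param stream non-negative integer substream counter.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' substream_seed(1, 0)
#' substream_seed(1, 1)
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(stream), length(stream) == 1, stream >= 0)
  m <- 2147483647
  h <- (abs(seed) %% m)
  h <- (h * 16807) %% m              # products stay below 2^53
  h <- (h + (stream %% m) * 48271) %% m
  h <- (h * 16807) %% m
  as.integer(max(1, h %% (m - 1)))
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict_min && x <= min)
    stop_domain(sprintf("'%s' must be > %g", name, min))
  if (!strict_min && x < min)
    stop_domain(sprintf("'%s' must be >= %g", name, min))
  invisible(x)
}

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
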