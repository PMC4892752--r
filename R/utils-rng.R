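#' Derive a deterministic child seed from a root seed
#'
#' All stochastic stages in the package draw their randomness from named
#' substreams of one root seed, so that a whole simulated study is exactly
#' reproducible from `(config, seed)` while individual subjects, tasks and
#' analysis stages remain statistically independent.
#'
#' @param root integer root seed.
#' @param ... further character or numeric labels naming the substream
#'   (e.g. subject id, task id).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(1, "S01", "p1")
#' @export
child_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  key <- paste(c(format(root, scientific = FALSE), ...), collapse = "/")
  h <- 2166136261
  for (ch in utf8ToInt(key)) {
    # FNV-1a-style mixing, kept exact in double precision
    h <- ((h %% 65536) * 16777619 + (h %/% 65536) * 41845 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# `seed` is forced before the stream is snapshot: a seed expression that
# itself draws from the RNG (e.g. sample.int) must advance the caller's
# stream, not be rewound with it.
with_seed <- function(seed, code) {
  force(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
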