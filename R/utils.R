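# Run expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministic fan-out of per-task seeds from a master seed; stays < 2^31.
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), is.numeric(counter))
  as.integer((as.numeric(master) %% 1e6) * 2038 + counter * 7919 + 1) %% 2147483647L
}

as_coord_matrix <- function(x, what = "coordinates") {
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(what, " must be an n x 3 matrix, got ", ncol(x), " columns")
  if (nrow(x) < 1L) stop(what, ": need at least one point")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(what, " contain non-finite values")
  x
}
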