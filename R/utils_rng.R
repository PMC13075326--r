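#' Derive a reproducible substream seed
#'
#' Hierarchical seed derivation: a single root seed fans out into named
#' substreams (per center, patient, episode, stage) so that any unit of the
#' pipeline can be re-simulated independently without disturbing the draws of
#' the others, and cohorts are stable under insertion of new centers.
#'
#' @param root integer root seed.
#' @param ... character or numeric tags naming the substream, outermost first.
#' @return An integer seed in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "simulate", "center_A", 3)
derive_seed <- function(root, ...) {
  tags <- as.character(unlist(list(...), use.names = FALSE))
  # 64-bit-safe modular hash in doubles (products stay < 2^53)
  h <- (as.numeric(root) %% 2147483629) + 1
  for (tag in tags) {
    for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483629
    h <- (h * 1000003 + 17) %% 2147483629
  }
  as.integer(h %% 2147483646) + 1L
}

# evaluate `code` under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
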