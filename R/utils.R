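# Seed discipline: every stochastic entry point takes an explicit integer
# seed, evaluates under it, and restores the caller's RNG state afterwards.
# One global seed fans out to per-component substreams through sub_seed(),
# so adding a component to a pipeline never perturbs the draws of another.

with_seed <- function(seed, code) {
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

#' Derive a component substream seed from a global seed
#'
#' Documented splitting rule: `(seed * 1009 + stream * 9973) mod (2^31 - 2) + 1`.
#' Distinct `stream` labels give independent-looking substreams and the
#' result always fits a 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stream Integer substream label (>= 0).
#' @return Integer seed.
#' @export
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + as.double(stream) * 9973) %%
               2147483645 + 1)
}
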