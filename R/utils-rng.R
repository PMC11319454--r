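# Deterministic per-run RNG streams. Run r of a resampling procedure with
# master seed s draws from the stream seeded with s + r, so results are
# reproducible and individual runs can be replayed in isolation. The
# caller's RNG state is restored afterwards.

with_run_seed <- function(seed, run, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) + as.integer(run))
  expr
}
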