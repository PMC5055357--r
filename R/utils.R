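# Run code under a fixed RNG seed without disturbing the caller's RNG
# stream; restores .Random.seed (or its absence) on exit.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# derive a child seed from a base seed and a stream label, kept < 2^31
.childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               2147483647)
}
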