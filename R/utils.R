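# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every generator routes its randomness
# through this so that one integer seed pins one artifact without
# perturbing the others.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a documented per-artifact sub-seed from a master seed. Offsets
# are small fixed integers, one per artifact kind; the result stays in
# 32-bit integer range.
subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 131 + offset) %% 2147483647)
}

stopifnotCount <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != floor(x))
        stop(what, " must be a positive integer")
    invisible(as.integer(x))
}

stopifnotFraction <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(what, " must be a fraction in [0, 1]")
    invisible(as.numeric(x))
}
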