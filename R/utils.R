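# Deterministic 31-bit seed derived from a master seed and string labels,
# so per-stage / per-pathway substreams are reproducible and order-free.
stableSeed <- function(master, ...) {
    labels <- paste(c(...), collapse = "\r")
    h <- as.double(master) %% 2147483647
    for (ch in utf8ToInt(labels))
        h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
}

# run `code` under a local RNG state seeded with `seed`
withSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    code
}
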