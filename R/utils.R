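## Internal helpers shared across modules.

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's .Random.seed afterwards so package functions never disturb the
## user's random stream.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic sub-seed derivation: keeps results independent across the
## named random substreams of one root seed, and below 2^31.
subSeed <- function(seed, stream) {
    offsets <- c(properties = 101L, compositions = 202L, sequences = 303L,
                 pairing = 404L, negatives = 505L, calibration = 606L,
                 folds = 707L, pool = 808L)
    off <- offsets[[stream]]
    (as.integer(seed) %% 1000000000L) * 2L + off
}

## Split sequence input (character vector, AAString, AAStringSet element)
## into a character vector of single residues.
seqChars <- function(sequence) {
    s <- as.character(sequence)
    if (length(s) != 1L || is.na(s) || !nzchar(s))
        stop("sequence must be a single non-empty string")
    strsplit(toupper(s), "", fixed = TRUE)[[1L]]
}

## Unordered pair key, used for duplicate / membership checks.
pairKey <- function(a, b) {
    swap <- a > b
    first <- ifelse(swap, b, a)
    second <- ifelse(swap, a, b)
    paste(first, second, sep = "\r")
}

softmax <- function(z) {
    e <- exp(z - max(z))
    e / sum(e)
}
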