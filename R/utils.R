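# internal helpers shared across modules

#' @importFrom withr with_seed
runSeeded <- function(seed, expr) {
    seed <- asSeed(seed)
    withr::with_seed(seed, expr)
}

# coerce to a valid 32-bit integer seed, failing loudly
asSeed <- function(seed) {
    if (length(seed) != 1L || is.na(seed) || !is.numeric(seed))
        stop("'seed' must be a single integer", call. = FALSE)
    if (abs(seed) >= 2^31)
        stop("'seed' must fit in a 32-bit integer", call. = FALSE)
    as.integer(seed)
}

# spawn k reproducible child seeds from one parent seed
spawnSeeds <- function(seed, k) {
    runSeeded(seed, sample.int(.Machine$integer.max, k))
}

# median without S3 dispatch / NA handling overhead (hot path)
fastMedian <- function(v) {
    n <- length(v)
    half <- (n + 1L) %/% 2L
    if (n %% 2L == 1L)
        sort(v, partial = half)[half]
    else {
        s <- sort(v, partial = c(half, half + 1L))
        (s[half] + s[half + 1L]) / 2
    }
}

checkFraction <- function(value, field) {
    if (length(value) < 1L || anyNA(value) || any(value < 0) || any(value > 1))
        stop(sprintf("'%s' must lie in [0, 1]", field), call. = FALSE)
    invisible(value)
}
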