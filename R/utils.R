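utils::globalVariables(c("frame", "row", "value", "condition", "n_bursts"))

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. NULL seed = use current state.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a stream-specific child seed from a master seed (stays < 2^31).
childSeed <- function(seed, stream) {
    (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Extract frame f of a 4-D (frame, z, row, col) array as a 3-D z-stack.
frameStack <- function(arr, f) {
    d <- dim(arr)
    array(arr[f, , , , drop = FALSE], dim = d[2:4])
}

# Contiguous runs of TRUE as inclusive (start, end) 0-based frame indices.
trueRuns <- function(x) {
    r <- rle(as.logical(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep] - 1L)
}
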