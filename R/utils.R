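# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    force(expr)
}

## Derive `n` child seeds from a master seed, keeping them valid 32-bit ints.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.log_msg <- function(..., verbose = TRUE) {
    if (isTRUE(verbose)) message("[somaticHotspots] ", ...)
    invisible(NULL)
}

## stop() with a condition class so the CLI can map errors to exit codes.
.stop_data <- function(...) {
    stop(errorCondition(paste0(...), class = c("shs_data_error", "error")))
}
.stop_config <- function(...) {
    stop(errorCondition(paste0(...), class = c("shs_config_error", "error")))
}
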