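# internal helpers shared across the package

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise the RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# sample() without the length-1 surprise: sample1(5) draws from 5 items,
# sample_vec(x) permutes/draws from the *elements* of x.
sample_vec <- function(x, size = length(x)) {
  if (length(x) <= 1L && size == length(x)) return(x)
  x[sample.int(length(x), size)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) {
  stop(structure(class = c("tcoa_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("tcoa_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
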