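# shared internal helpers

flim_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "flim_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

flim_warning <- function(class, msg, ...) {
  warning(structure(class = c(class, "flim_warning", "warning", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream, so all generators are pure functions of (params, seed)
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    flim_error("flim_invalid_config", "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# population (divisor N) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
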