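# Internal helpers: classed conditions and seed hygiene.

# Signal a classed error so callers can branch on failure kind, e.g.
# tryCatch(..., targetmr_insufficient_instruments = function(e) e$count).
tm_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c(paste0("targetmr_", class), "targetmr_error")))
}

tm_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) tm_error(class, msg, ...)
  invisible(TRUE)
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    tm_error("seed", "`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# 95% two-sided normal quantile used for all CIs.
Z975 <- qnorm(0.975)

# Deterministic sub-seed derivation, kept below 2^31 - 1.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 100003 * i + 7919 * j) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
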