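# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All user-facing stochastic operations route
# through this so results are a pure function of their `seed` argument.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a bounded 31-bit sub-seed for stage `label` / member `i` from a
# master seed. Recorded in output metadata so any member is re-runnable.
derive_seed <- function(seed, label, i = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2011L + h * 7919L + as.integer(i) * 104729L
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form sample SD per column that tolerates a single row.
col_sds <- function(m) apply(m, 2L, stats::sd)
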