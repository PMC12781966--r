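# Internal helpers shared across modules.

# Seed arithmetic: derived seeds must stay valid 32-bit integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647L)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is left untouched so library code does not clobber user seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Percentage formatting used in descriptive tables: nearest whole percent,
# printed with a fixed ".0" suffix ("59.0%" for 207/349).
format_percent <- function(x) {
  sprintf("%.1f%%", round(x))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar_number <- function(x, name) {
  if (!is_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
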