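# Internal helpers shared across modules.

# Complement of a vector of bases (A/C/G/T/N preserved class).
complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

# Stop with a consistent error class so callers/tests can distinguish
# user-input problems from bugs.
stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "ribostamp_input_error")
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input("`%s` is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Derive a child seed from a user seed deterministically; keeps values
# within the 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}
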