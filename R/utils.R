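# Internal numeric helpers.

# Stable sum of probabilities given on the log scale: exp(max) factored out
# so tails down to ~1e-300 keep full double relative precision.
sum_exp <- function(log_terms) {
  if (length(log_terms) == 0L) return(0)
  m <- max(log_terms)
  if (!is.finite(m)) return(0)
  exp(m) * sum(exp(log_terms - m))
}

# Equality at printed precision: both sides rounded to `digits` significant
# figures, compared with a small relative guard against FP representation.
signif_equal <- function(x, y, digits) {
  xs <- signif(x, digits)
  ys <- signif(y, digits)
  abs(xs - ys) <= 1e-9 * pmax(abs(xs), abs(ys), .Machine$double.xmin)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

assert_probability <- function(p, what = "p") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort(sprintf("`%s` must contain probabilities in (0, 1].", what))
  }
  invisible(p)
}
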