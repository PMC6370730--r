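# locale-independent ordering so cohorts align identically on any system
sort_ids <- function(x) sort(x, method = "radix")

frobenius <- function(m) sqrt(sum(m^2))

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

# check a numeric scalar lies in [lo, hi]
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stopf("`%s` must be a single number in [%s, %s]", name, format(lo), format(hi))
  }
  invisible(x)
}
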