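`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic child seeds so composite generators can hand independent
## streams to sub-steps while staying below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483587 + 10007 * (offset %% 1000) + offset) %% 2147483587) + 1L
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

## (chrom, pos) key; positions formatted fixed-point so integer and double
## storage (e.g. after a TSV round trip) produce identical keys
variant_key <- function(x) sprintf("%s:%.0f", x$chrom, x$pos)

## Two-sided normal (Wald) p-value, guarded against 0/NA se.
wald_p <- function(beta, se) {
  p <- 2 * pnorm(-abs(beta / se))
  p[!is.finite(p)] <- NA_real_
  ## p must lie in (0, 1]; underflow to 0 is clamped to the smallest double
  pmax(p, .Machine$double.xmin)
}
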