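# Internal numerical and RNG helpers shared across modules.

#' @importFrom stats pnorm pchisq pt qnorm qt rnorm runif sd var setNames
#' @importFrom utils read.table write.table
NULL

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (used for the H3 both-traits-distinct-variants term).
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is restored afterwards. seed = NULL runs
# against the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# p-values must live in (0, 1]: clamp the numeric zero that a t/normal
# tail returns for machine-exact fits.
clamp_pval <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
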