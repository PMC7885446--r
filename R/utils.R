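## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## DNA residues accepted in alignments; N and "-" are treated as missing
## for all pairwise comparisons (pairwise deletion).
.BASES <- c("A", "C", "G", "T")
.MISSING <- c("N", "-")

logsumexp <- function(x) {
  x <- x[!is.nan(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## vectorised log(exp(a) + exp(b)), tolerant of -Inf
lse2 <- function(a, b) {
  m <- pmax(a, b)
  lo <- pmin(a, b)
  out <- m + log1p(exp(lo - m))
  out[!is.finite(m) & m < 0] <- -Inf
  out
}

## Deterministic substream seeds: master seed + replicate index mapped into
## the 32-bit integer range (spec of R's set.seed).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 1664525 * (as.numeric(i) %% 2147483647)) %% 2147483647)
}

## Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
## seed = NULL means: use the ambient RNG stream as-is.
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Classed conditions so callers can distinguish bad input from an
## undefined statistic (e.g. Tajima's D with S = 0).
abort_input <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("molexpand_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_undefined <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("molexpand_undefined_statistic", "error", "condition"),
    list(message = msg, call = call)
  ))
}
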