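# Internal helpers shared across modules.

#' Harmonic number a_n = sum_{i=1}^{n} 1/i
#' @param n integer >= 0
#' @return numeric
#' @keywords internal
harmonic <- function(n) {
  if (n <= 0) return(0)
  sum(1 / seq_len(n))
}

# sum_{i=1}^{n} 1/i^2
harmonic2 <- function(n) {
  if (n <= 0) return(0)
  sum(1 / seq_len(n)^2)
}

# Set the RNG deterministically when a seed is supplied; seeds are kept
# below 2^31 so they remain valid R integers.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# (b + 1) / (B + 1) permutation p-value estimator: ties count as successes
# and the estimate can never be exactly zero.
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

# Valid nucleotide states; everything else (IUPAC ambiguity etc.) is missing.
.BASES <- c("A", "C", "G", "T")

normalize_base <- function(x) {
  x <- toupper(x)
  x[!(x %in% c(.BASES, "-"))] <- "N"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
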