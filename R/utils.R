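# internal helpers shared across modules

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards. All generators route their randomness here so
# that every output is a pure function of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed; kept below 2^31.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103L + h * 12347) %% 2147483629)
}

log_msg <- function(...) message("[baiminer] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two labellings agree (co-clustered in
#' both or separated in both). 1 means identical partitions. Used to score
#' recovery of planted sequence families by the SSN clustering.
#'
#' @param a,b label vectors over the same items, any comparable type.
#' @return a number in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
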