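# Internal helpers shared across modules.

# Derive a 32-bit sub-seed for one named operation from a global seed, so the
# simulator stages draw from decoupled streams (changing one stage's draws
# does not shift another's).
.opSeed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(op)
  as.integer((abs(seed) * 7919 + sum(codes * seq_along(codes))) %% 2147483587)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Single-character vector of a sequence (accepts character scalar, DNAString).
.seqChars <- function(sequence) {
  s <- as.character(sequence)
  stopifnot(length(s) == 1L)
  strsplit(s, "", fixed = TRUE)[[1L]]
}

# TRUE for soft-masked (lowercase) or ambiguous positions.
.isMaskedChar <- function(chars) {
  chars %in% c("a", "c", "g", "t", "n", "N")
}

.collapseChars <- function(chars) paste(chars, collapse = "")

# Coerce to integer with a range check, for S4 slot constructors.
.asCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number", what))
  }
  as.integer(x)
}
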