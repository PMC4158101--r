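# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Deterministically derive a stage seed from a master seed. Keeps the result a
# positive 32-bit integer so it is always a valid set.seed() argument.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed %% 1000003L) * 8191 + offset * 127 + 1) %%
               2147483646) + 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Vectorised reverse complement (delegates to Biostrings).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute a base different from `base` (used by error and SHM simulators).
other_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(bases, b), 1L), "",
         USE.NAMES = FALSE)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer, got %s", name,
                 deparse(substitute(x))), call. = FALSE)
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, open_zero = FALSE) {
  lo_ok <- if (open_zero) x > 0 else x >= 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1)
    stop(sprintf("`%s` must be a fraction in %s0,1]", name,
                 if (open_zero) "(" else "["), call. = FALSE)
  invisible(as.numeric(x))
}
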