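#' Amino-acid alphabets and residue classes
#'
#' Constants used throughout the property calculations: the 20 standard
#' one-letter amino-acid codes, the ambiguity codes tolerated with
#' `allow_ambiguous = TRUE` (they count as neither charged nor hydrophobic),
#' and the hydrophobic residue class \{G, A, V, L, I, M, F, W, P\} used for
#' the hydrophobicity percentage.
#'
#' @format Character vectors.
#' @name aa_alphabets
NULL

#' @rdname aa_alphabets
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname aa_alphabets
#' @export
AA_AMBIGUOUS <- c("X", "U", "B", "Z")

#' @rdname aa_alphabets
#' @export
AA_HYDROPHOBIC <- c("G", "A", "V", "L", "I", "M", "F", "W", "P")

# per-residue charges: K/R +1, D/E -1, everything else 0
.aa_charge <- c(K = 1L, R = 1L, D = -1L, E = -1L)

# Validate amino-acid strings; error names the offending character and its
# position. Returns the uppercased sequences invisibly.
check_aa <- function(seqs, allow_ambiguous = FALSE, what = "sequence",
                     ids = NULL) {
  seqs <- toupper(as.character(seqs))
  allowed <- AA_STANDARD
  if (allow_ambiguous) allowed <- c(allowed, AA_AMBIGUOUS)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad)) {
      label <- if (!is.null(ids)) sprintf(" (record '%s')", ids[[i]]) else ""
      stop(sprintf(
        "alphabet error in %s%s: invalid residue '%s' at position %d",
        what, label, chars[bad[1]], bad[1]), call. = FALSE)
    }
  }
  invisible(seqs)
}

# Round half-up, robust to binary representation of decimal fractions
# (e.g. mean hydrophobicities like 57.5 or 31.45 must round up, not to even).
round_half_up <- function(x, digits = 0) {
  y <- round(x * 10^digits, 6)
  floor(y + 0.5) / 10^digits
}

# Integer percentage count/total rounded half-up, in exact integer arithmetic.
pct_int <- function(count, total) {
  stopifnot(all(total > 0))
  as.integer((200L * as.integer(count) + as.integer(total)) %/%
               (2L * as.integer(total)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# DNA validation (strict ACGT)
check_dna <- function(seqs, what = "sequence") {
  seqs <- toupper(as.character(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% c("A", "C", "G", "T")))
    if (length(bad)) {
      stop(sprintf("invalid base '%s' at position %d in %s",
                   chars[bad[1]], bad[1], what), call. = FALSE)
    }
  }
  invisible(seqs)
}
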