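# Internal helpers shared across modules.

DNA_BASES4 <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulator calls do
#' not perturb the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single non-missing integer seed is required")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse-complement DNA strings
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (length(x) == 1L) return(.rc1(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scalar reverse complement without S4 overhead (hot loops)
.rc1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

.complement1 <- function(x) chartr("ACGTN", "TGCAN", x)

# Integer encoding used by the vectorised comparisons (utf8 code points).
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
.ints <- function(s) utf8ToInt(s)

.validate_dna <- function(x, what = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s} (first offender: element %d)",
                 what, paste(strsplit(alphabet, "")[[1]], collapse = ","),
                 which(bad)[1L]))
  }
  invisible(x)
}

# Substitution matrix over the alphabet used by the pipeline. N scores as a
# mismatch against everything, including itself.
.subst_matrix <- function(match, mismatch) {
  b <- c(DNA_BASES4, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m
}

# Count of positions where two equal-length strings agree.
.n_agree <- function(a, b) sum(.ints(a) == .ints(b))

.stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single value in [0, 1]", name))
  }
}
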