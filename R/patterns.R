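#' Encode a methylation pattern as an integer index
#'
#' Methylation patterns are binary vectors over the `n` CpG sites of a locus
#' (0 = unmethylated, 1 = methylated), written 5' to 3'.  Patterns are indexed
#' by the integers `1, ..., 2^n`: index `k` is the pattern whose binary
#' expansion (leftmost site = most significant bit) equals `k - 1`, so the
#' all-unmethylated pattern has index 1 and the all-methylated pattern `2^n`.
#' Sorting patterns by index is the same as sorting the pattern strings
#' lexicographically.
#'
#' @param pattern A pattern: either a character string of `"0"`/`"1"`
#'   (e.g. `"111101"`) or a vector of 0/1 site states.
#' @return The integer index `k` in `1, ..., 2^n`.
#' @examples
#' encode_pattern("111101")        # 62
#' decode_pattern(62, 6)           # "111101"
#' methylation_count("111101")     # 5
#' @seealso [decode_pattern()], [lexicographic_order()]
#' @export
encode_pattern <- function(pattern) {
  bits <- pattern_states(pattern)
  n <- length(bits)
  if (n > 52L) stop("patterns longer than 52 sites cannot be indexed exactly")
  k <- sum(bits * 2^((n - 1L):0)) + 1
  if (k <= .Machine$integer.max) as.integer(k) else k
}

#' Decode an integer index into a methylation pattern
#'
#' Inverse of [encode_pattern()].
#'
#' @param k Integer index in `1, ..., 2^n`.
#' @param n Number of CpG sites.
#' @return The pattern as a character string of `"0"`/`"1"`.
#' @export
decode_pattern <- function(k, n) {
  if (length(k) != 1L || !is.finite(k) || k != trunc(k))
    stop("'k' must be a single integer")
  if (length(n) != 1L || n < 1L || n != trunc(n))
    stop("'n' must be a single positive integer")
  if (k < 1 || k > 2^n) stop("'k' out of range 1..2^n for n = ", n)
  v <- k - 1
  bits <- integer(n)
  for (s in n:1) {
    bits[s] <- v %% 2
    v <- v %/% 2
  }
  paste(bits, collapse = "")
}

#' Number of methylated sites in a pattern
#'
#' @inheritParams encode_pattern
#' @return Integer count of 1-states.
#' @export
methylation_count <- function(pattern) {
  sum(pattern_states(pattern))
}

#' Order patterns lexicographically
#'
#' The display and index convention of the package: binary pattern strings
#' sorted as strings, which coincides with ascending [encode_pattern()] index.
#'
#' @param x A character vector of pattern strings, or a [pattern_counts()]
#'   object (reordered in place).
#' @return Object of the same type with patterns in lexicographic order.
#' @export
lexicographic_order <- function(x) {
  if (inherits(x, "pattern_counts")) {
    ord <- order(x$patterns, method = "radix")
    x$patterns <- x$patterns[ord]
    x$counts <- x$counts[ord]
    return(x)
  }
  sort(as.character(x), method = "radix")
}

# Normalise a single pattern to an integer 0/1 vector.
pattern_states <- function(pattern) {
  if (is.character(pattern)) {
    if (length(pattern) != 1L) stop("one pattern string at a time")
    bits <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    if (length(bits) < 1L || !all(bits %in% c("0", "1")))
      stop("invalid pattern: '", pattern, "' is not a string of 0s and 1s")
    return(as.integer(bits))
  }
  bits <- as.numeric(pattern)
  if (length(bits) < 1L || anyNA(bits) || !all(bits %in% c(0, 1)))
    stop("invalid pattern: site states must all be 0 or 1")
  as.integer(bits)
}

# Pattern strings -> 0/1 matrix, one row per pattern (columns = sites).
pattern_bit_matrix <- function(patterns) {
  n <- nchar(patterns[1L])
  m <- matrix(0L, length(patterns), n)
  split <- strsplit(patterns, "", fixed = TRUE)
  for (i in seq_along(patterns)) m[i, ] <- as.integer(split[[i]] == "1")
  rownames(m) <- patterns
  m
}

# All 2^n patterns in lexicographic (= index) order.
all_patterns <- function(n) {
  if (n > 16L) stop("refusing to enumerate 2^", n, " patterns")
  vapply(seq_len(2^n), decode_pattern, character(1L), n = n)
}

#' Pattern count table for one locus
#'
#' Container for the observed read counts `y_k` of each methylation pattern
#' at a single amplicon/locus.  All patterns must have the same number of
#' sites; duplicated patterns are an error (they usually indicate a malformed
#' input table, so they are not silently summed).  Zero-count patterns are
#' representable but omitted from written tables by default.
#'
#' @param patterns Character vector of binary pattern strings.
#' @param counts Integer vector of non-negative read counts, one per pattern.
#' @return An object of class `"pattern_counts"`: a list with elements
#'   `patterns` (lexicographically sorted), `counts`, `n` (number of CpG
#'   sites) and `N` (total reads).
#' @examples
#' pc <- pattern_counts(c("00", "11", "01"), c(3L, 7L, 1L))
#' pc$N
#' as.data.frame(pc)
#' @export
pattern_counts <- function(patterns, counts) {
  patterns <- as.character(patterns)
  if (length(patterns) < 1L) stop("at least one pattern is required")
  if (length(patterns) != length(counts))
    stop("'patterns' and 'counts' must have the same length")
  lens <- nchar(patterns)
  if (any(lens != lens[1L]))
    stop("all patterns must have the same length; found lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  bad <- grepl("[^01]", patterns)
  if (any(bad))
    stop("non-binary pattern(s): ", paste(patterns[bad], collapse = ", "))
  dup <- duplicated(patterns)
  if (any(dup))
    stop("duplicated pattern(s): ", paste(unique(patterns[dup]), collapse = ", "))
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("total read count must be at least 1")
  ord <- order(patterns, method = "radix")
  structure(
    list(patterns = patterns[ord], counts = as.integer(counts[ord]),
         n = lens[1L], N = as.integer(sum(counts))),
    class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("Pattern counts: %d CpG sites, %d patterns, N_read = %d\n",
              x$n, length(x$patterns), x$N))
  print(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (length(x$patterns) > 10L)
    cat("... and", length(x$patterns) - 10L, "more patterns\n")
  invisible(x)
}

#' @export
as.data.frame.pattern_counts <- function(x, ...) {
  data.frame(pattern = x$patterns, count = x$counts,
             stringsAsFactors = FALSE)
}

# Named count vector restricted to observed (y > 0) patterns.
observed_counts <- function(counts) {
  keep <- counts$counts > 0L
  stats::setNames(counts$counts[keep], counts$patterns[keep])
}
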