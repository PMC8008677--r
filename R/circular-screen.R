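# Circularity screening: a contig assembled from a circular template carries
# an exact direct repeat of its first bases at its end (an assembler k-mer
# artifact). Contigs whose terminal repeat falls in the configured window
# are flagged circular and trimmed to one copy of the genome.

#' Find the terminal direct repeat of a contig
#'
#' Scans for the longest r with `prefix(r) == suffix(r)` (exact match; N
#' never matches another base) and classifies the contig as circular when
#' that repeat length lies within `[min_len, max_len]`. Repeats longer than
#' `max_len` are reported as not circular with their own reason code: the
#' length window is an artifact filter, not a cap on repeat biology.
#'
#' @param seq a single DNA string
#' @param min_len,max_len accepted repeat-length window in bp
#' @param max_mismatch reserved; only 0 (exact match) is supported
#' @return a list of class `circularity_call` with elements `is_circular`,
#'   `repeat_length` (NA when none), `canonical_seq` (the contig with the
#'   duplicated suffix removed; NA when not circular), `reason` (one of
#'   `"ok"`, `"too_short"`, `"no_repeat"`, `"repeat_exceeds_max"`).
#' @export
find_terminal_repeat <- function(seq, min_len = 50, max_len = 200,
                                 max_mismatch = 0) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (max_mismatch != 0)
    stop("only exact terminal repeats (max_mismatch = 0) are supported")
  L <- nchar(seq)
  out <- function(circ, r, reason) {
    structure(list(is_circular = circ,
                   repeat_length = if (circ) r else NA_integer_,
                   found_repeat = r,
                   canonical_seq = if (circ) substr(seq, 1, L - r) else NA_character_,
                   length = L, reason = reason),
              class = "circularity_call")
  }
  if (L < 2 * min_len) return(out(FALSE, NA_integer_, "too_short"))

  # scan the widest window (up to L/2) so an over-long repeat can still be
  # classified with its own reason code
  v <- dna_to_int(seq)
  r <- cpp_terminal_repeat(v, min_len, floor(L / 2))
  if (r == 0) return(out(FALSE, NA_integer_, "no_repeat"))
  if (r > max_len) return(out(FALSE, r, "repeat_exceeds_max"))
  out(TRUE, r, "ok")
}

#' Screen a contig set for circularity
#'
#' @param contigs named character vector of contig sequences
#' @inheritParams find_terminal_repeat
#' @return data frame with columns `contig_id`, `length`, `is_circular`,
#'   `repeat_length`, `reason`; the trimmed sequences of circular contigs are
#'   attached as the named character vector attribute `"canonical"`.
#' @export
screen_circular <- function(contigs, min_len = 50, max_len = 200) {
  calls <- lapply(contigs, find_terminal_repeat,
                  min_len = min_len, max_len = max_len)
  df <- data.frame(
    contig_id = names(contigs),
    length = vapply(calls, `[[`, 0L, "length"),
    is_circular = vapply(calls, `[[`, TRUE, "is_circular"),
    repeat_length = vapply(calls, `[[`, 0L, "repeat_length"),
    reason = vapply(calls, `[[`, "", "reason"),
    row.names = NULL)
  canon <- vapply(calls, `[[`, "", "canonical_seq")
  attr(df, "canonical") <- stats::setNames(canon[df$is_circular],
                                           df$contig_id[df$is_circular])
  df
}

#' Canonical form of a circular genome
#'
#' Trims the duplicated terminal repeat and returns the lexicographically
#' least rotation of the remaining sequence, so every rotation of the same
#' circular genome maps to one canonical string.
#'
#' @param call a `circularity_call` from [find_terminal_repeat()], or a bare
#'   DNA string taken to be already trimmed
#' @return a single DNA string
#' @export
canonicalize <- function(call) {
  if (inherits(call, "circularity_call")) {
    if (!isTRUE(call$is_circular))
      stop("canonicalize() requires a circular call")
    s <- call$canonical_seq
  } else {
    stopifnot(is.character(call), length(call) == 1)
    s <- call
  }
  least_rotation(s)
}

#' @rdname canonicalize
#' @param s a DNA string
#' @export
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(s)
  d <- paste0(s, s)
  v <- as.integer(charToRaw(d))
  cand <- which(v[1:n] == min(v[1:n]))
  depth <- 1L
  while (length(cand) > 1 && depth < n) {
    nxt <- v[cand + depth]
    cand <- cand[nxt == min(nxt)]
    depth <- depth + 1L
    # identical candidates separated by a period: keep the earliest
    if (length(cand) > 1 && depth >= n) break
  }
  substr(d, cand[1], cand[1] + n - 1)
}
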