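# Microhomology enumeration, MMEJ product prediction and junction
# microhomology measurement.

#' Enumerate microhomology pairs flanking a cut window
#'
#' Finds every pair of identical substrings (direct repeats) of length
#' `>= min_len` that straddle the cut: the left copy ends at or before the
#' cut window's end, the right copy starts at or after the cut window's
#' start, both within `search_window` nt of the window. Copies may abut the
#' window and each other but never overlap. Only maximal pairs are reported:
#' a pair whose flanking bases still agree on both copies (i.e. that could be
#' extended and remain identical) is dropped in favour of its extension.
#'
#' @param reference reference sequence (character).
#' @param cut_window inclusive pair of 0-based gap coordinates, e.g. from
#'   [cut_positions()].
#' @param search_window how far (nt) from the cut window each copy may lie.
#' @param min_len minimum microhomology length (nt). The default 2 nt is the
#'   smallest signature that distinguishes a microhomology-guided join from a
#'   blunt join.
#' @return A `data.frame` with 0-based half-open copy intervals
#'   (`left_start`, `left_end`, `right_start`, `right_end`), `mh_seq`,
#'   `mh_len` and `deletion_len` (`right_start - left_start`), sorted by
#'   `mh_len` descending then `deletion_len` ascending.
#' @examples
#' enumerate_microhomologies("TTAGGCATCAGGCTAA", c(7, 8), 8, 4)
#' @export
enumerate_microhomologies <- function(reference, cut_window,
                                      search_window = 30L, min_len = 2L) {
  stopifnot(min_len >= 1L, search_window >= min_len)
  ref <- toupper(as.character(reference)[1])
  n <- nchar(ref)
  l <- as.integer(cut_window[1]); r <- as.integer(cut_window[2])
  if (l < 0L || r > n || l > r)
    stop("cut_window outside reference bounds")
  s <- strsplit(ref, "")[[1]]
  rows <- list()
  # Two copies at offset delta satisfy ref[a+i] == ref[a+delta+i]; for each
  # offset, maximal agreement runs of s[i] == s[i+delta] are exactly the
  # maximal (non-extendable) repeat pairs.
  delta_max <- min(n - min_len, r + search_window)
  if (delta_max >= 1L) {
    for (delta in 1:delta_max) {
      m <- n - delta
      if (m < min_len) break
      agree <- s[1:m] == s[(1L + delta):n]
      rl <- rle(agree)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in which(rl$values & rl$lengths >= min_len)) {
        a <- starts[k] - 1L              # 0-based run start
        b <- a + rl$lengths[k]           # 0-based half-open run end
        cc <- a + delta; d <- b + delta
        if (cc < b) next                 # copies must not overlap
        # straddle + search window: left copy ends at/before cut_window end
        # and within search_window of its start; right copy mirrored.
        if (b > r || b < l - search_window) next
        if (cc < l || cc > r + search_window) next
        rows[[length(rows) + 1L]] <- data.frame(
          left_start = a, left_end = b, right_start = cc, right_end = d,
          mh_seq = substr(ref, a + 1L, b), mh_len = b - a,
          deletion_len = delta, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      mh_seq = character(), mh_len = integer(),
                      deletion_len = integer(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out <- out[order(-out$mh_len, out$deletion_len, out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict MMEJ deletion products
#'
#' For each microhomology pair, microhomology-mediated end joining anneals
#' the two copies and resolves by deleting `[left_start, right_start)` —
#' one repeat copy plus everything between the copies — leaving a single
#' copy in the product. Products with identical sequence are deduplicated
#' (first in pair order kept).
#'
#' @param pairs output of [enumerate_microhomologies()] on `reference`.
#' @param reference the same reference sequence.
#' @return A `data.frame` with `deletion_start`, `deletion_end` (0-based
#'   half-open), `deletion_len`, `mh_seq`, `mh_len`, `product_seq`, and
#'   `frameshift` (`deletion_len %% 3 != 0`).
#' @examples
#' p <- enumerate_microhomologies("TTAGGCATCAGGCTAA", c(7, 8), 8, 4)
#' predict_mmej_products(p, "TTAGGCATCAGGCTAA")
#' @export
predict_mmej_products <- function(pairs, reference) {
  ref <- toupper(as.character(reference)[1])
  if (nrow(pairs) == 0L)
    return(data.frame(deletion_start = integer(), deletion_end = integer(),
                      deletion_len = integer(), mh_seq = character(),
                      mh_len = integer(), product_seq = character(),
                      frameshift = logical(), stringsAsFactors = FALSE))
  a <- pairs$left_start; cc <- pairs$right_start
  product <- paste0(substring(ref, 1L, a), substring(ref, cc + 1L))
  out <- data.frame(deletion_start = a, deletion_end = cc,
                    deletion_len = cc - a, mh_seq = pairs$mh_seq,
                    mh_len = pairs$mh_len, product_seq = product,
                    frameshift = (cc - a) %% 3L != 0L,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$product_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Junction microhomology of an observed deletion
#'
#' Measures how far a deletion can be slid left or right without changing
#' the deleted product — the signature of microhomology at the junction.
#' `mh_len` is the total number of alternative placements (left shifts +
#' right shifts), equal to the length of the longest exact match between the
#' sequence just inside the deletion and the flanking sequence on the
#' corresponding side.
#'
#' @param reference reference sequence.
#' @param deletion 0-based half-open interval `c(start, end)`, width >= 1.
#' @return A list with `mh_len` and `ambiguity_interval`, the inclusive
#'   range of gap coordinates at which the deletion's left edge can be
#'   placed (width equals `mh_len`).
#' @examples
#' junction_microhomology("TTAGGCATCAGGCTAA", c(6, 13))  # mh_len 4
#' @export
junction_microhomology <- function(reference, deletion) {
  ref <- toupper(as.character(reference)[1])
  n <- nchar(ref)
  dl <- as.integer(deletion[1]); dr <- as.integer(deletion[2])
  if (dl < 0L || dr > n || dr - dl < 1L)
    stop("deletion interval out of bounds or empty")
  s <- strsplit(ref, "")[[1]]
  right <- 0L  # slide right: ref[dl+right] == ref[dr+right]
  while (dl + right + 1L <= n && dr + right + 1L <= n &&
         s[dl + right + 1L] == s[dr + right + 1L])
    right <- right + 1L
  left <- 0L   # slide left: ref[dl-1-left] == ref[dr-1-left]
  while (dl - left >= 1L && dr - left >= 1L &&
         s[dl - left] == s[dr - left])
    left <- left + 1L
  list(mh_len = left + right,
       ambiguity_interval = c(dl - left, dl + right))
}

#' Write a microhomology report
#'
#' TSV with 1-based copy start coordinates
#' (`mh_seq`, `mh_len`, `left_start_1based`, `right_start_1based`,
#' `deletion_len`, `frameshift`).
#'
#' @param pairs output of [enumerate_microhomologies()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mh_report <- function(pairs, path) {
  out <- data.frame(
    mh_seq = pairs$mh_seq, mh_len = pairs$mh_len,
    left_start_1based = pairs$left_start + 1L,
    right_start_1based = pairs$right_start + 1L,
    deletion_len = pairs$deletion_len,
    frameshift = pairs$deletion_len %% 3L != 0L,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
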