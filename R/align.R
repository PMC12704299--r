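# Read QC, pair merging, global alignment and left-normalized indel calling.

#' Alignment scoring parameters
#'
#' Defaults favour one long gap over scattered mismatches, matching the
#' single-deletion alleles that dominate nuclease-edited amplicons: an
#' L-base gap costs `gap_open + L * gap_extend` (-6 - L at defaults) while a
#' mismatch costs -2.
#'
#' @param match match score.
#' @param mismatch mismatch score.
#' @param gap_open cost of opening a gap run (negative).
#' @param gap_extend per-base gap cost (negative).
#' @return A named list.
#' @export
align_scoring <- function(match = 2, mismatch = -2,
                          gap_open = -6, gap_extend = -1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Construct a read record
#'
#' @param id read identifier.
#' @param seq read sequence.
#' @param quals optional integer vector of per-base Phred qualities, same
#'   length as `seq`.
#' @return A list of class `read_record`.
#' @export
read_record <- function(id, seq, quals = NULL) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("read sequence must be non-empty")
  if (!is.null(quals) && length(quals) != nchar(seq))
    stop("quals must have one entry per base")
  structure(list(id = id, seq = seq, quals = quals), class = "read_record")
}

#' Merge a read pair into a consensus fragment
#'
#' `r2` is given in sequencing orientation and is reverse-complemented
#' before the best ungapped overlap with `r1` is sought. The merge succeeds
#' when the best overlap is at least `min_overlap` nt with at most
#' `max_mismatch_frac` disagreeing positions; at disagreements the
#' higher-quality base wins (ties go to `r1`). Failure is a value (`NULL`),
#' not an error, so callers can count unmerged pairs.
#'
#' @param r1,r2 [read_record()]s.
#' @param min_overlap minimum overlap length in nt.
#' @param max_mismatch_frac maximum fraction of mismatching positions in the
#'   overlap.
#' @return A merged [read_record()], or `NULL` on failure.
#' @export
merge_read_pair <- function(r1, r2, min_overlap = 20L,
                            max_mismatch_frac = 0.1) {
  s1 <- strsplit(r1$seq, "")[[1]]
  rc2 <- revcomp(r2$seq)
  s2 <- strsplit(rc2, "")[[1]]
  q1 <- if (is.null(r1$quals)) rep(30L, length(s1)) else r1$quals
  q2 <- if (is.null(r2$quals)) rep(30L, length(s2)) else rev(r2$quals)
  n1 <- length(s1); n2 <- length(s2)
  best <- NULL; best_score <- -Inf
  for (off in 0:max(0L, n1 - min_overlap)) {
    ov <- min(n1 - off, n2)
    if (ov < min_overlap && !(off == 0L && ov == min(n1, n2))) next
    if (ov < 1L) next
    i1 <- (off + 1L):(off + ov)
    mm <- sum(s1[i1] != s2[1:ov])
    if (mm > max_mismatch_frac * ov) next
    score <- (ov - mm) - mm
    if (score > best_score) { best_score <- score; best <- list(off = off, ov = ov, mm = mm) }
  }
  if (is.null(best)) return(NULL)
  off <- best$off; ov <- best$ov
  total <- max(n1, off + n2)
  seq_out <- character(total); qual_out <- integer(total)
  seq_out[1:n1] <- s1; qual_out[1:n1] <- q1
  if (off + n2 > n1) {
    tail_idx <- (n1 + 1L):(off + n2)
    seq_out[tail_idx] <- s2[(n1 - off + 1L):n2]
    qual_out[tail_idx] <- q2[(n1 - off + 1L):n2]
  }
  # consensus in the overlap: higher quality wins, tie -> r1
  i1 <- (off + 1L):(off + ov)
  take2 <- q2[1:ov] > q1[i1]
  seq_out[i1][take2] <- s2[1:ov][take2]
  qual_out[i1] <- pmax(q1[i1], q2[1:ov])
  read_record(r1$id, paste(seq_out, collapse = ""), qual_out)
}

#' Length filter for reads
#'
#' @param reads list of [read_record()]s.
#' @param min_len minimum length kept (nt). The default drops fragments too
#'   short to align informatively against an amplicon.
#' @return `list(kept = <reads>, discarded_count = <int>)`.
#' @export
qc_filter <- function(reads, min_len = 50L) {
  if (length(reads) == 0L) return(list(kept = list(), discarded_count = 0L))
  keep <- vapply(reads, function(r) nchar(r$seq) >= min_len, logical(1))
  list(kept = reads[keep], discarded_count = sum(!keep))
}

#' Global alignment of a read against a reference
#'
#' Optimal global alignment under affine-gap scoring (see
#' [align_scoring()]), computed by a three-state Needleman-Wunsch/Gotoh
#' dynamic program with deterministic traceback (diagonal preferred over a
#' gapped read base, preferred over a gapped reference base, at ties).
#' `N` in either sequence matches nothing and scores as a mismatch.
#'
#' @param read read sequence (character, ACGTN).
#' @param reference reference sequence (character, ACGTN).
#' @param scoring a score set from [align_scoring()].
#' @return A list of class `aligned_read` with `score`, the gapped rows
#'   `ref_aln`/`read_aln`, `identity` (matching columns / total columns) and
#'   `events`, the left-normalized [call_indels()] output.
#' @examples
#' global_align("ACGACGT", "ACGTACGT")$events
#' @export
global_align <- function(read, reference, scoring = align_scoring()) {
  read <- toupper(as.character(read)[1])
  reference <- toupper(as.character(reference)[1])
  if (!grepl("^[ACGTN]+$", read) || !grepl("^[ACGTN]+$", reference))
    stop("sequences must contain only A, C, G, T, N")
  aln <- .gotoh_align(read, reference, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  ra <- strsplit(aln$ref_aln, "")[[1]]
  qa <- strsplit(aln$read_aln, "")[[1]]
  out <- list(score = aln$score, ref_aln = aln$ref_aln,
              read_aln = aln$read_aln,
              identity = sum(ra == qa & ra != "-") / length(ra))
  out$events <- call_indels_gapped(ra, qa, reference)
  class(out) <- "aligned_read"
  out
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read> score %.1f, identity %.3f, %d event(s)\n",
              x$score, x$identity, nrow(x$events)))
  invisible(x)
}

empty_events <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             alt = character(), normalized = logical(),
             stringsAsFactors = FALSE)
}

#' Call indel events from an alignment
#'
#' Converts the gapped rows of an [global_align()] result into a table of
#' events: contiguous gap runs become single insertion or deletion events,
#' aligned mismatches become substitutions (never merged with gaps), and
#' every indel is left-normalized — shifted to the smallest reference
#' coordinate that preserves the read sequence, the conventional placement
#' inside repeats and homopolymers.
#'
#' @param aln an `aligned_read`.
#' @param reference reference sequence the read was aligned to.
#' @return A `data.frame` with `kind` (`insertion`/`deletion`/
#'   `substitution`), 0-based half-open `start`/`end` on the reference
#'   (width 0 for insertions), `alt` (inserted bases or substituted base,
#'   empty for deletions) and `normalized`, sorted by reference coordinate.
#' @export
call_indels <- function(aln, reference) {
  ra <- strsplit(aln$ref_aln, "")[[1]]
  qa <- strsplit(aln$read_aln, "")[[1]]
  call_indels_gapped(ra, qa, toupper(as.character(reference)[1]))
}

call_indels_gapped <- function(ra, qa, reference) {
  ncol <- length(ra)
  ref_pos <- cumsum(ra != "-")          # reference bases consumed up to col
  is_del <- qa == "-"
  is_ins <- ra == "-"
  is_sub <- !is_del & !is_ins & ra != qa
  events <- list()
  add <- function(kind, start, end, alt) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, start = start, end = end, alt = alt,
      stringsAsFactors = FALSE)
  }
  for (v in list(list(mask = is_del, kind = "deletion"),
                 list(mask = is_ins, kind = "insertion"))) {
    r <- rle(v$mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cs <- starts[k]; ce <- ends[k]
      if (v$kind == "deletion") {
        add("deletion", ref_pos[cs] - 1L, ref_pos[ce], "")
      } else {
        add("insertion", ref_pos[cs], ref_pos[cs],
            paste(qa[cs:ce], collapse = ""))
      }
    }
  }
  for (k in which(is_sub))
    add("substitution", ref_pos[k] - 1L, ref_pos[k], qa[k])
  if (length(events) == 0L) return(empty_events())
  ev <- do.call(rbind, events)
  normalize_indels(ev, reference)
}

#' Left-normalize indel events
#'
#' Shifts each insertion and deletion to its smallest reference coordinate
#' that leaves the implied read sequence unchanged (deletions slide while
#' the base before the deletion equals the base before its end; insertions
#' rotate while the last inserted base equals the base left of the
#' insertion point). Substitutions are untouched. Idempotent.
#'
#' @param events event `data.frame` as produced by [call_indels()].
#' @param reference reference sequence.
#' @return The normalized, coordinate-sorted event table with
#'   `normalized = TRUE`.
#' @export
normalize_indels <- function(events, reference) {
  if (nrow(events) == 0L) {
    events$normalized <- logical(0)
    return(events)
  }
  s <- strsplit(toupper(as.character(reference)[1]), "")[[1]]
  for (k in seq_len(nrow(events))) {
    kind <- events$kind[k]
    if (kind == "deletion") {
      a <- events$start[k]; b <- events$end[k]
      while (a > 0L && s[a] == s[b]) { a <- a - 1L; b <- b - 1L }
      events$start[k] <- a; events$end[k] <- b
    } else if (kind == "insertion") {
      g <- events$start[k]
      alt <- strsplit(events$alt[k], "")[[1]]
      while (g > 0L && s[g] == alt[length(alt)]) {
        alt <- c(s[g], alt[-length(alt)])
        g <- g - 1L
      }
      events$start[k] <- g; events$end[k] <- g
      events$alt[k] <- paste(alt, collapse = "")
    }
  }
  events$normalized <- TRUE
  events <- events[order(events$start, events$end, events$kind, events$alt), ,
                   drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Apply events to a reference
#'
#' Reconstructs the read implied by an event table, applying events
#' right-to-left so earlier coordinates stay valid. Events must not
#' overlap.
#'
#' @param reference reference sequence.
#' @param events event `data.frame` (see [call_indels()]).
#' @return The edited sequence (character).
#' @export
apply_events <- function(reference, events) {
  ref <- toupper(as.character(reference)[1])
  if (nrow(events) == 0L) return(ref)
  ev <- events[order(-events$start, -events$end), , drop = FALSE]
  # overlap check on the sorted (descending) intervals
  fwd <- events[order(events$start, events$end), , drop = FALSE]
  if (nrow(fwd) > 1L) {
    for (k in 2:nrow(fwd)) {
      prev_end <- fwd$end[k - 1L]
      # two zero-width insertions at the same gap are still an overlap
      if (fwd$start[k] < prev_end ||
          (fwd$start[k] == prev_end && fwd$end[k - 1L] == fwd$start[k - 1L] &&
           fwd$end[k] == fwd$start[k]))
        stop("events overlap")
    }
  }
  out <- ref
  for (k in seq_len(nrow(ev))) {
    a <- ev$start[k]; b <- ev$end[k]
    left <- substr(out, 1L, a)
    right <- substring(out, b + 1L)
    mid <- if (ev$kind[k] == "deletion") "" else ev$alt[k]
    out <- paste0(left, mid, right)
  }
  out
}

## ---- sequence file IO -----------------------------------------------------

#' Read a FASTA reference
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of uppercase sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read FASTQ reads
#'
#' @param path FASTQ file (optionally gzipped).
#' @return A list of [read_record()]s with integer Phred qualities.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping the (empty) mcols of plain FASTQ input;
  # nothing is lost
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- suppressWarnings(as.character(x))
  quals <- suppressWarnings(as(Biostrings::quality(x), "IntegerList"))
  ids <- sub("\\s.*$", "", names(x))
  lapply(seq_along(x), function(i)
    read_record(ids[i], seqs[i], as.integer(quals[[i]])))
}

#' Write FASTQ reads
#'
#' @param reads list of [read_record()]s; reads without qualities are
#'   written at a constant Q30.
#' @param path output FASTQ path (`.gz` suffix enables compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    q <- if (is.null(r$quals)) rep(30L, nchar(r$seq)) else r$quals
    writeLines(c(paste0("@", r$id), r$seq, "+",
                 intToUtf8(q + 33L, multiple = FALSE)), con)
  }
  invisible(path)
}
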