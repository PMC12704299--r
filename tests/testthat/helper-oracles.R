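# Independent oracles and fixture builders used across the suite. Each
# oracle re-derives a quantity by exhaustive/brute-force means, structured
# differently from the implementation it checks.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc_oracle <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Exhaustive affine-gap global alignment score by recursion over all move
# sequences. A maximal gap run of length L costs gap_open + L * gap_extend;
# the open is charged at the rightmost base of each run (recursing
# right-to-left, when the move to the right was a different kind).
brute_align_score <- function(x, y, sc = list(match = 2, mismatch = -2,
                                              gap_open = -6,
                                              gap_extend = -1)) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  rec <- function(i, j, right_move) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (xs[i] == ys[j] && xs[i] != "N") sc$match else sc$mismatch
      best <- max(best, rec(i - 1L, j - 1L, "M") + s)
    }
    if (i > 0L) {
      cost <- sc$gap_extend + if (right_move == "I") 0 else sc$gap_open
      best <- max(best, rec(i - 1L, j, "I") + cost)
    }
    if (j > 0L) {
      cost <- sc$gap_extend + if (right_move == "D") 0 else sc$gap_open
      best <- max(best, rec(i, j - 1L, "D") + cost)
    }
    best
  }
  rec(length(xs), length(ys), "none")
}

# All maximal microhomology pairs straddling the cut, by direct substring
# comparison over every (left end, right start, length) triple.
brute_mh_pairs <- function(ref, cut_window, sw, mn) {
  n <- nchar(ref); s <- strsplit(ref, "")[[1]]
  l <- cut_window[1]; r <- cut_window[2]
  rows <- list()
  for (a in 0:(n - 1L)) {
    if (a + mn > min(n, r)) next
    for (b in (a + mn):min(n, r)) {
      len <- b - a
      if (b < l - sw) next
      lo <- max(b, l); hi <- min(n - len, r + sw)
      if (lo > hi) next
      for (cc in lo:hi) {
        d <- cc + len
        if (substr(ref, a + 1L, b) != substr(ref, cc + 1L, d)) next
        if (a > 0L && cc > 0L && s[a] == s[cc]) next          # extendable left
        if (b < n && d < n && s[b + 1L] == s[d + 1L]) next    # extendable right
        rows[[length(rows) + 1L]] <- data.frame(
          left_start = a, left_end = b, right_start = cc, right_end = d,
          mh_len = len, deletion_len = cc - a, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      mh_len = integer(), deletion_len = integer()))
  out <- do.call(rbind, rows)
  out[order(out$left_start, out$right_start, out$mh_len), , drop = FALSE]
}

# Per-position off-target scan using substring extraction and match_pam.
brute_offtarget <- function(spacer, db, profile, max_mm) {
  glen <- nchar(spacer)
  plen <- nchar(profile$pam_pattern)
  gch <- strsplit(spacer, "")[[1]]
  rows <- list()
  for (sid in names(db)) {
    for (strand in c("plus", "minus")) {
      sq <- if (strand == "plus") db[[sid]] else rc_oracle(db[[sid]])
      n <- nchar(sq)
      for (a in 0:(n - glen)) {
        if (profile$pam_side == "three_prime") {
          pp <- a + glen
        } else {
          pp <- a - plen
        }
        if (pp < 0L || pp + plen > n) next
        pam <- substr(sq, pp + 1L, pp + plen)
        if (!match_pam(pam, profile$pam_pattern)) next
        sch <- strsplit(substr(sq, a + 1L, a + glen), "")[[1]]
        mm <- sum(sch != gch | sch == "N")
        if (mm > max_mm) next
        st <- if (strand == "plus") a else n - (a + glen)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = sid, strand = strand, site_start = st,
          site_end = st + glen, mismatch_count = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(sequence_id = character(), strand = character(),
                      site_start = integer(), site_end = integer(),
                      mismatch_count = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$sequence_id, out$site_start, out$strand != "plus"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Split an allele sequence into a simulated 2x150 read pair (no errors).
frag_to_pair <- function(id, frag, rlen = 150L) {
  fl <- nchar(frag)
  r1 <- substr(frag, 1L, min(rlen, fl))
  r2 <- rc_oracle(substring(frag, max(1L, fl - rlen + 1L), fl))
  list(r1 = read_record(id, r1), r2 = read_record(id, r2))
}

trbc_amplicon <- function() bundled_amplicons()["TRBC1_2"]

craft_site <- function() {
  locate_target(guide("CRAFT_crRNA", bundled_guides()[["CRAFT_crRNA"]]),
                trbc_amplicon(), nuclease_profile("AsCas12a"))
}

sgrna_site <- function() {
  locate_target(guide("TRBC_sgRNA", bundled_guides()[["TRBC_sgRNA"]]),
                trbc_amplicon(), nuclease_profile("SpCas9"))
}
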