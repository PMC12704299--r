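# Allele collapsing and five-category repair-outcome classification.

CATEGORIES <- c("wt_or_sub", "insertion", "deletion_on_position",
                "deletion_off_position")

#' Canonical allele key
#'
#' Deterministic, injective encoding of a normalized, sorted event list.
#' Substitutions are excluded: they do not define alleles, so
#' substitution-only reads share the `"WT"` key with unedited reads.
#'
#' @param events normalized event `data.frame` (see [call_indels()]).
#' @return A single string, `"WT"` for indel-free event lists.
#' @examples
#' canonical_allele_key(data.frame(kind = "deletion", start = 76, end = 84,
#'                                 alt = ""))
#' @export
canonical_allele_key <- function(events) {
  ev <- events[events$kind %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(ev) == 0L) return("WT")
  ev <- ev[order(ev$start, ev$end, ev$kind, ev$alt), , drop = FALSE]
  paste(ifelse(ev$kind == "deletion",
               sprintf("D%d-%d", ev$start, ev$end),
               sprintf("I%d+%s", ev$start, ev$alt)),
        collapse = ";")
}

#' Classify an allele into the repair-outcome taxonomy
#'
#' Precedence:
#' 1. no insertion or deletion events — `wt_or_sub` (substitution-only reads
#'    count as WT);
#' 2. any insertion — `insertion` (mixed insertion+deletion alleles count
#'    as insertion, keeping the taxonomy a partition);
#' 3. any deletion whose placement-ambiguity span (all equivalent
#'    left/right-shifted placements, from [junction_microhomology()]),
#'    padded by `pad` nt, intersects the cut window — `deletion_on_position`;
#'    the allele is additionally MMEJ-flagged when the junction
#'    microhomology of such a deletion reaches `min_mh` nt;
#' 4. otherwise — `deletion_off_position`.
#'
#' @param events normalized event `data.frame`.
#' @param cut_window inclusive gap-coordinate pair from [cut_positions()].
#' @param reference reference sequence (needed for junction microhomology).
#' @param pad nt of slack around the cut window; 1 nt absorbs alignment
#'   jitter around a point break.
#' @param min_mh junction microhomology (nt) required to flag MMEJ.
#' @return `list(category, mmej, mh_len)`; `mh_len` is the largest junction
#'   microhomology among on-position deletions (0 otherwise).
#' @export
classify_allele <- function(events, cut_window, reference, pad = 1L,
                            min_mh = 2L) {
  ev <- events[events$kind %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(ev) == 0L)
    return(list(category = "wt_or_sub", mmej = FALSE, mh_len = 0L))
  if (any(ev$kind == "insertion"))
    return(list(category = "insertion", mmej = FALSE, mh_len = 0L))
  l <- cut_window[1]; r <- cut_window[2]
  best_mh <- -1L
  for (k in seq_len(nrow(ev))) {
    jm <- junction_microhomology(reference, c(ev$start[k], ev$end[k]))
    width <- ev$end[k] - ev$start[k]
    span_lo <- jm$ambiguity_interval[1]          # leftmost placement start
    span_hi <- jm$ambiguity_interval[2] + width  # rightmost placement end
    if (span_lo - pad <= r && span_hi + pad >= l)
      best_mh <- max(best_mh, jm$mh_len)
  }
  if (best_mh >= 0L)
    return(list(category = "deletion_on_position",
                mmej = best_mh >= min_mh, mh_len = as.integer(best_mh)))
  list(category = "deletion_off_position", mmej = FALSE, mh_len = 0L)
}

#' Collapse per-read events into an allele table
#'
#' Groups reads by [canonical_allele_key()] and classifies each allele once
#' with [classify_allele()].
#'
#' @param events_by_read list of normalized event `data.frame`s, one per
#'   assigned read.
#' @param cut_window,reference,pad,min_mh passed to [classify_allele()].
#' @return A `data.frame` of class `allele_table` with `allele_key`,
#'   `read_count`, `category`, `mmej`, `mh_len`, sorted by `read_count`
#'   descending then `allele_key`.
#' @export
tabulate_alleles <- function(events_by_read, cut_window, reference,
                             pad = 1L, min_mh = 2L) {
  keys <- vapply(events_by_read, canonical_allele_key, character(1))
  counts <- table(keys)
  first_idx <- match(names(counts), keys)
  cls <- lapply(first_idx, function(i)
    classify_allele(events_by_read[[i]], cut_window, reference, pad, min_mh))
  out <- data.frame(
    allele_key = names(counts),
    read_count = as.integer(counts),
    category = vapply(cls, `[[`, character(1), "category"),
    mmej = vapply(cls, `[[`, logical(1), "mmej"),
    mh_len = vapply(cls, `[[`, integer(1), "mh_len"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$allele_key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Summarize an allele table
#'
#' Per-category read counts and fractions over assigned reads, the
#' MMEJ-flagged fraction, and the overall editing efficiency (fraction of
#' reads carrying any indel, i.e. `1 - wt_or_sub` fraction).
#'
#' @param alleles an `allele_table` from [tabulate_alleles()].
#' @return A list of class `classification_summary` with `total_reads`,
#'   `counts`, `fractions` (both named by category), `mmej_fraction` and
#'   `editing_efficiency`.
#' @export
summarize_classification <- function(alleles) {
  if (nrow(alleles) == 0L || sum(alleles$read_count) == 0L)
    stop("no classified reads")
  stopifnot(all(alleles$read_count >= 1L))
  total <- sum(alleles$read_count)
  counts <- vapply(CATEGORIES, function(cat)
    sum(alleles$read_count[alleles$category == cat]), integer(1))
  fractions <- counts / total
  out <- list(total_reads = total, counts = counts, fractions = fractions,
              mmej_fraction = sum(alleles$read_count[alleles$mmej]) / total,
              editing_efficiency = 1 - fractions[["wt_or_sub"]])
  class(out) <- "classification_summary"
  out
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> %d reads\n", x$total_reads))
  for (cat_ in CATEGORIES)
    cat(sprintf("  %-22s %8d  %6.2f%%\n", cat_, x$counts[[cat_]],
                100 * x$fractions[[cat_]]))
  cat(sprintf("  %-22s %8s  %6.2f%%\n", "mmej (within on-pos)", "",
              100 * x$mmej_fraction))
  cat(sprintf("  editing efficiency: %.2f%%\n", 100 * x$editing_efficiency))
  invisible(x)
}

#' Top indel alleles
#'
#' Ranks indel-bearing alleles by read count (ties broken by allele key)
#' and reports, per allele, its share of all reads and of indel-bearing
#' reads, plus the joint indel share of the listed alleles.
#'
#' @param alleles an `allele_table`.
#' @param n number of alleles to list.
#' @return `list(table = <data.frame>, joint_indel_share = <fraction>)`.
#' @export
top_alleles <- function(alleles, n = 5L) {
  stopifnot(n >= 1L)
  total <- sum(alleles$read_count)
  indel <- alleles[alleles$category != "wt_or_sub", , drop = FALSE]
  indel_total <- sum(indel$read_count)
  top <- head(indel, n)
  tab <- data.frame(
    allele_key = top$allele_key, read_count = top$read_count,
    category = top$category, mmej = top$mmej,
    ratio_total = if (nrow(top)) top$read_count / total else numeric(0),
    ratio_indel = if (nrow(top)) top$read_count / indel_total else numeric(0),
    stringsAsFactors = FALSE)
  list(table = tab,
       joint_indel_share = if (indel_total > 0L)
         sum(top$read_count) / indel_total else 0)
}

#' Compare two arms of an editing experiment
#'
#' Per category: fraction difference (`a - b`), a Wilson 95% confidence
#' interval for each arm's fraction, and the two-proportion z statistic
#' (pooled standard error) with its two-sided p value.
#'
#' @param a,b `classification_summary` objects.
#' @return A `data.frame`, one row per category plus a row for the
#'   MMEJ-flagged fraction.
#' @export
compare_arms <- function(a, b) {
  rows <- lapply(c(CATEGORIES, "mmej"), function(cat_) {
    if (cat_ == "mmej") {
      x1 <- round(a$mmej_fraction * a$total_reads)
      x2 <- round(b$mmej_fraction * b$total_reads)
    } else {
      x1 <- a$counts[[cat_]]; x2 <- b$counts[[cat_]]
    }
    n1 <- a$total_reads; n2 <- b$total_reads
    p1 <- x1 / n1; p2 <- x2 / n2
    ci1 <- wilson_ci(x1, n1); ci2 <- wilson_ci(x2, n2)
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    data.frame(category = cat_, frac_a = p1, frac_b = p2,
               difference = p1 - p2,
               ci_a_lo = ci1[1], ci_a_hi = ci1[2],
               ci_b_lo = ci2[1], ci_b_hi = ci2[2],
               z = z, p_value = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level.
#' @return `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Render an allele in dash notation
#'
#' Returns the reference-length rendering of a deletion allele with each
#' deleted nucleotide shown as `-`; insertions are appended as
#' `+<seq>@<1-based position>` tags and substitutions shown in place.
#'
#' @param reference reference sequence.
#' @param events normalized event `data.frame`.
#' @return A single string.
#' @export
render_allele <- function(reference, events) {
  s <- strsplit(toupper(as.character(reference)[1]), "")[[1]]
  tags <- character(0)
  for (k in seq_len(nrow(events))) {
    kind <- events$kind[k]
    if (kind == "deletion") {
      s[(events$start[k] + 1L):events$end[k]] <- "-"
    } else if (kind == "substitution") {
      s[events$start[k] + 1L] <- tolower(events$alt[k])
    } else {
      tags <- c(tags, sprintf("+%s@%d", events$alt[k], events$start[k] + 1L))
    }
  }
  paste0(paste(s, collapse = ""),
         if (length(tags)) paste0(" ", paste(tags, collapse = ",")) else "")
}
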