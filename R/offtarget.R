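# PAM-constrained, mismatch-bounded off-target scanning with feature
# annotation.

#' Scan a sequence database for candidate off-target sites
#'
#' Reports every position, on either strand of every database sequence,
#' where the PAM matches the profile's IUPAC pattern exactly and the
#' protospacer differs from the guide spacer by at most `max_mm` Hamming
#' mismatches (no bulges). PAM mismatches are not counted against the
#' budget — the PAM must simply match, the usual convention of
#' PAM-first off-target scanners. `N` in the database matches nothing:
#' it always counts as a mismatch and voids any PAM position (unless the
#' pattern itself says `N`).
#'
#' @param guide a [guide()].
#' @param database named character vector of sequences (or a
#'   `DNAStringSet`), uppercase ACGTN.
#' @param profile a [nuclease_profile()].
#' @param max_mm maximum protospacer mismatches.
#' @return A `data.frame` of class `offtarget_hits`: `sequence_id`,
#'   `strand`, 0-based half-open `site_start`/`site_end` (protospacer on
#'   the plus strand), `mismatch_count`, `site_seq` and `pam_seq` (both in
#'   guide orientation), and `on_target` (`TRUE` for exact matches).
#'   Sorted by (`sequence_id`, `site_start`, strand).
#' @export
scan_offtargets <- function(guide, database, profile, max_mm = 4L) {
  stopifnot(max_mm >= 0L)
  db <- toupper(setNames(as.character(database), names(database)))
  if (is.null(names(db)) || any(names(db) == ""))
    names(db) <- paste0("seq", seq_along(db))
  hits <- list()
  for (sid in names(db)) {
    ref <- db[[sid]]
    if (!grepl("^[ACGTN]*$", ref))
      stop("database sequences must contain only A, C, G, T, N")
    for (strand in c("plus", "minus")) {
      h <- scan_one_strand(guide$spacer, ref, profile, max_mm, strand)
      if (nrow(h)) { h$sequence_id <- sid; hits[[length(hits) + 1L]] <- h }
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(sequence_id = character(), strand = character(),
                      site_start = integer(), site_end = integer(),
                      mismatch_count = integer(), site_seq = character(),
                      pam_seq = character(), on_target = logical(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, hits)
    out <- out[, c("sequence_id", "strand", "site_start", "site_end",
                   "mismatch_count", "site_seq", "pam_seq", "on_target")]
    out <- out[order(out$sequence_id, out$site_start, out$strand != "plus"), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("offtarget_hits", "data.frame")
  out
}

# Vectorized single-strand scan. Minus-strand sites are found by scanning
# the reverse complement and mapping intervals back to plus coordinates.
scan_one_strand <- function(spacer, ref, profile, max_mm, strand) {
  seq_scan <- if (strand == "plus") ref else revcomp(ref)
  n <- nchar(seq_scan)
  glen <- nchar(spacer)
  plen <- nchar(profile$pam_pattern)
  empty <- data.frame(strand = character(), site_start = integer(),
                      site_end = integer(), mismatch_count = integer(),
                      site_seq = character(), pam_seq = character(),
                      on_target = logical(), stringsAsFactors = FALSE)
  if (n < glen + plen) return(empty)
  s <- strsplit(seq_scan, "")[[1]]
  g <- strsplit(spacer, "")[[1]]
  p <- strsplit(profile$pam_pattern, "")[[1]]
  # candidate protospacer starts (0-based) leaving room for the PAM
  if (profile$pam_side == "three_prime") {
    starts <- 0:(n - glen - plen)
    pam_off <- glen
  } else {
    starts <- plen:(n - glen)
    pam_off <- -plen
  }
  if (length(starts) == 0L) return(empty)
  mm <- integer(length(starts))
  for (k in seq_len(glen))
    mm <- mm + (s[starts + k] != g[k])    # N != ACGT: counts as mismatch
  pam_ok <- rep(TRUE, length(starts))
  for (k in seq_len(plen)) {
    base <- s[starts + pam_off + k]
    allowed <- IUPAC_SETS[[p[k]]]
    pam_ok <- pam_ok & (base %in% allowed | (base == "N" & p[k] == "N"))
  }
  keep <- which(pam_ok & mm <= max_mm)
  if (length(keep) == 0L) return(empty)
  st <- starts[keep]
  site_seq <- vapply(st, function(a) substr(seq_scan, a + 1L, a + glen), "")
  pam_seq <- vapply(st, function(a)
    substr(seq_scan, a + pam_off + 1L, a + pam_off + plen), "")
  if (strand == "plus") {
    site_start <- st
  } else {
    site_start <- n - (st + glen)         # map back to plus coordinates
  }
  data.frame(strand = strand, site_start = site_start,
             site_end = site_start + glen, mismatch_count = mm[keep],
             site_seq = site_seq, pam_seq = pam_seq,
             on_target = mm[keep] == 0L, stringsAsFactors = FALSE)
}

#' Read a feature track from BED or GFF3
#'
#' BED is 0-based half-open and is kept as such; GFF3 is 1-based inclusive
#' and converted on read (start - 1). The dialect actually applied is
#' reported in a message so coordinate provenance is explicit.
#'
#' @param path feature file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A `data.frame`: `sequence_id`, 0-based half-open
#'   `start`/`end`, `kind` (`exon`, `gene`, or the raw type), `name`.
#' @export
read_feature_track <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  message(sprintf("read_feature_track: %s parsed as %s (%s input, stored 0-based half-open)",
                  basename(path), toupper(format),
                  if (format == "bed") "0-based half-open" else "1-based inclusive"))
  md <- S4Vectors::mcols(gr)
  kind <- if (!is.null(md$type)) as.character(md$type) else
    if (!is.null(md$name)) guess_kind(as.character(md$name)) else
      rep("exon", length(gr))
  nm <- if (!is.null(md$Name)) as.character(md$Name) else
    if (!is.null(md$name)) as.character(md$name) else
      if (!is.null(md$gene_id)) as.character(md$gene_id) else
        rep(NA_character_, length(gr))
  data.frame(sequence_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # GRanges is 1-based
             end = GenomicRanges::end(gr),
             kind = tolower(kind), name = nm, stringsAsFactors = FALSE)
}

# BED tracks have no type column; a name like "GENE1_exon2" marks an exon,
# anything else is taken as a gene body.
guess_kind <- function(name) ifelse(grepl("exon", name, ignore.case = TRUE),
                                    "exon", "gene")

#' Annotate off-target hits with feature context
#'
#' Annotation precedence is exonic > intronic > intergenic: a hit
#' overlapping any exon interval is `exonic`; otherwise a hit inside a gene
#' body is `intronic`; everything else is `intergenic`. `feature_name` is
#' taken from the overlapped feature (exon first).
#'
#' @param hits output of [scan_offtargets()].
#' @param features feature `data.frame` as from [read_feature_track()].
#' @return `hits` with `annotation` and `feature_name` columns added.
#' @export
annotate_hits <- function(hits, features) {
  hits$annotation <- rep("intergenic", nrow(hits))
  hits$feature_name <- rep(NA_character_, nrow(hits))
  if (nrow(hits) == 0L) return(hits)
  for (lvl in c("gene", "exon")) {   # exon applied last so it wins
    f <- features[features$kind == lvl, , drop = FALSE]
    if (nrow(f) == 0L) next
    q <- IRanges::IRanges(hits$site_start + 1L, hits$site_end)
    s <- IRanges::IRanges(f$start + 1L, f$end)
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same <- hits$sequence_id[qh] == f$sequence_id[sh]
    qh <- qh[same]; sh <- sh[same]
    first <- !duplicated(qh)
    hits$annotation[qh[first]] <- if (lvl == "exon") "exonic" else "intronic"
    hits$feature_name[qh[first]] <- f$name[sh[first]]
  }
  hits
}

#' Write an off-target report
#'
#' TSV with 1-based site coordinates mirroring the usual off-target table
#' layout (site, mismatches, annotation, gene).
#'
#' @param hits annotated hits.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_offtarget_report <- function(hits, path) {
  out <- data.frame(
    sequence_id = hits$sequence_id, strand = hits$strand,
    site_start_1based = hits$site_start + 1L, site_end = hits$site_end,
    site_seq = hits$site_seq, pam = hits$pam_seq,
    mismatches = hits$mismatch_count,
    annotation = if (!is.null(hits$annotation)) hits$annotation else NA,
    feature = if (!is.null(hits$feature_name)) hits$feature_name else NA,
    on_target = hits$on_target, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
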