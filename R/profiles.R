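# Nuclease chemistry, guides, protospacer location and cut-site geometry.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define a nuclease profile
#'
#' A nuclease profile captures where a nuclease expects its PAM relative to
#' the protospacer and where the double-strand break falls. Two presets are
#' built in:
#'
#' * `"SpCas9"` — 3' NGG PAM, blunt cut 3 nt 5' of the PAM (between
#'   protospacer positions 17 and 18 counted from the PAM-distal end).
#' * `"AsCas12a"` — 5' TTTV PAM, staggered cut with nicks after protospacer
#'   positions 18 (non-target strand) and 23 (target strand) counted 1-based
#'   from the PAM-proximal end, giving the canonical 5-nt 5' overhang.
#'
#' All geometry fields are configurable, so engineered variants can be
#' described without code changes.
#'
#' @param name `"SpCas9"`, `"AsCas12a"`, or any identifier when the remaining
#'   arguments are given explicitly.
#' @param pam_pattern IUPAC pattern for the PAM, e.g. `"NGG"`.
#' @param pam_side `"three_prime"` or `"five_prime"` of the protospacer.
#' @param spacer_len_range integer pair, allowed spacer lengths.
#' @param cut_geometry `"blunt"` or `"staggered"`.
#' @param blunt_offset nt from the PAM-proximal protospacer end to the blunt
#'   cut (blunt geometry only).
#' @param stagger_offsets integer pair: 1-based protospacer positions, counted
#'   from the PAM-proximal end, after which the non-target and target strand
#'   are nicked (staggered geometry only). Must be strictly increasing.
#' @return An object of class `nuclease_profile`.
#' @examples
#' nuclease_profile("AsCas12a")
#' @export
nuclease_profile <- function(name,
                             pam_pattern = NULL,
                             pam_side = NULL,
                             spacer_len_range = NULL,
                             cut_geometry = NULL,
                             blunt_offset = NULL,
                             stagger_offsets = NULL) {
  presets <- list(
    SpCas9 = list(pam_pattern = "NGG", pam_side = "three_prime",
                  spacer_len_range = c(17L, 24L), cut_geometry = "blunt",
                  blunt_offset = 3L, stagger_offsets = NULL),
    AsCas12a = list(pam_pattern = "TTTV", pam_side = "five_prime",
                    spacer_len_range = c(18L, 25L), cut_geometry = "staggered",
                    blunt_offset = NULL, stagger_offsets = c(18L, 23L))
  )
  p <- presets[[name]]
  if (is.null(p)) {
    p <- list(pam_pattern = pam_pattern, pam_side = pam_side,
              spacer_len_range = spacer_len_range, cut_geometry = cut_geometry,
              blunt_offset = blunt_offset, stagger_offsets = stagger_offsets)
  } else {
    # explicit arguments override preset fields
    if (!is.null(pam_pattern)) p$pam_pattern <- pam_pattern
    if (!is.null(pam_side)) p$pam_side <- pam_side
    if (!is.null(spacer_len_range)) p$spacer_len_range <- spacer_len_range
    if (!is.null(cut_geometry)) p$cut_geometry <- cut_geometry
    if (!is.null(blunt_offset)) p$blunt_offset <- blunt_offset
    if (!is.null(stagger_offsets)) p$stagger_offsets <- stagger_offsets
  }
  p$name <- name
  chars <- strsplit(p$pam_pattern, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% names(IUPAC_SETS)))
    stop("pam_pattern must be a non-empty string of IUPAC codes")
  p$pam_side <- match.arg(p$pam_side, c("three_prime", "five_prime"))
  p$cut_geometry <- match.arg(p$cut_geometry, c("blunt", "staggered"))
  if (p$cut_geometry == "blunt") {
    if (is.null(p$blunt_offset)) stop("blunt geometry requires blunt_offset")
  } else {
    so <- p$stagger_offsets
    if (is.null(so) || length(so) != 2L || so[1] >= so[2])
      stop("staggered geometry requires stagger_offsets with offsets[1] < offsets[2]")
  }
  structure(p, class = "nuclease_profile")
}

#' @export
print.nuclease_profile <- function(x, ...) {
  cat(sprintf("<nuclease_profile> %s: PAM %s (%s), %s cut\n",
              x$name, x$pam_pattern, x$pam_side, x$cut_geometry))
  invisible(x)
}

#' Define a guide
#'
#' @param id guide identifier.
#' @param spacer spacer sequence, uppercase ACGT only.
#' @param profile optional [nuclease_profile()]; when given, the spacer length
#'   is checked against the profile's allowed range.
#' @return An object of class `guide`.
#' @examples
#' guide("TRBC_sgRNA", "GGAGAATGACGAGTGGACCC", nuclease_profile("SpCas9"))
#' @export
guide <- function(id, spacer, profile = NULL) {
  spacer <- toupper(spacer)
  if (!grepl("^[ACGT]+$", spacer))
    stop("guide spacer must contain only A, C, G, T")
  if (!is.null(profile)) {
    r <- profile$spacer_len_range
    if (nchar(spacer) < r[1] || nchar(spacer) > r[2])
      stop(sprintf("spacer length %d outside profile range [%d, %d]",
                   nchar(spacer), r[1], r[2]))
  }
  structure(list(id = id, spacer = spacer), class = "guide")
}

#' Test a sequence against an IUPAC PAM pattern
#'
#' Each base must belong to the IUPAC class of the corresponding pattern
#' position. An `N` in the sequence is treated as an unknown base: it matches
#' only the pattern code `N`.
#'
#' @param sequence candidate PAM sequence (same length as `pattern`).
#' @param pattern IUPAC pattern, e.g. `"TTTV"`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' match_pam("AGG", "NGG")   # TRUE
#' match_pam("TTTT", "TTTV") # FALSE: V = A/C/G
#' @export
match_pam <- function(sequence, pattern) {
  if (nchar(sequence) != nchar(pattern))
    stop("sequence and pattern must have equal length")
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  if (!all(p %in% names(IUPAC_SETS)))
    stop("pattern contains non-IUPAC characters")
  all(vapply(seq_along(p), function(i) {
    if (s[i] == "N") p[i] == "N" else s[i] %in% IUPAC_SETS[[p[i]]]
  }, logical(1)))
}

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Locate a guide's target sites in a reference
#'
#' Scans both strands of `reference` for exact occurrences of the guide
#' spacer whose adjacent PAM satisfies the profile's IUPAC pattern, and
#' attaches the predicted cut window of each hit. Only exact protospacer
#' matches count here; mismatched binding is the off-target scanner's job
#' ([scan_offtargets()]). `N` in the reference matches no spacer base.
#'
#' @param guide a [guide()].
#' @param reference reference sequence (uppercase ACGTN) or a named
#'   length-1 character vector; the name is used as `reference_id`.
#' @param profile a [nuclease_profile()].
#' @return A `data.frame` of class `target_sites` with 0-based half-open
#'   protospacer and PAM intervals, strand, the PAM sequence in guide
#'   orientation, and the cut window as an inclusive pair of gap coordinates
#'   (`cut_start`, `cut_end`). Rows are ordered by ascending plus-strand
#'   protospacer start, plus strand before minus at ties.
#' @examples
#' amp <- bundled_amplicons()["TRBC1_2"]
#' locate_target(guide("sg", "GGAGAATGACGAGTGGACCC"), amp, nuclease_profile("SpCas9"))
#' @export
locate_target <- function(guide, reference, profile) {
  reference_id <- if (!is.null(names(reference))) names(reference)[1] else "ref"
  ref <- toupper(as.character(reference)[1])
  if (nchar(ref) == 0L) return(empty_sites(reference_id))
  if (!grepl("^[ACGTN]+$", ref))
    stop("reference must contain only A, C, G, T, N")
  if (!grepl("^[ACGT]+$", guide$spacer))
    stop("ambiguous bases in guide spacer are not allowed")
  n <- nchar(ref)
  plen <- nchar(profile$pam_pattern)
  hits <- list()
  for (strand in c("plus", "minus")) {
    pat <- if (strand == "plus") guide$spacer else revcomp(guide$spacer)
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(ref), fixed = TRUE)
    for (k in seq_along(m)) {
      s <- Biostrings::start(m)[k] - 1L       # 0-based
      e <- Biostrings::end(m)[k]              # half-open end
      # PAM interval on the plus strand after strand mapping:
      # three_prime+plus and five_prime+minus put the PAM right of the
      # protospacer; the other two combinations put it left.
      pam_right <- (profile$pam_side == "three_prime") == (strand == "plus")
      if (pam_right) {
        ps <- e; pe <- e + plen
      } else {
        ps <- s - plen; pe <- s
      }
      if (ps < 0L || pe > n) next
      pam_plus <- substr(ref, ps + 1L, pe)
      pam_guide <- if (strand == "plus") pam_plus else revcomp(pam_plus)
      if (!match_pam(pam_guide, profile$pam_pattern)) next
      cw <- cut_window_for(s, e, strand, profile, n)
      hits[[length(hits) + 1L]] <- data.frame(
        reference_id = reference_id, strand = strand,
        proto_start = s, proto_end = e, pam_start = ps, pam_end = pe,
        pam_seq = pam_guide, cut_start = cw[1], cut_end = cw[2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty_sites(reference_id))
  out <- do.call(rbind, hits)
  out <- out[order(out$proto_start, out$strand != "plus"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

empty_sites <- function(reference_id) {
  out <- data.frame(reference_id = character(), strand = character(),
                    proto_start = integer(), proto_end = integer(),
                    pam_start = integer(), pam_end = integer(),
                    pam_seq = character(), cut_start = integer(),
                    cut_end = integer(), stringsAsFactors = FALSE)
  class(out) <- c("target_sites", "data.frame")
  out
}

# Plus-strand gap coordinates of the predicted cut(s) for a protospacer at
# 0-based [s, e) on `strand`. Blunt: a single gap coordinate blunt_offset nt
# from the PAM-proximal end. Staggered: the two nick coordinates from
# stagger_offsets, returned in ascending plus-strand order.
cut_window_for <- function(s, e, strand, profile, ref_len) {
  # PAM-proximal protospacer end on the plus strand: e when the PAM sits
  # right of the protospacer, s when it sits left.
  pam_right <- (profile$pam_side == "three_prime") == (strand == "plus")
  if (profile$cut_geometry == "blunt") {
    g <- if (pam_right) e - profile$blunt_offset else s + profile$blunt_offset
    cuts <- c(g, g)
  } else {
    cuts <- if (pam_right) e - profile$stagger_offsets
            else s + profile$stagger_offsets
    cuts <- sort(cuts)
  }
  if (cuts[1] < 0L || cuts[2] > ref_len)
    stop(sprintf("cut coordinate %d outside reference [0, %d]",
                 if (cuts[1] < 0L) cuts[1] else cuts[2], ref_len))
  as.integer(cuts)
}

#' Predicted cut window of a located target site
#'
#' Returns the inclusive pair of 0-based gap coordinates spanning all
#' predicted cut positions of `site` (one row of [locate_target()] output).
#' For blunt geometry both ends equal the single cut coordinate; for
#' staggered geometry they are the two strand nicks mapped into plus-strand
#' coordinates.
#'
#' @param site a single-row `target_sites` data frame (or one row of it).
#' @param profile the [nuclease_profile()] used to locate the site.
#' @param ref_len reference length in nt (defaults to a bound implied by the
#'   site; pass explicitly to get strict bounds checking).
#' @return Integer pair `c(cut_start, cut_end)`.
#' @export
cut_positions <- function(site, profile, ref_len = NULL) {
  if (nrow(site) != 1L) stop("site must be a single row")
  if (is.null(ref_len)) ref_len <- max(site$proto_end, site$pam_end)
  cut_window_for(site$proto_start, site$proto_end, site$strand, profile,
                 as.integer(ref_len))
}

#' Bundled reference amplicons
#'
#' The TRBC1/2 consensus amplicon (184 nt, covering exon 1 of both TCR beta
#' constant regions) and the TRAC amplicon (176 nt) used throughout the
#' examples, as a named character vector.
#'
#' @return Named character vector of DNA sequences.
#' @export
bundled_amplicons <- function() {
  path <- system.file("extdata", "amplicons.fa", package = "ampedit")
  read_reference(path)
}

#' Bundled guide sequences
#'
#' The four TCR-editing guides used in the worked examples: the CRAFT crRNA
#' (AsCas12a) and TRBC sgRNA (SpCas9) targeting the TRBC1/2 consensus
#' amplicon, plus the DN TRBC crRNA and TRAC crRNA.
#'
#' @return Named character vector of spacer sequences.
#' @export
bundled_guides <- function() {
  c(CRAFT_crRNA = "GCCCTATCCTGGGTCCACTCG",
    TRBC_sgRNA  = "GGAGAATGACGAGTGGACCC",
    DN_TRBC_crRNA = "GGTGTGGGAGATCTCTGCTTC",
    TRAC_crRNA  = "CACATGCAAAGTCAGATTTGT")
}

#' Write a target-site report
#'
#' Emits a TSV with 1-based inclusive coordinates
#' (columns `reference_id`, `strand`, `protospacer_start_1based`,
#' `protospacer_end`, `pam`, `cut_window`).
#'
#' @param sites output of [locate_target()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  out <- data.frame(
    reference_id = sites$reference_id, strand = sites$strand,
    protospacer_start_1based = sites$proto_start + 1L,
    protospacer_end = sites$proto_end,
    pam = sites$pam_seq,
    cut_window = sprintf("%d-%d", sites$cut_start, sites$cut_end),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
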