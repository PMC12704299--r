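# Synthetic amplicon-read generator: allele spectra, read simulation and
# per-read ground truth. The generator applies events to the reference by
# string surgery and never calls the aligner, so generator and pipeline are
# independent code paths for round-trip validation.

#' Read a spectrum configuration
#'
#' Key/value format, one `key value` pair per line, `#` comments allowed.
#' Recognised keys: `label`, `wt`, `insertion`, `deletion_on_position`,
#' `deletion_on_position_mmej` (subset of on-position deletions repaired
#' through microhomology), `deletion_off_position`. Category proportions
#' are normalised by their sum (printed summary values may carry rounding).
#'
#' @param path config file.
#' @return A list with `label` and named numeric `proportions` (summing to
#'   1) plus `mmej` (MMEJ share of all reads).
#' @export
read_spectrum_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[ \t]+")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  label <- if ("label" %in% keys) vals[keys == "label"][1] else
    tools::file_path_sans_ext(basename(path))
  num <- function(k, default = 0) if (k %in% keys)
    as.numeric(vals[keys == k][1]) else default
  props <- c(wt = num("wt"), insertion = num("insertion"),
             deletion_on_position = num("deletion_on_position"),
             deletion_off_position = num("deletion_off_position"))
  mmej <- num("deletion_on_position_mmej")
  total <- sum(props)
  if (total <= 0) stop("spectrum config has no positive category proportions")
  if (mmej > props[["deletion_on_position"]] + 1e-9)
    stop("MMEJ proportion exceeds the on-position deletion proportion")
  list(label = label, proportions = props / total, mmej = mmej / total)
}

#' Bundled arm spectra
#'
#' Paths to the two spectrum configurations shipped with the package: the
#' reported deep-sequencing outcome spectra of TRBC editing with
#' AsCas12a/CRAFT crRNA (`"cas12a_craft"`) and SpCas9/TRBC sgRNA
#' (`"cas9_sgrna"`).
#'
#' @param arm `"cas12a_craft"` or `"cas9_sgrna"`.
#' @return File path.
#' @export
bundled_spectrum <- function(arm = c("cas12a_craft", "cas9_sgrna")) {
  arm <- match.arg(arm)
  system.file("extdata", paste0("spectrum_", arm, ".cfg"),
              package = "ampedit")
}

#' Expand category proportions into a concrete allele spectrum
#'
#' Turns a category-level fixture into named alleles with events:
#'
#' * MMEJ on-position deletions are the top predicted MMEJ products of the
#'   site's microhomology pairs, weighted by microhomology length;
#' * non-MMEJ on-position deletions are random 1-20 nt deletions
#'   overlapping the cut window whose junction microhomology stays below
#'   `min_mh`;
#' * insertions are random 1-10 nt sequences at a cut position;
#' * off-position deletions are random 1-20 nt deletions placed at least
#'   `pad + 5` nt away from the cut window;
#' * WT is the empty allele.
#'
#' Within each random category, allele weights fall off harmonically
#' (1, 1/2, 1/3, ...), emulating the long-tailed allele spectra of real
#' editing data. Every candidate allele is accepted only if
#' [classify_allele()] applied to its own events reproduces the intended
#' category and MMEJ flag, so truth labels agree with the classifier by
#' construction. Deterministic under `seed`.
#'
#' @param fixture list from [read_spectrum_config()] (or equivalent).
#' @param reference reference amplicon sequence.
#' @param site single-row `target_sites` data frame for the edited locus.
#' @param seed integer seed (mandatory).
#' @param n_mmej,n_del_on,n_ins,n_del_off number of distinct alleles drawn
#'   per category.
#' @param search_window,min_mh,pad classification/enumeration parameters,
#'   matching the pipeline defaults.
#' @return A list of allele specs: `label`, `events`, `frequency`,
#'   `category`, `mmej`. Frequencies sum to 1.
#' @export
build_spectrum <- function(fixture, reference, site, seed,
                           n_mmej = 3L, n_del_on = 6L, n_ins = 3L,
                           n_del_off = 4L, search_window = 30L,
                           min_mh = 2L, pad = 1L) {
  set.seed(seed)
  ref <- toupper(as.character(reference)[1])
  n <- nchar(ref)
  cw <- c(site$cut_start, site$cut_end)
  props <- fixture$proportions
  mmej_frac <- fixture$mmej
  del_on_plain <- props[["deletion_on_position"]] - mmej_frac
  if (del_on_plain < -1e-9) stop("MMEJ fraction exceeds on-position fraction")
  del_on_plain <- max(0, del_on_plain)
  alleles <- list()
  # duplicate draws (same canonical key) merge their frequency into the
  # existing allele so category marginals stay exactly at the fixture values
  add <- function(label, events, freq, category, mmej) {
    key <- canonical_allele_key(events)
    for (i in seq_along(alleles)) {
      if (canonical_allele_key(alleles[[i]]$events) == key) {
        alleles[[i]]$frequency <<- alleles[[i]]$frequency + freq
        return(invisible(NULL))
      }
    }
    alleles[[length(alleles) + 1L]] <<- list(
      label = label, events = events, frequency = freq,
      category = category, mmej = mmej)
  }
  wt_events <- empty_events()
  if (props[["wt"]] > 0)
    add("WT", wt_events, props[["wt"]], "wt_or_sub", FALSE)

  if (mmej_frac > 0) {
    pairs <- enumerate_microhomologies(ref, cw, search_window, min_mh)
    prods <- predict_mmej_products(pairs, ref)
    if (nrow(prods) == 0L)
      stop("spectrum requests MMEJ alleles but the reference has no ",
           "microhomology pair near the cut")
    prods <- head(prods, n_mmej)
    w <- prods$mh_len / sum(prods$mh_len)
    for (k in seq_len(nrow(prods))) {
      ev <- normalize_indels(data.frame(
        kind = "deletion", start = prods$deletion_start[k],
        end = prods$deletion_end[k], alt = "", stringsAsFactors = FALSE), ref)
      cls <- classify_allele(ev, cw, ref, pad, min_mh)
      stopifnot(cls$category == "deletion_on_position", cls$mmej)
      add(sprintf("MMEJ_del%d_mh%d", prods$deletion_len[k], prods$mh_len[k]),
          ev, mmej_frac * w[k], "deletion_on_position", TRUE)
    }
  }

  draw_deletion <- function(want_on, want_mmej) {
    for (try in 1:500) {
      len <- sample(1:20, 1L)
      if (want_on) {
        # deletion must overlap the cut window
        lo <- max(0L, cw[1] - len + 1L)
        hi <- min(n - len, cw[2] - 1L + len)
        if (lo > hi) next
        a <- sample(lo:hi, 1L)
      } else {
        margin <- pad + 5L
        left_hi <- cw[1] - margin - len
        right_lo <- cw[2] + margin
        cand <- c(if (left_hi >= 5L) seq(5L, left_hi) else integer(0),
                  if (right_lo <= n - len - 5L)
                    seq(right_lo, n - len - 5L) else integer(0))
        if (length(cand) == 0L) next
        a <- sample(cand, 1L)
      }
      ev <- normalize_indels(data.frame(
        kind = "deletion", start = a, end = a + len, alt = "",
        stringsAsFactors = FALSE), ref)
      cls <- classify_allele(ev, cw, ref, pad, min_mh)
      target <- if (want_on) "deletion_on_position" else "deletion_off_position"
      if (cls$category == target && cls$mmej == want_mmej) return(ev)
    }
    stop("could not draw a deletion allele matching the requested category")
  }

  harmonic <- function(k) { w <- 1 / seq_len(k); w / sum(w) }

  if (del_on_plain > 0) {
    w <- harmonic(n_del_on)
    for (k in seq_len(n_del_on))
      add(sprintf("del_on_%d", k), draw_deletion(TRUE, FALSE),
          del_on_plain * w[k], "deletion_on_position", FALSE)
  }
  if (props[["insertion"]] > 0) {
    w <- harmonic(n_ins)
    for (k in seq_len(n_ins)) {
      len <- sample(1:10, 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      g <- sample(cw[1]:cw[2], 1L)
      ev <- normalize_indels(data.frame(
        kind = "insertion", start = g, end = g, alt = ins,
        stringsAsFactors = FALSE), ref)
      add(sprintf("ins_%d", k), ev, props[["insertion"]] * w[k],
          "insertion", FALSE)
    }
  }
  if (props[["deletion_off_position"]] > 0) {
    w <- harmonic(n_del_off)
    for (k in seq_len(n_del_off))
      add(sprintf("del_off_%d", k), draw_deletion(FALSE, FALSE),
          props[["deletion_off_position"]] * w[k], "deletion_off_position",
          FALSE)
  }
  freqs <- vapply(alleles, `[[`, numeric(1), "frequency")
  for (k in seq_along(alleles)) alleles[[k]]$frequency <- freqs[k] / sum(freqs)
  alleles
}

#' Apply an allele to a reference
#'
#' WT (no events) returns the reference unchanged; otherwise events are
#' applied right-to-left by [apply_events()].
#'
#' @param reference reference sequence.
#' @param allele an allele spec from [build_spectrum()] (or any list with
#'   an `events` data frame).
#' @return The allele sequence.
#' @export
apply_allele <- function(reference, allele) {
  apply_events(reference, allele$events)
}

#' Simulation specification
#'
#' @param reference reference amplicon.
#' @param site single-row `target_sites` data frame.
#' @param spectrum allele list from [build_spectrum()].
#' @param n_reads number of reads (or read pairs).
#' @param error_rate i.i.d. per-base substitution error probability,
#'   `0 <= error_rate < 0.1`.
#' @param mode `"paired_2x150"` (two 150-nt reads from the fragment ends,
#'   the second reverse-complemented, emulating a MiSeq 2x150 amplicon
#'   run) or `"merged"` (one full-fragment read).
#' @param seed integer seed (mandatory).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(reference, site, spectrum, n_reads = 20000L,
                     error_rate = 0.001, mode = c("paired_2x150", "merged"),
                     seed) {
  mode <- match.arg(mode)
  stopifnot(n_reads >= 1L, error_rate >= 0, error_rate < 0.1)
  if (missing(seed)) stop("seed is mandatory")
  freqs <- vapply(spectrum, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("spectrum frequencies must sum to 1")
  structure(list(reference = toupper(as.character(reference)[1]), site = site,
                 spectrum = spectrum, n_reads = as.integer(n_reads),
                 error_rate = error_rate, mode = mode,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate amplicon reads with ground truth
#'
#' Draws an allele per read from the spectrum frequencies, applies i.i.d.
#' per-base substitution errors (errors are substitutions only — simulated
#' sequencing indels would confound the indel taxonomy under test), and
#' emits reads plus one truth record per read. Fully reproducible from the
#' spec's seed. In paired mode, fragments shorter than the read length give
#' truncated reads and are flagged in the truth table.
#'
#' @param spec a [sim_spec()].
#' @return A list with `reads` (merged mode: list of [read_record()]s) or
#'   `r1`/`r2` (paired mode), and `truth`, a `data.frame` with `read_id`,
#'   `allele_label`, `category`, `mmej`, `truncated`.
#' @export
simulate_reads <- function(spec) {
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  allele_seqs <- vapply(spec$spectrum, function(a)
    apply_allele(spec$reference, a), character(1))
  freqs <- vapply(spec$spectrum, `[[`, numeric(1), "frequency")
  labels <- vapply(spec$spectrum, `[[`, character(1), "label")
  cats <- vapply(spec$spectrum, `[[`, character(1), "category")
  mmejs <- vapply(spec$spectrum, `[[`, logical(1), "mmej")
  idx <- sample.int(length(freqs), spec$n_reads, replace = TRUE, prob = freqs)
  ids <- sprintf("read%06d", seq_len(spec$n_reads))
  sub_errors <- function(seqs) {
    vapply(seqs, function(sq) {
      if (spec$error_rate == 0) return(sq)
      ch <- strsplit(sq, "")[[1]]
      hit <- which(runif(length(ch)) < spec$error_rate)
      for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  truncated <- logical(spec$n_reads)
  if (spec$mode == "merged") {
    seqs <- sub_errors(allele_seqs[idx])
    reads <- lapply(seq_len(spec$n_reads), function(i)
      read_record(ids[i], seqs[i], rep(30L, nchar(seqs[i]))))
    out <- list(reads = reads)
  } else {
    frag <- allele_seqs[idx]
    flen <- nchar(frag)
    rlen <- 150L
    truncated <- flen < rlen
    r1_seq <- substr(frag, 1L, pmin(rlen, flen))
    r2_seq <- vapply(seq_along(frag), function(i) {
      a <- max(1L, flen[i] - rlen + 1L)
      revcomp(substring(frag[i], a, flen[i]))
    }, character(1))
    r1_seq <- sub_errors(r1_seq)
    r2_seq <- sub_errors(r2_seq)
    r1 <- lapply(seq_len(spec$n_reads), function(i)
      read_record(ids[i], r1_seq[i], rep(30L, nchar(r1_seq[i]))))
    r2 <- lapply(seq_len(spec$n_reads), function(i)
      read_record(ids[i], r2_seq[i], rep(30L, nchar(r2_seq[i]))))
    out <- list(r1 = r1, r2 = r2)
  }
  out$truth <- data.frame(read_id = ids, allele_label = labels[idx],
                          category = cats[idx], mmej = mmejs[idx],
                          truncated = truncated, stringsAsFactors = FALSE)
  out
}

#' Write a truth table
#'
#' @param truth truth `data.frame` from [simulate_reads()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
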