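# End-to-end pipeline: QC -> merge -> align -> call -> classify -> report.

#' Pipeline parameters
#'
#' Central knob set for the profiling pipeline. Defaults: reads shorter
#' than 50 nt are discarded; pairs merge on a >= 20 nt ungapped overlap
#' with <= 10% disagreement; reads aligning below 60% identity are set
#' aside as unassigned (keeping contaminants out of the WT denominator);
#' the cut window is padded by 1 nt for on/off-position calling; 2 nt of
#' junction microhomology flags MMEJ.
#'
#' @param min_len QC length threshold (nt).
#' @param min_overlap,max_mismatch_frac pair-merge thresholds.
#' @param min_identity minimum alignment identity for a read to be
#'   assigned.
#' @param pad cut-window padding (nt) for on-position calling.
#' @param min_mh junction microhomology (nt) flagging MMEJ.
#' @param scoring [align_scoring()] set.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(min_len = 50L, min_overlap = 20L,
                            max_mismatch_frac = 0.1, min_identity = 0.6,
                            pad = 1L, min_mh = 2L,
                            scoring = align_scoring()) {
  list(min_len = min_len, min_overlap = min_overlap,
       max_mismatch_frac = max_mismatch_frac, min_identity = min_identity,
       pad = pad, min_mh = min_mh, scoring = scoring)
}

#' Profile a set of reads against a target site
#'
#' The analysis core shared by [run_profile()] and the simulation
#' round-trip tests: QC-filters reads (already merged), aligns each
#' distinct sequence once, calls left-normalized indels, collapses reads
#' into alleles and classifies them.
#'
#' @param reads list of [read_record()]s (merged/single-end).
#' @param reference reference amplicon (character).
#' @param site single-row `target_sites` data frame.
#' @param params [pipeline_params()].
#' @return A list with `summary` ([summarize_classification()]),
#'   `alleles`, `per_read` (read_id, allele_key, category, mmej),
#'   `qc_discarded` and `unassigned` counts.
#' @export
profile_reads <- function(reads, reference, site,
                          params = pipeline_params()) {
  ref <- toupper(as.character(reference)[1])
  cw <- c(site$cut_start, site$cut_end)
  qc <- qc_filter(reads, params$min_len)
  reads <- qc$kept
  if (length(reads) == 0L) stop("no reads pass QC")
  seqs <- vapply(reads, `[[`, character(1), "seq")
  ids <- vapply(reads, `[[`, character(1), "id")
  uniq <- unique(seqs)
  aln <- lapply(uniq, function(sq) global_align(sq, ref, params$scoring))
  identity <- vapply(aln, `[[`, numeric(1), "identity")
  events_u <- lapply(aln, `[[`, "events")
  keys_u <- vapply(events_u, canonical_allele_key, character(1))
  map <- match(seqs, uniq)
  assigned <- identity[map] >= params$min_identity
  events_by_read <- events_u[map[assigned]]
  if (length(events_by_read) == 0L) stop("no reads assigned to the reference")
  alleles <- tabulate_alleles(events_by_read, cw, ref,
                              params$pad, params$min_mh)
  cls_by_key <- alleles[match(keys_u, alleles$allele_key), , drop = FALSE]
  per_read <- data.frame(
    read_id = ids[assigned],
    allele_key = keys_u[map[assigned]],
    category = cls_by_key$category[map[assigned]],
    mmej = cls_by_key$mmej[map[assigned]],
    stringsAsFactors = FALSE)
  list(summary = summarize_classification(alleles), alleles = alleles,
       per_read = per_read, qc_discarded = qc$discarded_count,
       unassigned = sum(!assigned))
}

resolve_reference <- function(reference) {
  if (length(reference) == 1L && !grepl("^[ACGTNacgtn]+$", reference) &&
      file.exists(reference))
    return(read_reference(reference)[1])
  ref <- toupper(as.character(reference)[1])
  if (is.null(names(ref))) names(ref) <- "ref"
  ref
}

resolve_site <- function(gd, ref, profile) {
  sites <- locate_target(gd, ref, profile)
  if (nrow(sites) == 0L)
    stop("no target site: guide ", gd$id, " does not occur in the reference")
  if (nrow(sites) > 1L)
    stop("multiple target sites found at plus-strand starts: ",
         paste(sites$proto_start, collapse = ", "),
         "; profiling requires exactly one")
  sites
}

run_log <- function(path, ...) {
  kv <- c(...)
  lines <- sprintf("%s %s=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   names(kv), unlist(kv))
  cat(lines, file = path, sep = "\n", append = TRUE)
}

#' Run the editing-outcome profiling pipeline
#'
#' Executes QC, optional pair merging, alignment, indel calling,
#' classification, summarization and allele ranking, then writes the full
#' report bundle: `summary.json` (percentages on the 0-100 scale, 4
#' decimals), `alleles.tsv` (dash-notation rendering per allele),
#' `per_read.tsv`, and `run.log` recording every effective parameter.
#'
#' @param reference FASTA path or sequence.
#' @param guide_seq guide spacer sequence.
#' @param profile_name `"SpCas9"`, `"AsCas12a"`, or a [nuclease_profile()].
#' @param r1 FASTQ path or list of [read_record()]s.
#' @param r2 optional mate FASTQ path (or read list); triggers merging.
#' @param out_dir output directory (created if needed).
#' @param params [pipeline_params()].
#' @param guide_id identifier used in reports.
#' @param top_n number of top alleles reported.
#' @return Invisibly, a list with the [profile_reads()] result, the site,
#'   merge statistics and output paths.
#' @export
run_profile <- function(reference, guide_seq, profile_name, r1, r2 = NULL,
                        out_dir, params = pipeline_params(),
                        guide_id = "guide", top_n = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- if (inherits(profile_name, "nuclease_profile")) profile_name
             else nuclease_profile(profile_name)
  ref <- resolve_reference(reference)
  gd <- guide(guide_id, guide_seq, profile)
  site <- resolve_site(gd, ref, profile)
  reads1 <- if (is.character(r1)) read_fastq(r1) else r1
  merge_failed <- 0L
  if (!is.null(r2)) {
    reads2 <- if (is.character(r2)) read_fastq(r2) else r2
    if (length(reads1) != length(reads2))
      stop("r1 and r2 contain different read counts")
    # amplicon data is highly redundant: merge each distinct sequence pair
    # once and fan the result back out
    key <- paste(vapply(reads1, `[[`, character(1), "seq"),
                 vapply(reads2, `[[`, character(1), "seq"))
    first <- match(unique(key), key)
    merged_u <- lapply(first, function(i)
      merge_read_pair(reads1[[i]], reads2[[i]], params$min_overlap,
                      params$max_mismatch_frac))
    map <- match(key, key[first])
    merged <- lapply(seq_along(reads1), function(i) {
      m <- merged_u[[map[i]]]
      if (!is.null(m)) m$id <- reads1[[i]]$id
      m
    })
    ok <- !vapply(merged, is.null, logical(1))
    merge_failed <- sum(!ok)
    reads <- merged[ok]
  } else {
    reads <- reads1
  }
  res <- profile_reads(reads, ref, site, params)
  res$merge_failed <- merge_failed
  res$site <- site
  top <- top_alleles(res$alleles, top_n)

  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  run_log(log_path,
          tool = "ampedit", version = as.character(utils::packageVersion("ampedit")),
          guide = gd$id, spacer = gd$spacer, profile = profile$name,
          reference_id = site$reference_id,
          min_len = params$min_len, min_overlap = params$min_overlap,
          max_mismatch_frac = params$max_mismatch_frac,
          min_identity = params$min_identity, pad = params$pad,
          min_mh = params$min_mh,
          match = params$scoring$match, mismatch = params$scoring$mismatch,
          gap_open = params$scoring$gap_open,
          gap_extend = params$scoring$gap_extend,
          n_input = length(reads1), merge_failed = merge_failed,
          qc_discarded = res$qc_discarded, unassigned = res$unassigned)

  s <- res$summary
  summary_json <- list(
    reference_id = site$reference_id, guide = gd$id,
    total_reads = s$total_reads,
    unassigned_reads = res$unassigned,
    merge_failed = merge_failed,
    cut_window = c(site$cut_start, site$cut_end),
    percent = lapply(as.list(s$fractions), function(x) round(100 * x, 4)),
    mmej_percent = round(100 * s$mmej_fraction, 4),
    editing_efficiency_percent = round(100 * s$editing_efficiency, 4),
    top_alleles_joint_indel_share_percent =
      round(100 * top$joint_indel_share, 4))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  al <- res$alleles
  al$rendering <- vapply(al$allele_key, function(k)
    render_for_key(ref, k), character(1))
  al$ratio_total <- round(al$read_count / s$total_reads, 6)
  write.table(al, file.path(out_dir, "alleles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$per_read, file.path(out_dir, "per_read.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_site_report(site, file.path(out_dir, "site.tsv"))
  invisible(c(res, list(top = top, out_dir = out_dir)))
}

# Rebuild an event table from a canonical allele key (keys encode indels
# fully), used to render alleles without keeping per-allele event lists.
events_from_key <- function(key) {
  if (key == "WT") return(empty_events())
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    if (grepl("^D", p)) {
      m <- as.integer(strsplit(sub("^D", "", p), "-")[[1]])
      data.frame(kind = "deletion", start = m[1], end = m[2], alt = "",
                 stringsAsFactors = FALSE)
    } else {
      m <- strsplit(sub("^I", "", p), "+", fixed = TRUE)[[1]]
      data.frame(kind = "insertion", start = as.integer(m[1]),
                 end = as.integer(m[1]), alt = m[2], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

render_for_key <- function(reference, key) {
  render_allele(reference, events_from_key(key))
}

#' Run guide design: site + microhomology report
#'
#' Locates every target site of the guide and writes, per site, the target
#' table and the microhomology pairs flanking its cut window. A guide with
#' no site produces empty tables and a warning.
#'
#' @param reference FASTA path or sequence.
#' @param guide_seq guide spacer.
#' @param profile_name profile preset name or [nuclease_profile()].
#' @param out_dir output directory.
#' @param search_window,min_len microhomology enumeration parameters.
#' @param guide_id identifier used in reports.
#' @return Invisibly, `list(sites, mh)`.
#' @export
run_design <- function(reference, guide_seq, profile_name, out_dir,
                       search_window = 30L, min_len = 2L,
                       guide_id = "guide") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- if (inherits(profile_name, "nuclease_profile")) profile_name
             else nuclease_profile(profile_name)
  ref <- resolve_reference(reference)
  gd <- guide(guide_id, guide_seq, profile)
  sites <- locate_target(gd, ref, profile)
  if (nrow(sites) == 0L)
    warning("no target site found for guide ", gd$id)
  write_site_report(sites, file.path(out_dir, "sites.tsv"))
  mh <- if (nrow(sites) >= 1L)
    do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
      enumerate_microhomologies(ref, c(sites$cut_start[i], sites$cut_end[i]),
                                search_window, min_len)))
  else enumerate_microhomologies(ref, c(0L, 0L), search_window, min_len)[0, ]
  write_mh_report(mh, file.path(out_dir, "microhomology.tsv"))
  invisible(list(sites = sites, mh = mh))
}

#' Run the off-target scan
#'
#' @param guide_seq guide spacer.
#' @param database FASTA path or named character vector.
#' @param profile_name profile preset name or [nuclease_profile()].
#' @param out_dir output directory.
#' @param max_mm mismatch budget.
#' @param features optional feature file (BED/GFF3) or feature
#'   `data.frame` for annotation.
#' @param guide_id identifier used in reports.
#' @return Invisibly, the (annotated) hits.
#' @export
run_offtarget <- function(guide_seq, database, profile_name, out_dir,
                          max_mm = 4L, features = NULL, guide_id = "guide") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- if (inherits(profile_name, "nuclease_profile")) profile_name
             else nuclease_profile(profile_name)
  db <- if (is.character(database) && length(database) == 1L &&
            file.exists(database)) read_reference(database) else database
  gd <- guide(guide_id, guide_seq, profile)
  hits <- scan_offtargets(gd, db, profile, max_mm)
  if (!is.null(features)) {
    ft <- if (is.character(features)) read_feature_track(features) else features
    hits <- annotate_hits(hits, ft)
  }
  write_offtarget_report(hits, file.path(out_dir, "offtargets.tsv"))
  invisible(hits)
}

#' Run the read simulator
#'
#' Builds the spectrum from a config file, simulates reads, and writes
#' FASTQ output plus the truth table.
#'
#' @param reference FASTA path or sequence.
#' @param guide_seq guide spacer.
#' @param profile_name profile preset name or [nuclease_profile()].
#' @param spectrum_path spectrum config file (see
#'   [read_spectrum_config()]).
#' @param out_dir output directory.
#' @param n_reads,error_rate,mode,seed see [sim_spec()].
#' @param guide_id identifier used in reports.
#' @return Invisibly, the [simulate_reads()] result.
#' @export
run_simulate <- function(reference, guide_seq, profile_name, spectrum_path,
                         out_dir, n_reads = 20000L, error_rate = 0.001,
                         mode = "paired_2x150", seed, guide_id = "guide") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- if (inherits(profile_name, "nuclease_profile")) profile_name
             else nuclease_profile(profile_name)
  ref <- resolve_reference(reference)
  gd <- guide(guide_id, guide_seq, profile)
  site <- resolve_site(gd, ref, profile)
  fixture <- read_spectrum_config(spectrum_path)
  spectrum <- build_spectrum(fixture, ref, site, seed = seed)
  spec <- sim_spec(ref, site, spectrum, n_reads, error_rate, mode, seed)
  sim <- simulate_reads(spec)
  if (mode == "merged") {
    write_fastq(sim$reads, file.path(out_dir, "reads.fastq"))
  } else {
    write_fastq(sim$r1, file.path(out_dir, "reads_R1.fastq"))
    write_fastq(sim$r2, file.path(out_dir, "reads_R2.fastq"))
  }
  write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
  invisible(sim)
}

#' Compare two profiled arms
#'
#' @param summary_a,summary_b `classification_summary` objects (e.g. from
#'   [run_profile()] results).
#' @param out_dir output directory.
#' @return Invisibly, the [compare_arms()] table.
#' @export
run_compare <- function(summary_a, summary_b, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- compare_arms(summary_a, summary_b)
  num <- vapply(cmp, is.numeric, logical(1))
  cmp[num] <- lapply(cmp[num], function(x) round(x, 4))
  write.table(cmp, file.path(out_dir, "comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(cmp)
}
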