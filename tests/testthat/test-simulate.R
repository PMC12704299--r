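# Spectrum construction, allele application and read simulation.

test_that("apply_allele performs exact string surgery", {
  ref <- "TTAGGCATCAGGCTAA"
  wt <- list(events = data.frame(kind = character(), start = integer(),
                                 end = integer(), alt = character()))
  expect_equal(apply_allele(ref, wt), ref)
  del <- list(events = data.frame(kind = "deletion", start = 6, end = 13,
                                  alt = ""))
  expect_equal(apply_allele(ref, del), "TTAGGCTAA")
  ins <- list(events = data.frame(kind = "insertion", start = 3, end = 3,
                                  alt = "G"))
  expect_equal(apply_allele("ACGT", ins), "ACGGT")
  overlapping <- data.frame(kind = c("deletion", "deletion"),
                            start = c(2, 4), end = c(6, 8), alt = "")
  expect_error(apply_events(ref, overlapping), "overlap")
})

test_that("spectrum configs load, normalise and validate", {
  fix <- read_spectrum_config(bundled_spectrum("cas12a_craft"))
  expect_equal(sum(fix$proportions), 1, tolerance = 1e-12)
  expect_lte(fix$mmej, fix$proportions[["deletion_on_position"]])
  fix2 <- read_spectrum_config(bundled_spectrum("cas9_sgrna"))
  expect_equal(fix2$mmej, 0)
  bad <- tempfile()
  writeLines(c("wt 0.5", "deletion_on_position 0.5",
               "deletion_on_position_mmej 0.9"), bad)
  expect_error(read_spectrum_config(bad), "MMEJ")
})

test_that("build_spectrum expands categories into consistent alleles", {
  fix <- read_spectrum_config(bundled_spectrum("cas12a_craft"))
  amp <- trbc_amplicon()
  site <- craft_site()
  sp <- build_spectrum(fix, amp, site, seed = 5)
  freqs <- vapply(sp, `[[`, numeric(1), "frequency")
  expect_equal(sum(freqs), 1, tolerance = 1e-9)
  # category marginals equal the (normalised) fixture values
  cats <- vapply(sp, `[[`, character(1), "category")
  marg <- tapply(freqs, cats, sum)
  key_map <- c(wt = "wt_or_sub", insertion = "insertion",
               deletion_on_position = "deletion_on_position",
               deletion_off_position = "deletion_off_position")
  for (cat_ in names(fix$proportions))
    expect_equal(unname(marg[[key_map[[cat_]]]]),
                 unname(fix$proportions[[cat_]]), tolerance = 1e-9)
  mmej_marg <- sum(freqs[vapply(sp, `[[`, logical(1), "mmej")])
  expect_equal(mmej_marg, fix$mmej, tolerance = 1e-9)
  # truth labels agree with the classifier on the generating events
  cw <- c(site$cut_start, site$cut_end)
  for (a in sp) {
    cls <- classify_allele(a$events, cw, amp)
    expect_equal(cls$category, a$category)
    expect_equal(cls$mmej, a$mmej)
  }
})

test_that("requesting MMEJ alleles without microhomology errors", {
  fix <- list(label = "x",
              proportions = c(wt = 0.5, insertion = 0,
                              deletion_on_position = 0.5,
                              deletion_off_position = 0),
              mmej = 0.25)
  # no 2-nt repeat straddles the cut within a 2-nt search window
  ref <- c(r = "AACGTT")
  site <- data.frame(reference_id = "r", strand = "plus", proto_start = 0,
                     proto_end = 4, pam_start = 4, pam_end = 6,
                     pam_seq = "TT", cut_start = 2, cut_end = 2)
  expect_error(build_spectrum(fix, ref, site, seed = 3, search_window = 2),
               "no\\s+microhomology")
})

test_that("simulation is deterministic and reproducible from the seed", {
  fix <- read_spectrum_config(bundled_spectrum("cas9_sgrna"))
  amp <- trbc_amplicon()
  site <- sgrna_site()
  sp <- build_spectrum(fix, amp, site, seed = 9)
  spec <- sim_spec(amp, site, sp, n_reads = 300, error_rate = 0.002,
                   mode = "paired_2x150", seed = 10)
  s1 <- simulate_reads(spec)
  s2 <- simulate_reads(spec)
  expect_identical(vapply(s1$r1, `[[`, "", "seq"),
                   vapply(s2$r1, `[[`, "", "seq"))
  expect_identical(s1$truth, s2$truth)
  # byte-identical FASTQ output
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(s1$r1, f1); write_fastq(s2$r1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("error-free reads reconstruct allele sequences exactly", {
  fix <- read_spectrum_config(bundled_spectrum("cas12a_craft"))
  amp <- trbc_amplicon()
  site <- craft_site()
  sp <- build_spectrum(fix, amp, site, seed = 11)
  allele_seqs <- vapply(sp, function(a) apply_allele(amp, a), character(1))
  names(allele_seqs) <- vapply(sp, `[[`, "", "label")
  spec <- sim_spec(amp, site, sp, n_reads = 150, error_rate = 0,
                   mode = "merged", seed = 12)
  sim <- simulate_reads(spec)
  for (i in seq_along(sim$reads))
    expect_equal(sim$reads[[i]]$seq,
                 unname(allele_seqs[[sim$truth$allele_label[i]]]))
})

test_that("paired reads cover the fragment ends and flag truncation", {
  amp <- trbc_amplicon()
  site <- craft_site()
  # one big-deletion allele (fragment < 150 nt) plus WT
  big <- list(label = "bigdel",
              events = data.frame(kind = "deletion", start = 30, end = 100,
                                  alt = ""),
              frequency = 0.5, category = "deletion_on_position",
              mmej = FALSE)
  wt <- list(label = "WT", events = big$events[0, ], frequency = 0.5,
             category = "wt_or_sub", mmej = FALSE)
  spec <- sim_spec(amp, site, list(big, wt), n_reads = 60, error_rate = 0,
                   mode = "paired_2x150", seed = 13)
  sim <- simulate_reads(spec)
  frag_wt <- amp[[1]]
  frag_big <- apply_allele(amp, big)
  for (i in seq_len(60)) {
    frag <- if (sim$truth$allele_label[i] == "WT") frag_wt else frag_big
    expect_equal(sim$r1[[i]]$seq, substr(frag, 1, min(150, nchar(frag))))
    expect_equal(sim$truth$truncated[i], nchar(frag) < 150)
    # r2 is the reverse complement of the fragment tail
    tail_seq <- substring(frag, max(1, nchar(frag) - 149))
    expect_equal(rc_oracle(sim$r2[[i]]$seq), tail_seq)
  }
})

test_that("allele draw frequencies follow the spectrum", {
  amp <- trbc_amplicon()
  site <- craft_site()
  half <- list(
    list(label = "WT", events = data.frame(kind = character(),
                                           start = integer(), end = integer(),
                                           alt = character()),
         frequency = 0.5, category = "wt_or_sub", mmej = FALSE),
    list(label = "del", events = data.frame(kind = "deletion", start = 76,
                                            end = 84, alt = ""),
         frequency = 0.5, category = "deletion_on_position", mmej = FALSE))
  spec <- sim_spec(amp, site, half, n_reads = 10000, error_rate = 0,
                   mode = "merged", seed = 14)
  sim <- simulate_reads(spec)
  wt_share <- mean(sim$truth$allele_label == "WT")
  # binomial 99% interval around 0.5 at n = 10000
  expect_lt(abs(wt_share - 0.5), 2.576 * sqrt(0.25 / 10000))
})

test_that("sim_spec validates its contract", {
  amp <- trbc_amplicon(); site <- craft_site()
  al <- list(list(label = "WT",
                  events = data.frame(kind = character(), start = integer(),
                                      end = integer(), alt = character()),
                  frequency = 0.9, category = "wt_or_sub", mmej = FALSE))
  expect_error(sim_spec(amp, site, al, seed = 1), "sum to 1")
  al[[1]]$frequency <- 1
  expect_error(sim_spec(amp, site, al, error_rate = 0.5, seed = 1))
  expect_error(sim_spec(amp, site, al), "seed")
})
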