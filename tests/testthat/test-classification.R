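# Allele keys, category assignment, summaries, rankings, arm comparison.

del_ev <- function(a, b) data.frame(kind = "deletion", start = a, end = b,
                                    alt = "", stringsAsFactors = FALSE)
ins_ev <- function(g, alt) data.frame(kind = "insertion", start = g, end = g,
                                      alt = alt, stringsAsFactors = FALSE)
sub_ev <- function(p, alt) data.frame(kind = "substitution", start = p,
                                      end = p + 1, alt = alt,
                                      stringsAsFactors = FALSE)

test_that("allele keys are deterministic, injective, and ignore subs", {
  expect_equal(canonical_allele_key(del_ev(0, 0)[0, ]), "WT")
  expect_equal(canonical_allele_key(sub_ev(5, "A")), "WT")
  k1 <- canonical_allele_key(del_ev(76, 84))
  expect_equal(k1, canonical_allele_key(del_ev(76, 84)))
  expect_false(k1 == canonical_allele_key(del_ev(76, 85)))
  expect_false(k1 == canonical_allele_key(ins_ev(76, "ACGTACGT")))
  # same deletion placed differently pre-normalization collapses to one key
  ref <- "ACGTTTTTACG"
  e1 <- normalize_indels(del_ev(4, 5), ref)
  e2 <- normalize_indels(del_ev(7, 8), ref)   # same T-run deletion
  expect_equal(canonical_allele_key(e1), canonical_allele_key(e2))
})

test_that("classification follows the category precedence", {
  ref <- trbc_amplicon()
  cw <- c(76, 81)
  expect_equal(classify_allele(del_ev(0, 0)[0, ], cw, ref)$category,
               "wt_or_sub")
  expect_equal(classify_allele(sub_ev(78, "T"), cw, ref)$category,
               "wt_or_sub")
  expect_equal(classify_allele(ins_ev(78, "TT"), cw, ref)$category,
               "insertion")
  # mixed insertion + deletion counts as insertion
  expect_equal(classify_allele(rbind(ins_ev(78, "T"), del_ev(100, 104)),
                               cw, ref)$category, "insertion")
  expect_equal(classify_allele(del_ev(76, 84), cw, ref)$category,
               "deletion_on_position")
  # 1-nt deletion 30 nt away from the window
  far <- classify_allele(del_ev(30, 31), cw, ref)
  expect_equal(far$category, "deletion_off_position")
  expect_false(far$mmej)
})

test_that("the MMEJ toy allele classifies on-position with mh 4", {
  toy <- "TTAGGCATCAGGCTAA"
  p <- enumerate_microhomologies(toy, c(7, 8), 8, 4)
  pr <- predict_mmej_products(p, toy)
  ev <- normalize_indels(del_ev(pr$deletion_start, pr$deletion_end), toy)
  cls <- classify_allele(ev, c(7, 8), toy)
  expect_equal(cls$category, "deletion_on_position")
  expect_true(cls$mmej)
  expect_equal(cls$mh_len, 4L)
})

test_that("ambiguity expansion rescues slid deletion placements", {
  # a deletion whose normalized placement is left of the window but whose
  # equivalent placements reach it must still be on-position
  ref <- "ACGTACAAAAAAACGTACGT"       # A-run spanning positions 6..12
  cw <- c(12, 12)
  ev <- normalize_indels(del_ev(10, 12), ref)   # normalizes to [6, 8)
  expect_equal(ev$start, 6L)
  expect_equal(classify_allele(ev, cw, ref)$category,
               "deletion_on_position")
})

test_that("summaries compute exact fractions and efficiency", {
  al <- data.frame(
    allele_key = c("WT", "I1", "D1", "D2", "D3"),
    read_count = c(50L, 5L, 10L, 30L, 5L),
    category = c("wt_or_sub", "insertion", "deletion_on_position",
                 "deletion_on_position", "deletion_off_position"),
    mmej = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    mh_len = c(0L, 0L, 3L, 0L, 0L), stringsAsFactors = FALSE)
  s <- summarize_classification(al)
  expect_equal(s$total_reads, 100L)
  expect_equal(unname(s$fractions),
               c(0.50, 0.05, 0.40, 0.05))
  expect_equal(s$mmej_fraction, 0.10)
  expect_equal(s$editing_efficiency, 0.50)
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  # all-WT input
  wt <- al[1, ]
  expect_equal(summarize_classification(wt)$editing_efficiency, 0)
  # single allele
  one <- al[4, ]
  expect_equal(unname(summarize_classification(one)$fractions[3]), 1)
  expect_error(summarize_classification(al[0, ]), "no classified reads")
})

test_that("top_alleles ranks indel alleles and reports joint share", {
  al <- data.frame(
    allele_key = paste0("D", 1:5),
    read_count = c(40L, 30L, 20L, 7L, 3L),
    category = rep("deletion_on_position", 5),
    mmej = FALSE, mh_len = 0L, stringsAsFactors = FALSE)
  t5 <- top_alleles(al, 5)
  expect_equal(t5$joint_indel_share, 1)
  expect_equal(t5$table$read_count, c(40L, 30L, 20L, 7L, 3L))
  t10 <- top_alleles(al, 10)
  expect_equal(nrow(t10$table), 5L)
  wt_only <- data.frame(allele_key = "WT", read_count = 10L,
                        category = "wt_or_sub", mmej = FALSE, mh_len = 0L)
  t0 <- top_alleles(wt_only, 5)
  expect_equal(nrow(t0$table), 0L)
  expect_equal(t0$joint_indel_share, 0)
})

test_that("arm comparison reports differences, Wilson CIs and z", {
  mk <- function(counts, mmej_reads = 0L) {
    al <- data.frame(
      allele_key = c("WT", "I", "DON", "DOFF"),
      read_count = counts,
      category = c("wt_or_sub", "insertion", "deletion_on_position",
                   "deletion_off_position"),
      mmej = FALSE, mh_len = 0L, stringsAsFactors = FALSE)
    al <- al[al$read_count > 0, ]
    if (mmej_reads > 0) {
      al <- rbind(al, data.frame(allele_key = "DMM", read_count = mmej_reads,
                                 category = "deletion_on_position",
                                 mmej = TRUE, mh_len = 3L))
    }
    summarize_classification(al)
  }
  a <- mk(c(94L, 0L, 906L, 0L))       # on-position 90.6%
  b <- mk(c(553L, 0L, 447L, 0L))      # on-position 44.7%
  cmp <- compare_arms(a, b)
  don <- cmp[cmp$category == "deletion_on_position", ]
  expect_equal(don$difference, 0.459, tolerance = 1e-12)
  same <- compare_arms(a, a)
  expect_true(all(same$difference == 0))
  # Wilson CI closed form at n = 100, p = 0.5
  ci <- wilson_ci(50, 100)
  expect_equal(ci, c(0.404, 0.596), tolerance = 5e-3)
})

test_that("mmej_fraction is non-increasing in min_mh", {
  set.seed(41)
  ref <- trbc_amplicon()
  site <- craft_site()
  cw <- c(site$cut_start, site$cut_end)
  events <- lapply(1:120, function(i) {
    a <- sample(60:95, 1); L <- sample(1:15, 1)
    normalize_indels(del_ev(a, min(a + L, 183)), ref)
  })
  prev <- Inf
  for (mh in 0:5) {
    al <- tabulate_alleles(events, cw, ref, pad = 1, min_mh = mh)
    s <- summarize_classification(al)
    expect_lte(s$mmej_fraction, prev + 1e-12)
    expect_lte(s$mmej_fraction, s$fractions[["deletion_on_position"]])
    prev <- s$mmej_fraction
  }
})

test_that("dash-notation rendering marks deleted bases", {
  ref <- "ACGTACGT"
  r <- render_allele(ref, del_ev(2, 5))
  expect_equal(r, "AC---CGT")
  r2 <- render_allele(ref, ins_ev(4, "TT"))
  expect_match(r2, "\\+TT@5")
})
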