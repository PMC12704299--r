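# Nuclease profiles, PAM matching, target location and cut geometry.

test_that("match_pam follows IUPAC classes and the N rules", {
  expect_true(match_pam("AGG", "NGG"))
  expect_true(match_pam("TTTG", "TTTV"))
  expect_false(match_pam("TTTT", "TTTV"))   # V = A/C/G
  expect_true(match_pam("TGG", "NGG"))
  expect_false(match_pam("TCG", "NGG"))
  # degenerate classes
  expect_true(match_pam("AG", "RS"))        # R = A/G, S = C/G
  expect_false(match_pam("CA", "RS"))
  # N in the sequence matches only pattern N
  expect_false(match_pam("NGG", "NGG") == FALSE)  # pattern N accepts seq N
  expect_true(match_pam("NGG", "NGG"))
  expect_false(match_pam("ANG", "NGG"))
  expect_error(match_pam("AG", "NGG"), "length")
})

test_that("guide and profile constructors enforce their invariants", {
  prof <- nuclease_profile("AsCas12a")
  expect_equal(prof$pam_pattern, "TTTV")
  expect_equal(prof$stagger_offsets, c(18L, 23L))
  expect_error(guide("g", "ACGTN"), "A, C, G, T")
  expect_error(guide("g", "ACGT", nuclease_profile("SpCas9")), "length")
  expect_error(nuclease_profile("X", pam_pattern = "QGG",
                                pam_side = "three_prime",
                                spacer_len_range = c(18, 24),
                                cut_geometry = "blunt", blunt_offset = 3),
               "IUPAC")
  expect_error(nuclease_profile("X", pam_pattern = "TTTV",
                                pam_side = "five_prime",
                                spacer_len_range = c(18, 25),
                                cut_geometry = "staggered",
                                stagger_offsets = c(23, 18)),
               "offsets")
})

test_that("the TRBC sgRNA and CRAFT crRNA locate once each in the amplicon", {
  sg <- sgrna_site()
  expect_equal(nrow(sg), 1L)
  expect_equal(sg$strand, "plus")
  expect_equal(c(sg$proto_start, sg$proto_end), c(69L, 89L))
  expect_equal(sg$pam_seq, "AGG")
  expect_equal(c(sg$pam_start, sg$pam_end), c(89L, 92L))
  expect_equal(c(sg$cut_start, sg$cut_end), c(86L, 86L))  # blunt: width 0

  cr <- craft_site()
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$strand, "minus")
  expect_equal(c(cr$proto_start, cr$proto_end), c(78L, 99L))
  expect_equal(cr$pam_seq, "TTTG")
  expect_equal(c(cr$pam_start, cr$pam_end), c(99L, 103L))
  expect_equal(c(cr$cut_start, cr$cut_end), c(76L, 81L))
})

test_that("guides absent from a reference yield no sites", {
  amp <- bundled_amplicons()
  g <- bundled_guides()
  expect_equal(nrow(locate_target(guide("sg", g[["TRBC_sgRNA"]]),
                                  c(ref = "ACGTACGTACGT"),
                                  nuclease_profile("SpCas9"))), 0L)
  # the DN TRBC and TRAC spacers do not occur verbatim in either bundled
  # amplicon (verified here by the scanner; the tables they came from keep
  # their own counsel)
  for (gn in c("DN_TRBC_crRNA", "TRAC_crRNA")) {
    for (an in names(amp)) {
      hits12 <- locate_target(guide(gn, g[[gn]]), amp[an],
                              nuclease_profile("AsCas12a"))
      expect_equal(nrow(hits12), 0L)
    }
  }
})

test_that("locate_target agrees with a per-position oracle on random refs", {
  set.seed(11)
  prof_list <- list(nuclease_profile("SpCas9"), nuclease_profile("AsCas12a"))
  for (rep in 1:25) {
    prof <- prof_list[[1 + rep %% 2]]
    spacer <- rand_dna(20)
    ref <- rand_dna(sample(100:2000, 1))
    # plant the protospacer with a valid PAM on a random strand
    pos <- sample(30:(nchar(ref) - 60), 1)
    pam <- if (prof$name == "SpCas9") "AGG" else "TTTC"
    ins <- if (prof$name == "SpCas9") paste0(spacer, pam) else
      paste0(pam, spacer)
    if (rep %% 3 == 0) ins <- rc_oracle(ins)
    ref <- paste0(substr(ref, 1, pos), ins, substring(ref, pos + 1))
    hits <- locate_target(guide("g", spacer), c(r = ref), prof)
    # oracle: test every position and strand by substring + match_pam
    glen <- nchar(spacer); plen <- nchar(prof$pam_pattern)
    n <- nchar(ref)
    exp_rows <- list()
    for (strand in c("plus", "minus")) {
      pat <- if (strand == "plus") spacer else rc_oracle(spacer)
      for (a in 0:(n - glen)) {
        if (substr(ref, a + 1, a + glen) != pat) next
        pam_right <- (prof$pam_side == "three_prime") == (strand == "plus")
        pp <- if (pam_right) a + glen else a - plen
        if (pp < 0 || pp + plen > n) next
        pam_seq <- substr(ref, pp + 1, pp + plen)
        if (strand == "minus") pam_seq <- rc_oracle(pam_seq)
        if (!match_pam(pam_seq, prof$pam_pattern)) next
        exp_rows[[length(exp_rows) + 1]] <- c(a, strand)
      }
    }
    expect_equal(nrow(hits), length(exp_rows))
    if (length(exp_rows)) {
      got <- paste(hits$proto_start, hits$strand)
      want <- vapply(exp_rows, function(x) paste(x[1], x[2]), "")
      expect_setequal(got, want)
    }
  }
})

test_that("protospacer extraction round-trips the spacer on fuzzed refs", {
  set.seed(12)
  for (rep in 1:30) {
    prof <- nuclease_profile(sample(c("SpCas9", "AsCas12a"), 1))
    spacer <- rand_dna(sample(18:24, 1))
    ref <- rand_dna(300)
    pam <- if (prof$name == "SpCas9") "CGG" else "TTTA"
    ins <- if (prof$name == "SpCas9") paste0(spacer, pam) else
      paste0(pam, spacer)
    if (rep %% 2 == 0) ins <- rc_oracle(ins)
    pos <- sample(20:250, 1)
    ref <- paste0(substr(ref, 1, pos), ins, substring(ref, pos + 1))
    hits <- locate_target(guide("g", spacer), c(r = ref), prof)
    for (k in seq_len(nrow(hits))) {
      proto <- substr(ref, hits$proto_start[k] + 1, hits$proto_end[k])
      if (hits$strand[k] == "minus") proto <- rc_oracle(proto)
      expect_equal(proto, spacer)
    }
  }
})

test_that("cut windows are invariant under reverse-complement remapping", {
  set.seed(13)
  for (rep in 1:12) {
    prof <- nuclease_profile(sample(c("SpCas9", "AsCas12a"), 1))
    spacer <- rand_dna(20)
    pam <- if (prof$name == "SpCas9") "TGG" else "TTTG"
    ins <- if (prof$name == "SpCas9") paste0(spacer, pam) else
      paste0(pam, spacer)
    ref <- paste0(rand_dna(60), ins, rand_dna(60))
    n <- nchar(ref)
    fwd <- locate_target(guide("g", spacer), c(r = ref), prof)
    rev <- locate_target(guide("g", spacer), c(r = rc_oracle(ref)), prof)
    expect_equal(nrow(fwd), nrow(rev))
    # map the reverse-complement hit back to plus coordinates
    mapped <- sort(c(n - rev$cut_end, n - rev$cut_start))
    expect_equal(c(fwd$cut_start, fwd$cut_end), mapped)
  }
})

test_that("stagger offsets beyond the reference raise a coordinate error", {
  prof <- nuclease_profile("AsCas12a", stagger_offsets = c(18L, 300L))
  amp <- trbc_amplicon()
  expect_error(
    locate_target(guide("cr", bundled_guides()[["CRAFT_crRNA"]]), amp, prof),
    "outside reference")
})

test_that("site reports are written 1-based", {
  tf <- tempfile(fileext = ".tsv")
  write_site_report(sgrna_site(), tf)
  tab <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(tab$protospacer_start_1based, 70L)
  expect_equal(tab$protospacer_end, 89L)
})
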