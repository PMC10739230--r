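test_that("the published homeobox fragments contain one WFXNXR hit at residue 15", {
  frags <- read_protein_fasta(tetrapolar_extdata("hd2_homeobox.fasta"))
  expect_length(frags, 2L)
  for (s in frags) {
    hits <- motif_scan(s, "WFXNXR")
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, 15L)
    expect_equal(hits$match, "WFQNHR")
  }
})

test_that("motif scanning honours wildcards, alternatives and overlaps", {
  expect_equal(nrow(motif_scan("ACDEF", "WFXNXR")), 0L)
  # bracketed alternatives
  expect_equal(motif_scan("AAHNPYPTAA", "HNPYP[TS]")$start, 3L)
  expect_equal(motif_scan("AAHNPYPSAA", "HNPYP[TS]")$start, 3L)
  expect_equal(nrow(motif_scan("AAHNPYPAAA", "HNPYP[TS]")), 0L)
  # overlapping occurrences are all reported
  expect_equal(motif_scan("AAAA", "AXA")$start, 1:2)
  # case-insensitive over the protein alphabet
  expect_equal(motif_scan("aahnpypsaa", "HNPYP[TS]")$start, 3L)
  expect_error(motif_scan("ACDZF", "WFXNXR"), "position 4")
  expect_error(motif_scan("ACDEF", "WF1R"), "invalid symbol")
  expect_error(motif_scan("ACDEF", "QQ[TS"), "unterminated")
})

test_that("motif_scan agrees with a regex oracle on random sequences", {
  set.seed(77)
  for (i in 1:1000) {
    s <- random_protein(sample(10:40, 1))
    if (i %% 3 == 0) {   # plant a motif instance at a random position
      pos <- sample(nchar(s) - 5, 1)
      substr(s, pos, pos + 5) <- "WFQNQR"
    }
    expect_identical(motif_scan(s, "WFXNXR")$start, motif_oracle(s, "WFXNXR"),
                     info = s)
  }
})

test_that("hydropathy profiles are windowed means on the published scale", {
  expect_equal(kd_profile("III", window = 3)$value, 4.5)
  expect_equal(kd_profile("RRR", window = 3)$value, -4.5)
  # degenerate window = whole sequence: single mean value
  s <- "MARKSMMT"
  p <- kd_profile(s, window = nchar(s) - 1 + (nchar(s) %% 2))
  sc <- kyte_doolittle_scale()
  expect_equal(length(p$value), nchar(s) - p$window + 1)
  expect_equal(mean(sc[strsplit(s, "")[[1]]][1:p$window]), p$value[1])
  expect_error(kd_profile("III", window = 2), "odd")
  expect_error(kd_profile("III", window = 5), "exceeds")
})

test_that("reversing a sequence reverses its hydropathy profile", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_protein(sample(25:60, 1), alphabet = names(kyte_doolittle_scale()))
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    for (w in c(7, 19)) {
      if (w > nchar(s)) next
      expect_equal(kd_profile(rev_s, w)$value, rev(kd_profile(s, w)$value))
    }
  }
})

test_that("transmembrane calls find hydrophobic runs and respect the threshold", {
  tm <- paste0(strrep("R", 15), strrep("I", 30), strrep("R", 15))
  res <- call_globular(kd_profile(tm, 19))
  expect_equal(res$call, "has_transmembrane")
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$max_value, 4.5)
  expect_equal(call_globular(kd_profile(strrep("R", 40), 19))$call, "globular")
  # monotone in the threshold: every region at a higher cutoff lies inside a
  # region at a lower cutoff (no new territory appears), and the flagged
  # positions shrink
  set.seed(47)
  for (i in 1:20) {
    s <- random_protein(60, alphabet = names(kyte_doolittle_scale()))
    prof <- kd_profile(s, 9)
    thresholds <- c(0.5, 1.0, 1.6, 2.5)
    regs <- lapply(thresholds, function(t) call_globular(prof, t)$regions)
    for (k in seq_along(thresholds)[-1]) {
      hi <- regs[[k]]; lo <- regs[[k - 1]]
      for (r in seq_len(nrow(hi))) {
        expect_true(any(lo$start <= hi$start[r] & hi$end[r] <= lo$end),
                    info = paste("seed rep", i, "threshold", thresholds[k]))
      }
    }
    above <- vapply(thresholds, function(t) sum(prof$value > t), numeric(1))
    expect_true(all(diff(above) <= 0))
  }
})

test_that("the NLS composition screen flags K/R- and P/H-rich stretches", {
  res <- nls_screen("KRKRKRK")
  expect_equal(nrow(res), 1L)
  expect_equal(res$class, "KR")
  expect_equal(c(res$start, res$end), c(1, 7))
  expect_equal(nrow(nls_screen("ACDEFGW")), 0L)
  # P/H class, and merging of overlapping windows
  res2 <- nls_screen(paste0("AA", strrep("PH", 6), "AA"))
  expect_equal(res2$class, "PH")
  expect_equal(nrow(res2), 1L)
  # the published homeobox fragment never reaches 4 marker residues per
  # 7-mer (max is 2), so the default screen is empty and a 2/7 screen is not
  frag <- "MARKSMMTDRQIEVWFQNHRNSR"
  expect_equal(nrow(nls_screen(frag)), 0L)
  relaxed <- nls_screen(frag, min_fraction = 2 / 7)
  expect_true(any(relaxed$class == "KR"))
  expect_error(nls_screen("KRKR", window = 3), ">= 4")
})

test_that("length comparison is descriptive over pairs and sets", {
  expect_equal(compare_lengths(c(200), c(160))$mean_difference, 40)
  same <- compare_lengths(c("AAAA", "RRRR"), c("KKKK", "EEEE"))
  expect_equal(same$mean_difference, 0)
  expect_true(same$paired)
  unpaired <- compare_lengths(c(100, 110), c(60, 70, 80))
  expect_false(unpaired$paired)
  expect_length(unpaired$differences, 6L)
  expect_error(compare_lengths(character(0), "AA"), "non-empty")
})

test_that("matA locus models validate cassette structure and export GFF3", {
  pc9 <- locus_model("PC9", c("mip", "hd1", "hd2", "fg"), c("+", "-", "+", "+"))
  pc15 <- locus_model("PC15", c("mip", "hd1.1", "hd1.2", "hd2", "fg"),
                      c("+", "+", "-", "+", "+"))
  expect_error(locus_model("X", c("mip", "hd1"), c("+", "+")), "fg")
  expect_error(locus_model("X", c("hd1", "fg"), c("+", "+")), "mip")
  expect_error(locus_model("X", c("mip", "fg"), c("+", "+")), "1-3 hd")
  expect_error(locus_model("X", c("mip", "hd1.1", "hd1.2", "fg"),
                           c("+", "+", "+", "+")), "divergently")

  f9 <- tempfile(fileext = ".gff3"); f15 <- tempfile(fileext = ".gff3")
  write_locus_gff(pc9, f9); write_locus_gff(pc15, f15)
  expect_equal(readLines(f9, n = 1), "##gff-version 3")
  g9 <- rtracklayer::import(f9)
  g15 <- rtracklayer::import(f15)
  expect_length(g9, 4L)
  expect_length(g15, 5L)
  expect_true(all(g9$type == "gene"))
  s <- as.character(GenomicRanges::strand(g15))[match(c("hd1.1", "hd1.2"), g15$Name)]
  expect_setequal(s, c("+", "-"))
  # genes appear in cassette order along the placeholder scaffold
  expect_identical(g15$Name[order(GenomicRanges::start(g15))],
                   c("mip", "hd1.1", "hd1.2", "hd2", "fg"))
})
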