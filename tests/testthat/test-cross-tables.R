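write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f, useBytes = TRUE)
  f
}

test_that("a minimal 2x2 table parses with labels and symbols intact", {
  f <- write_lines_tmp(c("strain,m1,m2", "m1,-,+", "m2,+,-"))
  tab <- read_cross_table(f)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(count_plus(tab), 2L)
  expect_equal(rownames(tab$entries), c("m1", "m2"))
  expect_equal(tab$entries["m1", "m2"], "+")
})

test_that("en/em dashes, blanks, '?' and footnote asterisks normalise on parse", {
  f <- write_lines_tmp(c("strain,m1,m2,m3", "x,+*,–,?", "y,—,,-"))
  tab <- read_cross_table(f, check_symmetry = FALSE)
  expect_equal(unname(tab$entries["x", ]), c("+", "-", NA))
  expect_equal(unname(tab$entries["y", ]), c("-", NA, "-"))
})

test_that("unknown symbols, duplicate labels and ragged rows are parse errors", {
  expect_error(read_cross_table(write_lines_tmp(c("strain,m1", "x,±"))),
               "unknown cross-table symbol")
  expect_error(read_cross_table(write_lines_tmp(c("strain,m1,m2", "x,+,-", "x,-,+"))),
               "duplicate")
  expect_error(read_cross_table(write_lines_tmp(c("strain,m1,m2", "x,+"))))
})

test_that("symmetry violations are reported, not silently fixed", {
  f <- write_lines_tmp(c("strain,x,y", "x,-,+", "y,-,-"))
  expect_error(read_cross_table(f), "asymmetric")
  # a self-compatible diagonal is impossible under the model
  f2 <- write_lines_tmp(c("strain,x,y", "x,+,+", "y,+,-"))
  expect_error(read_cross_table(f2), "self-cross")
})

test_that("write/read round-trips tables in both dialects", {
  set.seed(5)
  for (sep in c(",", "\t")) {
    ent <- matrix(sample(c("+", "-", NA), 20, replace = TRUE), 4, 5,
                  dimnames = list(paste0("r", 1:4), paste0("c", 1:5)))
    tab <- cross_table(ent, row_kind = "monokaryon")
    f <- tempfile()
    write_cross_table(tab, f, sep = sep)
    back <- read_cross_table(f, sep = sep, check_symmetry = FALSE)
    expect_identical(back$entries, tab$entries)
    expect_identical(back$row_kind, tab$row_kind)
  }
})

test_that("the transcribed mutual-cross table has the published block structure", {
  study <- load_crossing_study()
  tab <- study$monmon_mutual
  m8 <- paste0("M-8.m", 1:4); m9 <- paste0("M-9.m", 1:4); m13 <- paste0("M-13.m", 1:4)
  # each self-block: 4 '+' of 16
  for (blk in list(m8, m9, m13)) {
    expect_equal(count_plus(tab, blk, blk), 4L)
  }
  # M-8 x M-9 fully compatible in both recorded orientations
  expect_equal(count_plus(tab, m8, m9), 16L)
  expect_equal(count_plus(tab, m9, m8), 16L)
  # M-8 x M-13: 50% compatible (8 of 16), recorded in the M-13 rows
  expect_equal(count_plus(tab, m13, m8), 8L)
  expect_true(all(is.na(tab$entries[m8, m13])))
})

test_that("forward prediction reproduces the published tables from genotypes", {
  study <- load_crossing_study()
  panels <- study$panels
  geno <- function(p) stats::setNames(lapply(p$genotypes, parse_genotype), p$testers)
  # natural panels vs the reference panel: all 16 cells '+'
  pred <- predict_cross_table(geno(panels[["M-8"]]), geno(panels[["M-38"]]))
  expect_equal(count_plus(pred), 16L)
  # M-13 vs M-8 (post-deduction genotypes): 8 of 16, matching the record
  pred2 <- predict_cross_table(geno(panels[["M-13"]]), geno(panels[["M-8"]]))
  expect_equal(count_plus(pred2), 8L)
  expect_identical(pred2$entries,
                   study$monmon_mutual$entries[paste0("M-13.m", 1:4), paste0("M-8.m", 1:4)])
  # any panel against itself: 4 of 16
  pred3 <- predict_cross_table(geno(panels[["M-9"]]))
  expect_equal(count_plus(pred3), 4L)
  expect_identical(unname(pred3$entries),
                   unname(study$monmon_mutual$entries[paste0("M-9.m", 1:4), paste0("M-9.m", 1:4)]))
})

test_that("panel specifications validate the spore-set structure", {
  expect_s3_class(panel_spec("X", paste0("X.m", 1:4),
                             c("A1B1", "A1B2", "A2B1", "A2B2")), "panel_spec")
  expect_error(panel_spec("X", paste0("X.m", 1:4),
                          c("A1B1", "A2B2", "A2B1", "A1B2")), "spore types")
  expect_error(panel_spec("X", c("a", "a", "b", "c")))
  panels <- read_panels(tetrapolar_extdata("panels.yaml"))
  expect_length(panels, 6L)
  expect_equal(panels[["M-13"]]$genotypes, c("A7B3", "A7B4", "A8B3", "A8B4"))
})
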