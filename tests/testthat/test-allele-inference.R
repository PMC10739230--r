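test_that("cells translate into the constraints the tetrapolar rule implies", {
  ent <- matrix(c("-", "+", "+", "-"), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  cs <- build_constraints(cross_table(ent))
  # one '+' pair: inequality at both loci; diagonal '-' contributes nothing
  expect_equal(nrow(cs$ineq), 2L)
  expect_equal(sort(cs$ineq$locus), c("A", "B"))
  expect_equal(nrow(cs$disj), 0L)

  study <- load_crossing_study()
  m8 <- paste0("M-8.m", 1:4); m13 <- paste0("M-13.m", 1:4)
  sub <- cross_table(study$monmon_mutual$entries[m13, m8])
  cs2 <- build_constraints(sub)
  expect_equal(nrow(cs2$disj), 8L)           # 8 '-' cells
  expect_equal(nrow(cs2$ineq), 16L)          # 8 '+' cells, two loci each

  bad <- matrix("+", 1, 1, dimnames = list("x", "x"))
  expect_error(build_constraints(cross_table(bad)), "self-compatibility")
})

test_that("propagation forces the shared matB identities between panels", {
  res <- infer_study_alleles()
  pc <- attr(res, "propagated")
  # the M-8 and M-13 panels share both matB classes, pairwise by tester
  for (i in 1:4) {
    expect_true(same_class(pc, "B", paste0("M-8.m", i), paste0("M-13.m", i)))
  }
  # forced by deduction, with no residual ambiguity
  expect_gte(nrow(pc$forced), 2L)
  expect_true(all(pc$forced$locus == "B"))
  expect_equal(nrow(pc$open_disj), 0L)
  # matA classes remain distinct between the two panels
  expect_false(same_class(pc, "A", "M-8.m1", "M-13.m1"))
})

test_that("an all-'+' table propagates to all-distinct classes with no merges", {
  ent <- matrix("+", 3, 3, dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  cs <- build_constraints(cross_table(ent))
  pc <- propagate(cs)
  expect_equal(nrow(pc$forced), 0L)
  expect_equal(length(unique(pc$comp_A)), 6L)
})

test_that("unsatisfiable '-' records are detected and named", {
  # x,y incompatible, but third-party crosses contradict both the shared-A
  # and the shared-B explanation once panels force the classes apart
  ent <- matrix(NA_character_, 4, 4,
                dimnames = list(paste0("m", 1:4), paste0("m", 1:4)))
  ent["m1", "m2"] <- "-"
  p <- panel_spec("P", paste0("m", 1:4), c("A1B1", "A1B2", "A2B1", "A2B2"))
  # panel says m1/m2 share A; force A apart via an impossible extra record:
  # claim m1 x m2 '-' is fine, but m1 x m2 also '+' elsewhere is conflicting
  ent2 <- ent; ent2["m2", "m1"] <- "+"
  expect_error(build_constraints(cross_table(ent2)), "conflicting")
  # a '-' whose two branches are both contradicted
  ent3 <- matrix(NA_character_, 3, 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  ent3["x", "y"] <- "-"
  cs <- build_constraints(cross_table(ent3, row_kind = "monokaryon"))
  cs$ineq <- rbind(cs$ineq,
                   data.frame(locus = c("A", "B"), m1 = "x", m2 = "y",
                              source = "crafted"))
  expect_error(propagate(cs), "unsatisfiable")
})

test_that("minimal assignments match hand-checkable cases", {
  study <- load_crossing_study()
  # a single four-tester panel alone: two classes at each locus
  cs <- build_constraints(list(), panels = study$panels["M-8"])
  ma <- minimal_assignment(cs)
  expect_equal(c(ma$n_A, ma$n_B), c(2L, 2L))
  # M-8 + M-13 panels with the published pattern: 4 matA, 2 matB classes
  m8 <- paste0("M-8.m", 1:4); m13 <- paste0("M-13.m", 1:4)
  sub <- cross_table(study$monmon_mutual$entries[c(m8, m13), c(m8, m13)],
                     row_kind = "monokaryon")
  cs2 <- build_constraints(sub, panels = study$panels[c("M-8", "M-13")])
  ma2 <- minimal_assignment(cs2)
  expect_equal(c(ma2$n_A, ma2$n_B), c(4L, 2L))
  expect_equal(unname(brute_force_allele_counts(cs2)), c(4L, 2L))
})

test_that("the brute-force oracle handles its reference cases and refuses big input", {
  study <- load_crossing_study()
  cs <- build_constraints(list(), panels = study$panels["M-8"])
  expect_equal(unname(brute_force_allele_counts(cs)), c(2L, 2L))
  # two panels, all cross-panel '+': 4 classes at each locus
  p1 <- panel_spec("P", paste0("p", 1:4), c("A1B1", "A1B2", "A2B1", "A2B2"))
  p2 <- panel_spec("Q", paste0("q", 1:4), c("A3B3", "A3B4", "A4B3", "A4B4"))
  ent <- matrix("+", 4, 4, dimnames = list(p1$testers, p2$testers))
  cs2 <- build_constraints(cross_table(ent), panels = list(p1, p2))
  expect_equal(unname(brute_force_allele_counts(cs2)), c(4L, 4L))
  big <- build_constraints(load_crossing_study()$monmon_stated)  # 20 monokaryons
  expect_error(brute_force_allele_counts(big), "too large")
})

test_that("solver and oracle agree on randomized small instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed, mask = if (seed %% 2) 0 else 0.3)
    cs <- build_constraints(inst$table)
    ma <- minimal_assignment(cs)
    bf <- brute_force_allele_counts(cs)
    expect_equal(c(ma$n_A, ma$n_B), unname(bf),
                 info = paste("seed", seed))
  }
})

test_that("any returned assignment reproduces every recorded cell (soundness)", {
  for (seed in c(3, 14, 27)) {
    inst <- random_instance(seed, mask = 0.25)
    ma <- minimal_assignment(build_constraints(inst$table))
    pred <- predict_cross_table(assignment_genotypes(ma))
    obs <- inst$table$entries
    keep <- !is.na(obs)
    expect_identical(pred$entries[keep], obs[keep], info = paste("seed", seed))
  }
  # and end-to-end on the bundled study
  res <- infer_study_alleles()
  pred <- predict_cross_table(assignment_genotypes(res))
  study <- load_crossing_study()
  for (tab in list(study$monmon_mutual, study$monmon_stated)) {
    obs <- tab$entries
    keep <- !is.na(obs)
    expect_identical(pred$entries[rownames(obs), colnames(obs)][keep], obs[keep])
  }
})

test_that("counts are monotone in the recorded evidence", {
  for (seed in c(2, 9, 21, 33)) {
    inst <- random_instance(seed)
    cs <- build_constraints(inst$table)
    base <- brute_force_allele_counts(cs)
    ent <- inst$table$entries
    off <- which(row(ent) != col(ent) & !is.na(ent), arr.ind = TRUE)
    set.seed(seed)
    pick <- off[sample(nrow(off), 1), ]
    # masking a recorded cell can only relax the instance
    ent2 <- ent; ent2[pick[1], pick[2]] <- NA
    ent2[pick[2], pick[1]] <- NA
    ma2 <- minimal_assignment(build_constraints(cross_table(ent2)))
    expect_lte(ma2$n_A + ma2$n_B, sum(base))
    # turning a '-' into '+' adds constraints and can only raise the counts
    minus <- which(ent == "-" & row(ent) != col(ent), arr.ind = TRUE)
    if (nrow(minus)) {
      pick <- minus[sample(nrow(minus), 1), ]
      ent3 <- ent
      ent3[pick[1], pick[2]] <- "+"
      ent3[pick[2], pick[1]] <- "+"
      ma3 <- try(minimal_assignment(build_constraints(cross_table(ent3))),
                 silent = TRUE)
      if (!inherits(ma3, "try-error")) {
        expect_gte(ma3$n_A + ma3$n_B, sum(base))
      }
    }
  }
})

test_that("panel-structured simulations recover the true allele counts", {
  for (seed in c(101, 202, 303)) {
    pop <- random_panel_instance(seed, n_isolates = 2)
    ma <- minimal_assignment(build_constraints(pop$monmon, panels = pop$panels))
    expect_equal(c(ma$n_A, ma$n_B), unname(pop$truth), info = paste("seed", seed))
  }
})

test_that("di-mon rows are checked by exhaustive genotype enumeration", {
  ref <- spore_types(dikaryon("A1B1", "A2B2"))
  mk_row <- function(cells, id) {
    cross_table(matrix(cells, 1, 4, dimnames = list(id, names(ref))),
                row_kind = "dikaryon")
  }
  # an all-'+' row is satisfiable without any novel matA allele being forced:
  # {A1,Bnew}+{A2,Bnew'} genotypes also reproduce it
  rep1 <- check_dimon_consistency(mk_row(rep("+", 4), "D1"), ref)
  expect_true(rep1$satisfiable)
  expect_false(rep1$forced_novel_A)
  expect_false(rep1$forced_novel_B)
  # the parental pattern '+,-,-,+' is satisfiable by {A1B1, A2B2}-type dikaryons
  rep2 <- check_dimon_consistency(mk_row(c("+", "-", "-", "+"), "D2"), ref)
  expect_true(rep2$satisfiable)
  expect_equal(rep2$example, "A1B1+A2B2")
  # an all-'-' row cannot come from any valid dikaryon over the universe
  rep3 <- check_dimon_consistency(mk_row(rep("-", 4), "D3"), ref)
  expect_false(rep3$satisfiable)
  # the bundled di-mon block: all twelve rows consistent, nothing forced
  study <- load_crossing_study()
  p38 <- study$panels[["M-38"]]
  rep4 <- check_dimon_consistency(study$dimon_reference, p38)
  expect_equal(nrow(rep4), 12L)
  expect_true(all(rep4$satisfiable))
  expect_false(any(rep4$forced_novel_A))
  expect_false(any(rep4$forced_novel_B))
})
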