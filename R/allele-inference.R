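# Inference of allele identity classes at matA and matB from an observed
# +/- compatibility matrix.
#
# Under the tetrapolar rule every scored mon-mon cell is a logical constraint
# on allele classes:
#   "+"  =>  A(m) != A(m')  AND  B(m) != B(m')
#   "-"  =>  A(m)  = A(m')  OR   B(m)  = B(m')
# and a four-tester panel adds the within-panel equalities/inequalities that
# follow from its derivation from a single dikaryon. "At least N alleles"
# is formalised as the minimum number of distinct classes over all
# assignments consistent with every constraint: unit propagation (union-find)
# resolves the disjunctions whose other branch is contradicted, and an exact
# backtracking search over the residual ambiguity minimises the class counts.

# ---------------------------------------------------------------------------
# Constraint construction
# ---------------------------------------------------------------------------

#' Build the constraint set implied by crossing tables and panels
#'
#' Scans the monokaryon rows of one or more cross tables and emits, per
#' non-missing cell, the constraint the tetrapolar rule implies (see above).
#' Each unordered strain pair contributes one constraint; cells recorded in
#' both orientations must agree. Dikaryon rows are ignored here (they carry
#' no allele labels; see [check_dimon_consistency()]). Panel specifications
#' contribute the within-panel structure: m1/m2 and m3/m4 share a matA class,
#' m1/m3 and m2/m4 share a matB class, and the two classes at each locus
#' differ.
#'
#' @param tables A [cross_table()] or list of them.
#' @param panels Optional list of [panel_spec()]s.
#' @param restrict Optional character vector of monokaryon ids; constraints
#'   (and panels) touching any other id are dropped.
#' @return An object of class `constraint_set` with elements `monokaryons`
#'   (canonical order: panels first, then table rows, then columns), `ineq`,
#'   `eq` and `disj` data frames.
#' @export
build_constraints <- function(tables, panels = NULL, restrict = NULL) {
  if (inherits(tables, "cross_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "cross_table")))

  mons <- character(0)
  add_mons <- function(ids) mons <<- c(mons, setdiff(ids, mons))
  if (!is.null(panels)) for (p in panels) add_mons(p$testers)
  for (tab in tables) {
    add_mons(rownames(tab$entries)[tab$row_kind == "monokaryon"])
    add_mons(colnames(tab$entries))
  }
  if (!is.null(restrict)) mons <- intersect(mons, restrict)

  seen <- new.env(parent = emptyenv())   # unordered pair -> "+"/"-"
  ineq <- list(); eq <- list(); disj <- list()

  for (tab in tables) {
    ent <- tab$entries
    rn <- rownames(ent); cn <- colnames(ent)
    for (i in which(tab$row_kind == "monokaryon")) {
      if (!(rn[i] %in% mons)) next
      for (j in seq_along(cn)) {
        v <- ent[i, j]
        if (is.na(v) || !(cn[j] %in% mons)) next
        r <- rn[i]; s <- cn[j]
        if (r == s) {
          if (v == PLUS) stop("self-compatibility recorded for '", r,
                              "': impossible under the tetrapolar model")
          next
        }
        key <- paste(sort(c(r, s)), collapse = "\r")
        if (!is.null(seen[[key]])) {
          if (seen[[key]] != v) stop("conflicting records for cross (", r, ", ", s, ")")
          next
        }
        seen[[key]] <- v
        src <- paste0("cell (", r, ", ", s, ")")
        if (v == PLUS) {
          ineq[[length(ineq) + 1L]] <- list("A", r, s, src)
          ineq[[length(ineq) + 1L]] <- list("B", r, s, src)
        } else {
          disj[[length(disj) + 1L]] <- list(r, s, src)
        }
      }
    }
  }

  if (!is.null(panels)) {
    for (p in panels) {
      t <- p$testers
      if (!all(t %in% mons)) next
      src <- paste0("panel ", p$isolate)
      eq[[length(eq) + 1L]] <- list("A", t[1L], t[2L], src)
      eq[[length(eq) + 1L]] <- list("A", t[3L], t[4L], src)
      eq[[length(eq) + 1L]] <- list("B", t[1L], t[3L], src)
      eq[[length(eq) + 1L]] <- list("B", t[2L], t[4L], src)
      ineq[[length(ineq) + 1L]] <- list("A", t[1L], t[3L], src)
      ineq[[length(ineq) + 1L]] <- list("B", t[1L], t[2L], src)
    }
  }

  as_df <- function(lst, nm) {
    if (!length(lst)) {
      return(stats::setNames(as.data.frame(rep(list(character(0)), length(nm))), nm))
    }
    stats::setNames(as.data.frame(do.call(rbind, lapply(lst, unlist)),
                                  stringsAsFactors = FALSE), nm)
  }
  structure(list(
    monokaryons = mons,
    ineq = as_df(ineq, c("locus", "m1", "m2", "source")),
    eq   = as_df(eq,   c("locus", "m1", "m2", "source")),
    disj = as_df(disj, c("m1", "m2", "source"))
  ), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> ", length(x$monokaryons), " monokaryons; ",
      nrow(x$ineq), " inequalities, ", nrow(x$eq), " equalities, ",
      nrow(x$disj), " disjunctions\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Unit propagation (union-find fixpoint)
# ---------------------------------------------------------------------------

# comp: integer component id per monokaryon index. Merging relabels the whole
# component (tables are small; clarity over asymptotics).
merge_comp <- function(comp, i, j) {
  ci <- comp[i]; cj <- comp[j]
  if (ci != cj) comp[comp == cj] <- ci
  comp
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Propagate a constraint set to its fixpoint
#'
#' Applies all equality constraints, then repeatedly resolves every
#' disjunction one of whose branches is contradicted by the accumulated
#' inequalities, recording each such resolution as a *forced* class
#' identification (this is the formal counterpart of deducing, from a
#' crossing matrix, that two panels share matB classes). Stops with an error
#' naming the offending cell if the set is unsatisfiable.
#'
#' @param cs A `constraint_set` from [build_constraints()].
#' @return An object of class `propagated_constraints`: the input plus
#'   integer component vectors `comp_A`, `comp_B` (per monokaryon), a
#'   `forced` data frame of propagation-forced equalities, and `open_disj`,
#'   the disjunctions left genuinely unresolved.
#' @export
propagate <- function(cs) {
  stopifnot(inherits(cs, "constraint_set"))
  mons <- cs$monokaryons
  n <- length(mons)
  idx <- function(m) match(m, mons)
  compA <- seq_len(n); compB <- seq_len(n)

  for (k in seq_len(nrow(cs$eq))) {
    e <- cs$eq[k, ]
    if (e$locus == "A") compA <- merge_comp(compA, idx(e$m1), idx(e$m2))
    else compB <- merge_comp(compB, idx(e$m1), idx(e$m2))
  }

  iA <- cs$ineq[cs$ineq$locus == "A", , drop = FALSE]
  iB <- cs$ineq[cs$ineq$locus == "B", , drop = FALSE]
  iA1 <- idx(iA$m1); iA2 <- idx(iA$m2)
  iB1 <- idx(iB$m1); iB2 <- idx(iB$m2)
  d1 <- idx(cs$disj$m1); d2 <- idx(cs$disj$m2)
  active <- rep(TRUE, length(d1))
  forced <- list()

  check_contra <- function(compA, compB) {
    bad <- which(compA[iA1] == compA[iA2])
    if (length(bad)) stop("inconsistent constraints: '+' at ", iA$source[bad[1L]],
                          " contradicts a forced matA identity")
    bad <- which(compB[iB1] == compB[iB2])
    if (length(bad)) stop("inconsistent constraints: '+' at ", iB$source[bad[1L]],
                          " contradicts a forced matB identity")
  }
  check_contra(compA, compB)

  repeat {
    if (!any(active)) break
    forbidA <- pair_key(compA[iA1], compA[iA2])
    forbidB <- pair_key(compB[iB1], compB[iB2])
    aeq <- compA[d1] == compA[d2]
    beq <- compB[d1] == compB[d2]
    adead <- pair_key(compA[d1], compA[d2]) %in% forbidA
    bdead <- pair_key(compB[d1], compB[d2]) %in% forbidB

    sat <- active & (aeq | beq)
    active[sat] <- FALSE
    both <- active & adead & bdead
    if (any(both)) {
      stop("unsatisfiable '-' record at ", cs$disj$source[which(both)[1L]],
           ": both shared-A and shared-B explanations are contradicted")
    }
    todo <- which(active & (adead | bdead))
    if (!length(todo)) break
    k <- todo[1L]
    if (adead[k]) {
      compB <- merge_comp(compB, d1[k], d2[k])
      forced[[length(forced) + 1L]] <- list("B", mons[d1[k]], mons[d2[k]], cs$disj$source[k])
    } else {
      compA <- merge_comp(compA, d1[k], d2[k])
      forced[[length(forced) + 1L]] <- list("A", mons[d1[k]], mons[d2[k]], cs$disj$source[k])
    }
    active[k] <- FALSE
    check_contra(compA, compB)
  }

  forced_df <- if (length(forced)) {
    stats::setNames(as.data.frame(do.call(rbind, lapply(forced, unlist)),
                                  stringsAsFactors = FALSE),
                    c("locus", "m1", "m2", "source"))
  } else {
    data.frame(locus = character(0), m1 = character(0), m2 = character(0),
               source = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    constraints = cs,
    comp_A = compA, comp_B = compB,
    forced = forced_df,
    open_disj = cs$disj[active, , drop = FALSE]
  ), class = "propagated_constraints")
}

#' @export
print.propagated_constraints <- function(x, ...) {
  cat("<propagated_constraints> ", length(unique(x$comp_A)), " matA / ",
      length(unique(x$comp_B)), " matB components; ",
      nrow(x$forced), " forced identifications, ",
      nrow(x$open_disj), " open disjunctions\n", sep = "")
  invisible(x)
}

#' Are two monokaryons in the same propagated class?
#'
#' @param pc A `propagated_constraints` object.
#' @param locus `"A"` or `"B"`.
#' @param m1,m2 Monokaryon ids.
#' @return Logical scalar.
#' @export
same_class <- function(pc, locus, m1, m2) {
  mons <- pc$constraints$monokaryons
  comp <- if (locus == "A") pc$comp_A else pc$comp_B
  comp[match(m1, mons)] == comp[match(m2, mons)]
}

# ---------------------------------------------------------------------------
# Exact minimisation
# ---------------------------------------------------------------------------

# Greedy clique lower bound on the chromatic number of a comp-level graph.
clique_bound <- function(adj) {
  p <- nrow(adj)
  if (p == 0L) return(0L)
  ord <- order(rowSums(adj), decreasing = TRUE)
  clique <- integer(0)
  for (v in ord) if (all(adj[v, clique])) clique <- c(clique, v)
  length(clique)
}

#' Minimal consistent allele-class assignment
#'
#' Finds an assignment of matA and matB classes to every monokaryon that
#' satisfies all constraints and minimises the total number of distinct
#' classes `n_A + n_B` (ties broken by smaller `n_A`, then by the
#' lexicographically smallest restricted-growth labelling per locus). The
#' search is exact: depth-first over canonical colourings of the propagated
#' component graphs, with the cross-locus disjunctions enforced during
#' search and a clique lower bound for pruning. Class labels are assigned by
#' first appearance in monokaryon order (`A1`, `A2`, ... / `B1`, `B2`, ...).
#'
#' @param pc A `propagated_constraints` object (or a `constraint_set`, which
#'   is propagated first).
#' @param count_solutions If `TRUE` (default) the search additionally
#'   enumerates optimal solutions (up to relabelling, capped) to report
#'   whether the minimal assignment is unique.
#' @return An object of class `allele_assignment`: `assignment` data frame
#'   (`monokaryon`, `matA`, `matB`), counts `n_A`, `n_B`, the `forced`
#'   identifications from propagation, `unique_up_to_relabeling`, and
#'   `chosen_merges`, the class identifications that were optional (chosen
#'   only to minimise counts).
#' @export
minimal_assignment <- function(pc, count_solutions = TRUE) {
  if (inherits(pc, "constraint_set")) pc <- propagate(pc)
  stopifnot(inherits(pc, "propagated_constraints"))
  cs <- pc$constraints
  mons <- cs$monokaryons
  n <- length(mons)
  if (n == 0L) {
    return(structure(list(
      assignment = data.frame(monokaryon = character(0), matA = character(0),
                              matB = character(0), stringsAsFactors = FALSE),
      n_A = 0L, n_B = 0L, forced = pc$forced,
      unique_up_to_relabeling = TRUE, chosen_merges = 0L,
      open_disjunctions = 0L), class = "allele_assignment"))
  }

  # components in canonical order (first monokaryon appearance)
  comp_index <- function(comp) {
    reps <- comp[!duplicated(comp)]
    match(comp, reps)   # 1..p, ordered by first appearance
  }
  cA <- comp_index(pc$comp_A); pA <- max(cA)
  cB <- comp_index(pc$comp_B); pB <- max(cB)

  adj_of <- function(comp, locus) {
    ii <- cs$ineq[cs$ineq$locus == locus, , drop = FALSE]
    p <- max(comp)
    adj <- matrix(FALSE, p, p)
    if (nrow(ii)) {
      a <- comp[match(ii$m1, mons)]; b <- comp[match(ii$m2, mons)]
      adj[cbind(a, b)] <- TRUE; adj[cbind(b, a)] <- TRUE
    }
    adj
  }
  adjA <- adj_of(cA, "A")
  adjB <- adj_of(cB, "B")

  # open disjunctions lifted to component pairs (deduplicated)
  od <- pc$open_disj
  if (nrow(od)) {
    dA1 <- cA[match(od$m1, mons)]; dA2 <- cA[match(od$m2, mons)]
    dB1 <- cB[match(od$m1, mons)]; dB2 <- cB[match(od$m2, mons)]
    dk <- !duplicated(paste(pair_key(dA1, dA2), pair_key(dB1, dB2)))
    dA1 <- dA1[dk]; dA2 <- dA2[dk]; dB1 <- dB1[dk]; dB2 <- dB2[dk]
  } else dA1 <- dA2 <- dB1 <- dB2 <- integer(0)
  nd <- length(dA1)

  lbB <- clique_bound(adjB)

  best <- list(total = Inf, key = NULL, colA = NULL, colB = NULL, nA = NA_integer_)
  sols <- new.env(parent = emptyenv()); sol_cap <- 8L

  colA <- integer(pA); colB <- integer(pB)

  # disjunction checks against partial colourings; a colour of 0 means
  # unassigned. Phase A: a disjunction whose A-pair is decided unequal and
  # whose B-pair is joined by an inequality edge can never be satisfied.
  ok_A_partial <- function(v) {
    for (k in seq_len(nd)) {
      a1 <- dA1[k]; a2 <- dA2[k]
      if (a1 > v || a2 > v) next
      if (colA[a1] != colA[a2] && adjB[dB1[k], dB2[k]]) return(FALSE)
    }
    TRUE
  }
  ok_B_partial <- function(v) {
    for (k in seq_len(nd)) {
      b1 <- dB1[k]; b2 <- dB2[k]
      if (b1 > v || b2 > v) next
      if (colA[dA1[k]] != colA[dA2[k]] && colB[b1] != colB[b2]) return(FALSE)
    }
    TRUE
  }

  record <- function(usedA, usedB) {
    total <- usedA + usedB
    keyA <- paste(colA[cA], collapse = ",")
    keyB <- paste(colB[cB], collapse = ",")
    key <- paste(keyA, keyB, sep = ";")
    if (total < best$total ||
        (total == best$total && (usedA < best$nA ||
          (usedA == best$nA && key < best$key)))) {
      if (total < best$total) {
        rm(list = ls(sols), envir = sols)
      }
      best <<- list(total = total, key = key, colA = colA[cA], colB = colB[cB],
                    nA = usedA)
    }
    if (total == best$total && length(ls(sols)) < sol_cap) assign(key, TRUE, sols)
  }

  dfsB <- function(v, usedB, usedA) {
    if (usedA + max(usedB, lbB) > best$total) return(invisible())
    if (v > pB) { record(usedA, usedB); return(invisible()) }
    for (co in seq_len(min(usedB + 1L, best$total - usedA))) {
      if (v > 1L && any(adjB[v, seq_len(v - 1L)] & colB[seq_len(v - 1L)] == co)) next
      colB[v] <<- co
      if (ok_B_partial(v)) dfsB(v + 1L, max(usedB, co), usedA)
      colB[v] <<- 0L
    }
  }

  dfsA <- function(v, usedA) {
    if (usedA + lbB > best$total) return(invisible())
    if (v > pA) { dfsB(1L, 0L, usedA); return(invisible()) }
    for (co in seq_len(usedA + 1L)) {
      if (v > 1L && any(adjA[v, seq_len(v - 1L)] & colA[seq_len(v - 1L)] == co)) next
      colA[v] <<- co
      if (ok_A_partial(v)) dfsA(v + 1L, max(usedA, co))
      colA[v] <<- 0L
    }
  }
  dfsA(1L, 0L)

  if (!is.finite(best$total)) stop("no consistent assignment found (unsatisfiable constraints)")

  # class labels by first appearance in monokaryon order
  relabel <- function(v) match(v, v[!duplicated(v)])
  a_lab <- relabel(best$colA); b_lab <- relabel(best$colB)
  assignment <- data.frame(
    monokaryon = mons,
    matA = paste0("A", a_lab),
    matB = paste0("B", b_lab),
    stringsAsFactors = FALSE
  )
  n_sols <- if (count_solutions) length(ls(sols)) else NA_integer_
  structure(list(
    assignment = assignment,
    n_A = max(a_lab), n_B = max(b_lab),
    forced = pc$forced,
    unique_up_to_relabeling = if (count_solutions) n_sols == 1L else NA,
    n_optimal_solutions = n_sols,
    chosen_merges = (pA - max(a_lab)) + (pB - max(b_lab)),
    open_disjunctions = nd
  ), class = "allele_assignment")
}

#' @export
print.allele_assignment <- function(x, ...) {
  cat("<allele_assignment> ", nrow(x$assignment), " monokaryons: n_A = ",
      x$n_A, ", n_B = ", x$n_B,
      if (isTRUE(x$unique_up_to_relabeling)) " (unique up to relabeling)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Genotypes of an assignment, for forward prediction
#'
#' @param x An `allele_assignment`.
#' @return Named list of [mating_genotype()]s keyed by monokaryon id.
#' @export
assignment_genotypes <- function(x) {
  stopifnot(inherits(x, "allele_assignment"))
  out <- Map(mating_genotype, x$assignment$matA, x$assignment$matB)
  names(out) <- x$assignment$monokaryon
  out
}

# ---------------------------------------------------------------------------
# Brute-force oracle
# ---------------------------------------------------------------------------

#' Exhaustive minimal allele counts (verification oracle)
#'
#' Independent of [minimal_assignment()]: enumerates label assignments
#' monokaryon by monokaryon, canonically restricted per locus
#' (restricted-growth strings), under ascending caps on the class counts,
#' and returns the first satisfiable `(n_A, n_B)` in (total, then `n_A`)
#' order. No propagation, no component graphs. Exponential: refuses
#' instances above `max_monokaryons`. Intended for tests.
#'
#' @param cs A `constraint_set`.
#' @param max_monokaryons Refusal threshold (default 12).
#' @return Integer vector `c(n_A, n_B)`.
#' @export
brute_force_allele_counts <- function(cs, max_monokaryons = 12L) {
  stopifnot(inherits(cs, "constraint_set"))
  mons <- cs$monokaryons
  n <- length(mons)
  if (n > max_monokaryons) {
    stop("instance too large for brute force (", n, " > ", max_monokaryons, " monokaryons)")
  }
  if (n == 0L) return(c(n_A = 0L, n_B = 0L))
  idx <- function(m) match(m, mons)
  iA <- cs$ineq[cs$ineq$locus == "A", , drop = FALSE]
  iB <- cs$ineq[cs$ineq$locus == "B", , drop = FALSE]
  eA <- cs$eq[cs$eq$locus == "A", , drop = FALSE]
  eB <- cs$eq[cs$eq$locus == "B", , drop = FALSE]
  con <- list(
    iA = cbind(idx(iA$m1), idx(iA$m2)), iB = cbind(idx(iB$m1), idx(iB$m2)),
    eA = cbind(idx(eA$m1), idx(eA$m2)), eB = cbind(idx(eB$m1), idx(eB$m2)),
    dj = cbind(idx(cs$disj$m1), idx(cs$disj$m2))
  )

  a <- integer(n); b <- integer(n)
  ok_at <- function(i) {
    chk <- function(M, f) {
      for (r in seq_len(nrow(M))) {
        u <- M[r, 1L]; v <- M[r, 2L]
        if ((u == i && v <= i) || (v == i && u <= i)) {
          if (!f(u, v)) return(FALSE)
        }
      }
      TRUE
    }
    chk(con$iA, function(u, v) a[u] != a[v]) &&
      chk(con$iB, function(u, v) b[u] != b[v]) &&
      chk(con$eA, function(u, v) a[u] == a[v]) &&
      chk(con$eB, function(u, v) b[u] == b[v]) &&
      chk(con$dj, function(u, v) a[u] == a[v] || b[u] == b[v])
  }

  sat <- function(i, maxa, maxb, capA, capB) {
    if (i > n) return(TRUE)
    for (ai in seq_len(min(maxa + 1L, capA))) {
      a[i] <<- ai
      for (bi in seq_len(min(maxb + 1L, capB))) {
        b[i] <<- bi
        if (ok_at(i) &&
            sat(i + 1L, max(maxa, ai), max(maxb, bi), capA, capB)) return(TRUE)
      }
    }
    a[i] <<- 0L; b[i] <<- 0L
    FALSE
  }

  for (s in 2L:(2L * n)) {
    for (nA in seq_len(min(s - 1L, n))) {
      nB <- s - nA
      if (nB > n) next
      if (sat(1L, 0L, 0L, nA, nB)) {
        # confirm the caps are tight (the found solution may use fewer)
        return(c(n_A = max(a), n_B = max(b)))
      }
    }
  }
  stop("unsatisfiable constraint set")   # unreachable: caps reach (n, n)
}

# ---------------------------------------------------------------------------
# Di-mon consistency reports
# ---------------------------------------------------------------------------

#' Consistency analysis of di-mon (Buller) crossing rows
#'
#' Di-mon rows carry no allele labels of their own; what they support is a
#' consistency question: which dikaryon genotypes could have produced the
#' observed row against a genotyped tester panel? The answer is obtained by
#' exhaustive enumeration over a bounded allele universe (the alleles
#' observed among the testers plus `n_fresh` fresh alleles per locus, which
#' suffices because the Buller rule only distinguishes equal-to-observed
#' from different). A row is flagged inconsistent if no valid dikaryon
#' reproduces it, and the report states whether every satisfying genotype
#' requires a novel (unobserved) allele at either locus.
#'
#' @param tab A [cross_table()] whose dikaryon rows are to be analysed.
#' @param testers Named list of tester genotypes (names = column labels), or
#'   a [panel_spec()] with genotypes.
#' @param n_fresh Fresh alleles per locus in the enumeration universe.
#' @return A data frame with one row per dikaryon row: `strain`,
#'   `satisfiable`, `n_genotypes` (satisfying dikaryon genotypes),
#'   `forced_novel_A`, `forced_novel_B`, and `example` (one satisfying
#'   genotype, or `NA`).
#' @export
check_dimon_consistency <- function(tab, testers, n_fresh = 2L) {
  stopifnot(inherits(tab, "cross_table"))
  if (inherits(testers, "panel_spec")) {
    if (is.null(testers$genotypes)) stop("panel_spec has no genotypes")
    g <- lapply(testers$genotypes, parse_genotype)
    names(g) <- testers$testers
    testers <- g
  }
  testers <- lapply(testers, as_genotype)
  cols <- colnames(tab$entries)
  if (!all(cols %in% names(testers))) {
    stop("missing tester genotypes for columns: ",
         paste(setdiff(cols, names(testers)), collapse = ", "))
  }
  testers <- testers[cols]

  obsA <- unique(vapply(testers, function(g) g$a, character(1)))
  obsB <- unique(vapply(testers, function(g) g$b, character(1)))
  freshA <- paste0("A.novel", seq_len(n_fresh))
  freshB <- paste0("B.novel", seq_len(n_fresh))
  allA <- c(obsA, freshA); allB <- c(obsB, freshB)

  # all unordered valid dikaryons over the bounded universe
  nuclei <- expand.grid(a = allA, b = allB, stringsAsFactors = FALSE)
  nn <- nrow(nuclei)
  cand <- list()
  for (i in seq_len(nn - 1L)) {
    for (j in (i + 1L):nn) {
      if (nuclei$a[i] != nuclei$a[j] && nuclei$b[i] != nuclei$b[j]) {
        cand[[length(cand) + 1L]] <- list(
          n1 = mating_genotype(nuclei$a[i], nuclei$b[i]),
          n2 = mating_genotype(nuclei$a[j], nuclei$b[j]))
      }
    }
  }

  rows <- which(tab$row_kind == "dikaryon")
  out <- data.frame(strain = rownames(tab$entries)[rows],
                    satisfiable = NA, n_genotypes = NA_integer_,
                    forced_novel_A = NA, forced_novel_B = NA,
                    example = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_along(rows)) {
    obs <- tab$entries[rows[r], ]
    hits <- logical(length(cand))
    usesA <- logical(length(cand)); usesB <- logical(length(cand))
    for (k in seq_along(cand)) {
      d <- cand[[k]]
      match_all <- TRUE
      for (j in seq_along(testers)) {
        if (is.na(obs[j])) next
        pred <- compatible(d$n1, testers[[j]]) || compatible(d$n2, testers[[j]])
        if (pred != (obs[j] == PLUS)) { match_all <- FALSE; break }
      }
      if (match_all) {
        hits[k] <- TRUE
        usesA[k] <- d$n1$a %in% freshA || d$n2$a %in% freshA
        usesB[k] <- d$n1$b %in% freshB || d$n2$b %in% freshB
      }
    }
    out$satisfiable[r] <- any(hits)
    out$n_genotypes[r] <- sum(hits)
    out$forced_novel_A[r] <- any(hits) && all(usesA[hits])
    out$forced_novel_B[r] <- any(hits) && all(usesB[hits])
    if (any(hits)) {
      d <- cand[[which(hits)[1L]]]
      out$example[r] <- paste0(format(d$n1), "+", format(d$n2))
    }
  }
  out
}
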