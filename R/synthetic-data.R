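# Seeded simulators for the two kinds of data the package analyses:
# (1) a natural population of dikaryotic isolates drawn from allele pools at
#     the two mating-type loci, with tester panels and crossing matrices;
# (2) homeodomain-like protein sequences with the structural features the
#     sequence analyses look for (embedded WFXNXR motif, HD1 longer than
#     HD2, hydrophilic/globular composition, variable N-terminus).

#' Population simulation configuration
#'
#' Defaults reflect the allelic richness previously reported for
#' *P. ostreatus* populations (24 matA alleles, 21 matB alleles) and a
#' collection of 17 natural isolates.
#'
#' @param n_A_pool,n_B_pool Allele pool sizes (>= 2).
#' @param n_isolates Number of dikaryotic isolates to draw.
#' @param freq `"uniform"` allele frequencies, or `"dirichlet"` for a skewed
#'   spectrum drawn once per locus.
#' @param concentration Dirichlet concentration (used when
#'   `freq = "dirichlet"`); smaller is more skewed.
#' @param error_rate Probability that any one crossing-table cell is scored
#'   wrongly (symmetric flip). Clamp scoring is treated as reliable, so the
#'   default is 0.
#' @param seed Mandatory integer seed.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_A_pool = 24L, n_B_pool = 21L, n_isolates = 17L,
                              freq = c("uniform", "dirichlet"),
                              concentration = 1, error_rate = 0, seed) {
  freq <- match.arg(freq)
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_A_pool >= 2L, n_B_pool >= 2L, n_isolates >= 1L,
            error_rate >= 0, error_rate <= 1, concentration > 0)
  structure(list(n_A_pool = as.integer(n_A_pool), n_B_pool = as.integer(n_B_pool),
                 n_isolates = as.integer(n_isolates), freq = freq,
                 concentration = concentration, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "population_config")
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

#' Simulate a population crossing study
#'
#' Draws `n_isolates` dikaryons from the configured allele pools (rejection
#' sampling until the two nuclei are heteroallelic at both loci), derives the
#' four-tester panel of each by [spore_types()], predicts the full pairwise
#' mon-mon crossing matrix of all testers with [predict_cross_table()], and
#' optionally a di-mon table of the dikaryotic isolates against a reference
#' panel. With `error_rate > 0` every cell is flipped independently with that
#' probability. Fully reproducible from the seed.
#'
#' @param cfg A [population_config()].
#' @param dimon_reference Optional isolate index whose panel serves as the
#'   reference for a di-mon table of all isolates (NULL = no di-mon table).
#' @return A list of class `simulated_population`: `isolates` (dikaryons),
#'   `panels` ([panel_spec()]s with true genotypes), `monmon`
#'   ([cross_table()]), optional `dimon`, and `truth` (the distinct allele
#'   counts truly present among the testers, `n_A`/`n_B`).
#' @export
simulate_population <- function(cfg, dimon_reference = NULL) {
  stopifnot(inherits(cfg, "population_config"))
  set.seed(cfg$seed)
  pA <- switch(cfg$freq, uniform = rep(1 / cfg$n_A_pool, cfg$n_A_pool),
               dirichlet = rdirichlet1(cfg$n_A_pool, cfg$concentration))
  pB <- switch(cfg$freq, uniform = rep(1 / cfg$n_B_pool, cfg$n_B_pool),
               dirichlet = rdirichlet1(cfg$n_B_pool, cfg$concentration))
  draw_nucleus <- function() {
    mating_genotype(paste0("A", sample.int(cfg$n_A_pool, 1L, prob = pA)),
                    paste0("B", sample.int(cfg$n_B_pool, 1L, prob = pB)))
  }
  isolates <- vector("list", cfg$n_isolates)
  for (i in seq_len(cfg$n_isolates)) {
    repeat {
      n1 <- draw_nucleus(); n2 <- draw_nucleus()
      if (n1$a != n2$a && n1$b != n2$b) break
    }
    isolates[[i]] <- dikaryon(n1, n2)
  }
  names(isolates) <- paste0("S", seq_len(cfg$n_isolates))

  panels <- vector("list", cfg$n_isolates)
  testers <- list()
  for (i in seq_len(cfg$n_isolates)) {
    sp <- spore_types(isolates[[i]])
    ids <- paste0("S", i, ".m", 1:4)
    panels[[i]] <- panel_spec(paste0("S", i), ids,
                              genotypes = vapply(sp, format, character(1)))
    names(sp) <- ids
    testers <- c(testers, sp)
  }
  names(panels) <- names(isolates)

  monmon <- predict_cross_table(testers)
  if (cfg$error_rate > 0) {
    ent <- monmon$entries
    flip <- matrix(stats::runif(length(ent)) < cfg$error_rate, nrow(ent))
    ent[flip] <- ifelse(ent[flip] == PLUS, MINUS, PLUS)
    monmon <- cross_table(ent, row_kind = "monokaryon")
  }

  dimon <- NULL
  if (!is.null(dimon_reference)) {
    ref <- panels[[dimon_reference]]
    ref_testers <- stats::setNames(lapply(ref$genotypes, parse_genotype), ref$testers)
    dimon <- predict_cross_table(isolates, cols = ref_testers)
    if (cfg$error_rate > 0) {
      ent <- dimon$entries
      flip <- matrix(stats::runif(length(ent)) < cfg$error_rate, nrow(ent))
      ent[flip] <- ifelse(ent[flip] == PLUS, MINUS, PLUS)
      dimon <- cross_table(ent, row_kind = "dikaryon")
    }
  }

  truth <- c(
    n_A = length(unique(vapply(testers, function(g) g$a, character(1)))),
    n_B = length(unique(vapply(testers, function(g) g$b, character(1))))
  )
  structure(list(isolates = isolates, panels = panels, monmon = monmon,
                 dimon = dimon, truth = truth, config = cfg),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat("<simulated_population> ", length(x$isolates), " isolates, ",
      nrow(x$monmon$entries), " testers; true n_A = ", x$truth["n_A"],
      ", n_B = ", x$truth["n_B"], "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Homeodomain-like protein generator
# ---------------------------------------------------------------------------

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic homeodomain protein configuration
#'
#' Encodes the structural expectations for the two classes of homeodomain
#' transcription factors of the matA locus: HD1 proteins run 40-50 residues
#' longer than HD2, and the conserved WFXNXR DNA-binding motif sits at
#' residues 125-175 in HD1 versus 145-200 in HD2. The N-terminal
#' dimerisation region is hypervariable between alleles; `n_term_variability`
#' is the per-residue resampling rate used when deriving allelic variants
#' (no quantitative divergence level is established for real alleles; 0.5 is
#' this package's default).
#'
#' @param class `"HD1"` or `"HD2"`.
#' @param hd2_length_range Range the HD2 backbone length is drawn from.
#' @param hd1_extra_range HD1 length surplus over HD2, drawn uniformly.
#' @param motif_window 1-based residue interval the WFXNXR motif start is
#'   placed in; defaults depend on `class` (125-175 for HD1, 145-200 for
#'   HD2; the match must end inside the window).
#' @param n_term_variability Per-residue N-terminal resampling rate in
#'   `[0, 1]`.
#' @param n_term_length Length of the variable N-terminal region.
#' @param seed Mandatory integer seed.
#' @return A list of class `hd_protein_config`.
#' @export
hd_protein_config <- function(class = c("HD2", "HD1"),
                              hd2_length_range = c(210L, 240L),
                              hd1_extra_range = c(40L, 50L),
                              motif_window = NULL,
                              n_term_variability = 0.5,
                              n_term_length = 60L,
                              seed) {
  class <- match.arg(class)
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  if (is.null(motif_window)) {
    motif_window <- if (class == "HD1") c(125L, 175L) else c(145L, 200L)
  }
  stopifnot(length(motif_window) == 2L, motif_window[1L] >= 1L,
            motif_window[1L] <= motif_window[2L],
            n_term_variability >= 0, n_term_variability <= 1)
  structure(list(class = class,
                 hd2_length_range = as.integer(hd2_length_range),
                 hd1_extra_range = as.integer(hd1_extra_range),
                 motif_window = as.integer(motif_window),
                 n_term_variability = n_term_variability,
                 n_term_length = as.integer(n_term_length),
                 seed = as.integer(seed)),
            class = "hd_protein_config")
}

# Hydrophilic-biased residue sampler: weights decay with the Kyte-Doolittle
# value, so hydrophobic runs are rare and the rejection step below almost
# never loops.
sample_hydrophilic <- function(n) {
  w <- exp(-kyte_doolittle_scale()[AA20] / 2)
  sample(AA20, n, replace = TRUE, prob = w)
}

instantiate_motif <- function(pattern = "WFXNXR") {
  ch <- strsplit(pattern, "")[[1]]
  ch[ch == "X"] <- sample(AA20, sum(ch == "X"), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a homeodomain-like protein sequence
#'
#' Builds a sequence over the 20-residue alphabet with hydrophilic-biased
#' composition, one WFXNXR instance placed uniformly inside the configured
#' window (random X residues), and, for class HD1, one HNPYP(T/S) instance
#' upstream of the homeodomain (the motif found in HD1 proteins only).
#' Regions that would create a spurious WFXNXR match or a
#' transmembrane-grade hydrophobic stretch (19-residue mean hydropathy above
#' 1.6) are resampled, so every output is globular and carries exactly one
#' WFXNXR hit. Ground truth is returned alongside the sequence.
#'
#' @param cfg An [hd_protein_config()].
#' @param length_override Optional exact sequence length (used for paired
#'   HD1/HD2 draws); must accommodate the motif window.
#' @return A list of class `hd_protein`: `sequence`, `class`, `length`,
#'   `motif_start`, `motif_seq`, and for HD1 `hnpyp_start`.
#' @export
generate_hd_protein <- function(cfg, length_override = NULL) {
  stopifnot(inherits(cfg, "hd_protein_config"))
  set.seed(cfg$seed)
  len <- if (!is.null(length_override)) as.integer(length_override)
         else {
           base <- sample(seq(cfg$hd2_length_range[1L], cfg$hd2_length_range[2L]), 1L)
           if (cfg$class == "HD1")
             base + sample(seq(cfg$hd1_extra_range[1L], cfg$hd1_extra_range[2L]), 1L)
           else base
         }
  if (cfg$motif_window[2L] > len) {
    stop("motif window [", cfg$motif_window[1L], ", ", cfg$motif_window[2L],
         "] does not fit a sequence of length ", len)
  }
  motif <- instantiate_motif("WFXNXR")
  # the whole match must lie inside the window
  last_start <- cfg$motif_window[2L] - nchar(motif) + 1L
  if (last_start < cfg$motif_window[1L]) stop("motif window too narrow for WFXNXR")
  start <- sample(seq(cfg$motif_window[1L], last_start), 1L)

  seq_ch <- sample_hydrophilic(len)
  seq_ch[seq(start, start + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]

  hnpyp_start <- NA_integer_
  if (cfg$class == "HD1") {
    hn <- paste0("HNPYP", sample(c("T", "S"), 1L))
    hnpyp_start <- sample(seq(10L, max(11L, cfg$motif_window[1L] - 40L)), 1L)
    seq_ch[seq(hnpyp_start, hnpyp_start + 5L)] <- strsplit(hn, "")[[1]]
  }

  protected <- seq(start, start + nchar(motif) - 1L)
  if (!is.na(hnpyp_start)) protected <- c(protected, seq(hnpyp_start, hnpyp_start + 5L))

  seq_str <- paste(seq_ch, collapse = "")
  for (iter in 1:200) {
    bad <- integer(0)
    # spurious WFXNXR matches outside the planted one
    hits <- motif_scan(seq_str, "WFXNXR")
    for (h in hits$start[hits$start != start]) bad <- c(bad, seq(h, h + 5L))
    if (cfg$class == "HD2") {
      hh <- motif_scan(seq_str, "HNPYP[TS]")
      for (h in hh$start) bad <- c(bad, seq(h, h + 5L))
    }
    # transmembrane-grade hydrophobic windows
    if (len >= 19L) {
      prof <- kd_profile(seq_str, window = 19L)
      for (p in prof$position[prof$value > 1.6]) bad <- c(bad, seq(p - 9L, p + 9L))
    }
    bad <- setdiff(unique(bad), protected)
    bad <- bad[bad >= 1L & bad <= len]
    if (!length(bad)) break
    seq_ch[bad] <- sample_hydrophilic(length(bad))
    seq_str <- paste(seq_ch, collapse = "")
  }

  structure(list(sequence = seq_str, class = cfg$class, length = len,
                 motif_start = start, motif_seq = motif,
                 hnpyp_start = hnpyp_start, config = cfg),
            class = "hd_protein")
}

#' @export
print.hd_protein <- function(x, ...) {
  cat("<hd_protein> class ", x$class, ", ", x$length, " aa, WFXNXR at ",
      x$motif_start, "\n", sep = "")
  invisible(x)
}

#' Generate a paired HD1/HD2 protein draw
#'
#' Draws an HD2 backbone length, sets the HD1 length 40-50 residues longer
#' (uniform), and generates one protein of each class. This mirrors the
#' length relation observed between the two classes of homeodomain proteins
#' encoded in one matA cassette.
#'
#' @param seed Integer seed.
#' @param ... Passed to [hd_protein_config()] (except `class` and `seed`).
#' @return List with elements `hd1` and `hd2` (class `hd_protein`).
#' @export
generate_hd_pair <- function(seed, ...) {
  set.seed(seed)
  cfg2 <- hd_protein_config(class = "HD2", seed = seed + 1L, ...)
  hd2_len <- sample(seq(cfg2$hd2_length_range[1L], cfg2$hd2_length_range[2L]), 1L)
  extra <- sample(seq(cfg2$hd1_extra_range[1L], cfg2$hd1_extra_range[2L]), 1L)
  cfg1 <- hd_protein_config(class = "HD1", seed = seed + 2L, ...)
  list(hd1 = generate_hd_protein(cfg1, length_override = hd2_len + extra),
       hd2 = generate_hd_protein(cfg2, length_override = hd2_len))
}

#' Write hd_protein objects to FASTA
#'
#' @param proteins List of `hd_protein` objects.
#' @param file Output FASTA path (wrapped at 60 columns).
#' @param ids Optional sequence names; defaults to `class_i`.
#' @return `file`, invisibly.
#' @export
write_hd_fasta <- function(proteins, file, ids = NULL) {
  seqs <- vapply(proteins, function(p) p$sequence, character(1))
  if (is.null(ids)) {
    ids <- paste0(vapply(proteins, function(p) p$class, character(1)),
                  "_", seq_along(proteins))
  }
  x <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(x, file, width = 60L)
  invisible(file)
}
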