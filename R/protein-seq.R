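# Sequence-level analyses of homeodomain proteins: wildcard motif scanning,
# Kyte-Doolittle hydropathy with a transmembrane/globular call, a
# compositional nuclear-localization-signal screen, HD1-vs-HD2 length
# comparison, and a gene-cassette model of the matA locus with GFF3 export.

#' Kyte-Doolittle hydropathy scale
#'
#' The per-residue hydropathy constants of Kyte & Doolittle (1982),
#' J. Mol. Biol. 157:105-132, Table 1: positive is hydrophobic (isoleucine
#' +4.5) and negative hydrophilic (arginine -4.5).
#'
#' @return Named numeric vector over the 20 amino acids (one-letter codes).
#' @export
kyte_doolittle_scale <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

check_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(ch %in% names(kyte_doolittle_scale())))
  if (length(bad)) {
    stop("invalid residue symbol '", ch[bad[1L]], "' at position ", bad[1L])
  }
  ch
}

# ---------------------------------------------------------------------------
# Motif scanning
# ---------------------------------------------------------------------------

# Pattern grammar: upper-case residue letters match themselves, X matches any
# residue, and [..] matches any residue listed inside the brackets
# (e.g. HNPYP[TS] encodes the HNPYPT/S motif of HD1 proteins).
parse_motif_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  aa <- names(kyte_doolittle_scale())
  out <- list()
  i <- 1L
  ch <- strsplit(pattern, "")[[1]]
  while (i <= length(ch)) {
    if (ch[i] == "[") {
      j <- i + 1L
      alt <- character(0)
      while (j <= length(ch) && ch[j] != "]") { alt <- c(alt, ch[j]); j <- j + 1L }
      if (j > length(ch)) stop("unterminated '[' in motif pattern '", pattern, "'")
      if (!length(alt) || !all(alt %in% aa)) {
        stop("invalid alternative set in motif pattern '", pattern, "'")
      }
      out[[length(out) + 1L]] <- alt
      i <- j + 1L
    } else if (ch[i] == "X") {
      out[[length(out) + 1L]] <- aa
      i <- i + 1L
    } else if (ch[i] %in% aa) {
      out[[length(out) + 1L]] <- ch[i]
      i <- i + 1L
    } else {
      stop("invalid symbol '", ch[i], "' in motif pattern '", pattern, "'")
    }
  }
  out
}

#' Scan a protein sequence for a wildcard motif
#'
#' Reports every occurrence (overlapping ones included) of a motif pattern
#' such as `"WFXNXR"` — the conserved DNA-binding hexamer of the third
#' homeodomain alpha-helix — or `"HNPYP[TS]"`. `X` matches any residue,
#' `[TS]` either listed residue. Matching is case-insensitive over the
#' 20-residue alphabet.
#'
#' @param seq Protein sequence (character scalar).
#' @param pattern Motif pattern string.
#' @param id Optional sequence identifier carried into the result.
#' @return A data frame of hits in ascending order: `id`, `start` (1-based),
#'   `end`, `match`.
#' @examples
#' motif_scan("MARKSMMTDRQIEVWFQNHRNSR", "WFXNXR")
#' @export
motif_scan <- function(seq, pattern, id = NA_character_) {
  ch <- check_protein(seq)
  pat <- parse_motif_pattern(pattern)
  k <- length(pat)
  n <- length(ch)
  starts <- integer(0)
  if (n >= k) {
    for (s in seq_len(n - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!(ch[s + j - 1L] %in% pat[[j]])) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, s)
    }
  }
  data.frame(
    id = rep(id, length(starts)),
    start = starts,
    end = starts + k - 1L,
    match = vapply(starts, function(s) paste(ch[s:(s + k - 1L)], collapse = ""),
                   character(1)),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Hydropathy
# ---------------------------------------------------------------------------

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding arithmetic mean of per-residue hydropathy values over an odd
#' window; each value is reported at the window's centre residue. Window 19
#' is the conventional choice for transmembrane-segment detection; window 9
#' favours surface features.
#'
#' @param seq Protein sequence.
#' @param window Odd window size, at most the sequence length.
#' @return An object of class `hydropathy_profile`: `position` (centre
#'   residue, 1-based), `value`, `window`, `scale`.
#' @examples
#' kd_profile("III", window = 3)$value   # 4.5
#' @export
kd_profile <- function(seq, window = 19L) {
  ch <- check_protein(seq)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (window > length(ch)) {
    stop("window (", window, ") exceeds sequence length (", length(ch), ")")
  }
  sc <- kyte_doolittle_scale()
  vals <- sc[ch]
  means <- as.numeric(stats::filter(vals, rep(1 / window, window), sides = 2L))
  half <- (window - 1L) %/% 2L
  centres <- seq(half + 1L, length(ch) - half)
  structure(list(position = centres, value = means[centres],
                 window = window, scale = sc),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat("<hydropathy_profile> window ", x$window, ", ", length(x$position),
      " positions, range [", round(min(x$value), 2), ", ",
      round(max(x$value), 2), "]\n", sep = "")
  invisible(x)
}

#' Call a protein globular or transmembrane from its hydropathy profile
#'
#' A transmembrane region is a maximal run of window centres whose mean
#' hydropathy exceeds `tm_threshold`; a protein without any such run is
#' called globular — the expectation for nuclear transcription factors such
#' as the homeodomain proteins. The default threshold 1.6 is the
#' conventional Kyte-Doolittle cutoff for a 19-residue window.
#'
#' @param profile A [kd_profile()] result (window >= 7 recommended).
#' @param tm_threshold Hydropathy cutoff.
#' @return A list: `call` (`"globular"` or `"has_transmembrane"`) and
#'   `regions`, a data frame of runs (`start`, `end` in centre-residue
#'   coordinates, `max_value`).
#' @export
call_globular <- function(profile, tm_threshold = 1.6) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  above <- profile$value > tm_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  regions <- data.frame(
    start = profile$position[starts[keep]],
    end = profile$position[ends[keep]],
    max_value = vapply(keep, function(k) {
      max(profile$value[starts[k]:ends[k]])
    }, numeric(1))
  )
  list(call = if (nrow(regions)) "has_transmembrane" else "globular",
       regions = regions)
}

# ---------------------------------------------------------------------------
# NLS composition screen
# ---------------------------------------------------------------------------

#' Screen for composition-based nuclear localization signal candidates
#'
#' Slides a window over the sequence and reports stretches enriched either
#' in the basic residues arginine/lysine (class `"KR"`) or in
#' proline/histidine (class `"PH"`) — the residue classes used as NLS
#' markers. Overlapping candidate windows of the same class are merged into
#' maximal intervals. This is a composition heuristic, not a trained
#' localization predictor.
#'
#' @param seq Protein sequence.
#' @param window Window length (>= 4; default 7).
#' @param min_fraction Minimum fraction of marker residues in a window
#'   (default 4/7).
#' @return Data frame of merged candidates: `class`, `start`, `end`
#'   (1-based residue coordinates of the merged interval).
#' @examples
#' nls_screen("KRKRKRK")
#' @export
nls_screen <- function(seq, window = 7L, min_fraction = 4 / 7) {
  ch <- check_protein(seq)
  window <- as.integer(window)
  if (window < 4L) stop("window must be >= 4")
  n <- length(ch)
  if (n < window) {
    return(data.frame(class = character(0), start = integer(0), end = integer(0)))
  }
  hit_windows <- function(marker) {
    ind <- as.numeric(ch %in% marker)
    counts <- as.numeric(stats::filter(ind, rep(1, window), sides = 1L))
    starts <- which(counts[window:n] / window >= min_fraction)
    starts   # window start positions
  }
  merge_runs <- function(starts, cls) {
    if (!length(starts)) {
      return(data.frame(class = character(0), start = integer(0), end = integer(0)))
    }
    ends <- starts + window - 1L
    # overlapping windows (start <= running max end) share a group
    grp <- cumsum(c(TRUE, starts[-1L] > cummax(ends)[-length(ends)]))
    data.frame(class = cls,
               start = tapply(starts, grp, min),
               end = tapply(ends, grp, max),
               row.names = NULL)
  }
  out <- rbind(merge_runs(hit_windows(c("K", "R")), "KR"),
               merge_runs(hit_windows(c("P", "H")), "PH"))
  out[order(out$start, out$class), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Length comparison
# ---------------------------------------------------------------------------

#' Compare HD1 and HD2 sequence lengths
#'
#' Descriptive comparison of two sets of protein sequences (or lengths):
#' when the sets pair up one-to-one the differences are per-pair, otherwise
#' all cross-set differences are reported. No thresholding: class HD1
#' proteins are expected, but not required, to run ~40-50 residues longer.
#'
#' @param hd1,hd2 Character vectors of sequences, lists of `hd_protein`
#'   objects, or numeric length vectors. Must be non-empty.
#' @return A list: `differences` (numeric), `mean_difference`, `range`,
#'   `paired` (logical).
#' @export
compare_lengths <- function(hd1, hd2) {
  as_len <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    if (is.list(x)) x <- vapply(x, function(p) p$sequence, character(1))
    nchar(x)
  }
  l1 <- as_len(hd1); l2 <- as_len(hd2)
  if (!length(l1) || !length(l2)) stop("both sequence sets must be non-empty")
  paired <- length(l1) == length(l2)
  diffs <- if (paired) l1 - l2 else as.numeric(outer(l1, l2, "-"))
  list(differences = diffs, mean_difference = mean(diffs),
       range = range(diffs), paired = paired)
}

# ---------------------------------------------------------------------------
# matA locus cassette model and GFF3 export
# ---------------------------------------------------------------------------

LOCUS_GENES <- c("mip", "hd1", "hd1.1", "hd1.2", "hd2", "fg")

#' Gene-cassette model of a matA locus
#'
#' The matA locus is a cassette of one to three homeodomain genes (`hd1`,
#' `hd1.1`, `hd1.2`, `hd2`) flanked by the conserved `mip` gene
#' (mitochondrial intermediate peptidase) upstream and the `fg`
#' (beta-flanking) gene downstream. When both `hd1.1` and `hd1.2` are
#' present they are transcribed divergently (opposite strands).
#'
#' @param strain Strain identifier (e.g. `"PC9"`).
#' @param genes Ordered character vector of gene names from
#'   `mip`, `hd1`, `hd1.1`, `hd1.2`, `hd2`, `fg`, starting with `mip` and
#'   ending with `fg`.
#' @param strands Strand per gene (`"+"`/`"-"`), same length as `genes`.
#' @return An object of class `locus_model`.
#' @examples
#' locus_model("PC9", c("mip", "hd1", "hd2", "fg"), c("+", "-", "+", "+"))
#' @export
locus_model <- function(strain, genes, strands) {
  stopifnot(is.character(strain), length(strain) == 1L,
            is.character(genes), is.character(strands),
            length(strands) == length(genes))
  bad <- setdiff(genes, LOCUS_GENES)
  if (length(bad)) stop("unknown locus gene(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(genes)) stop("duplicate gene names in locus model")
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'")
  if (genes[1L] != "mip") stop("locus model must start with the flanking 'mip' gene")
  if (genes[length(genes)] != "fg") stop("locus model must end with the flanking 'fg' gene")
  hd <- setdiff(genes, c("mip", "fg"))
  if (length(hd) < 1L || length(hd) > 3L) {
    stop("locus model must carry 1-3 hd genes between mip and fg, got ", length(hd))
  }
  if (all(c("hd1.1", "hd1.2") %in% genes)) {
    s <- strands[match(c("hd1.1", "hd1.2"), genes)]
    if (s[1L] == s[2L]) {
      stop("hd1.1 and hd1.2 must be divergently oriented (opposite strands)")
    }
  }
  structure(list(strain = strain, genes = genes, strands = strands),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model> ", x$strain, ": ",
      paste0(x$genes, "(", x$strands, ")", collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Export a matA locus model as GFF3
#'
#' Coordinates are ordinal placeholders on a per-strain scaffold (gene i
#' occupies a fixed-width slot), since the model captures gene order and
#' orientation only. One `gene` feature per cassette member.
#'
#' @param model A [locus_model()].
#' @param file Output GFF3 path.
#' @param slot_width Placeholder gene width in bp.
#' @param gap Placeholder intergenic gap in bp.
#' @return `file`, invisibly.
#' @export
write_locus_gff <- function(model, file, slot_width = 1000L, gap = 500L) {
  stopifnot(inherits(model, "locus_model"))
  n <- length(model$genes)
  starts <- (seq_len(n) - 1L) * (slot_width + gap) + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = paste0(model$strain, "_matA_scaffold"),
    ranges = IRanges::IRanges(start = starts, width = slot_width),
    strand = model$strands
  )
  gr$source <- "tetrapolar"
  gr$type <- "gene"
  gr$ID <- paste0(model$strain, "_", model$genes)
  gr$Name <- model$genes
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Read protein sequences from FASTA as plain characters
#'
#' Thin convenience wrapper over [Biostrings::readAAStringSet()] so that the
#' scanning and hydropathy functions (which take character scalars) apply
#' directly.
#'
#' @param file FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
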