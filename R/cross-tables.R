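# Labelled +/- compatibility matrices (mon-mon and di-mon crossing tables).
#
# Internally a cross_table stores a character matrix with entries "+", "-" or
# NA (missing / not crossed), plus a row_kind vector marking each row as a
# monokaryon or a dikaryon. The matrix is stored as recorded: symmetry of
# mon-mon tables is an invariant that is *checked*, not enforced, so that
# asymmetric experimental records can be represented and flagged.

PLUS <- "+"
MINUS <- "-"

#' Construct a cross table
#'
#' @param entries Character matrix over `"+"`, `"-"`, `NA`, with row and
#'   column dimnames (strain/tester identifiers).
#' @param row_kind Character vector, one of `"monokaryon"` / `"dikaryon"` per
#'   row; recycled if length 1.
#' @return An object of class `cross_table`.
#' @export
cross_table <- function(entries, row_kind = "monokaryon") {
  stopifnot(is.matrix(entries))
  if (is.null(rownames(entries)) || is.null(colnames(entries))) {
    stop("cross table entries must have row and column labels")
  }
  if (anyDuplicated(rownames(entries))) stop("duplicate row labels in cross table")
  if (anyDuplicated(colnames(entries))) stop("duplicate column labels in cross table")
  bad <- !(entries %in% c(PLUS, MINUS) | is.na(entries))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop("invalid cell value '", entries[idx], "' in cross table")
  }
  row_kind <- rep_len(match.arg(row_kind, c("monokaryon", "dikaryon"), several.ok = TRUE),
                      nrow(entries))
  structure(list(entries = entries, row_kind = row_kind), class = "cross_table")
}

#' @export
print.cross_table <- function(x, ...) {
  cat("<cross_table> ", nrow(x$entries), " x ", ncol(x$entries), " (",
      sum(x$row_kind == "dikaryon"), " dikaryon rows)\n", sep = "")
  disp <- x$entries
  disp[is.na(disp)] <- "?"
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
dim.cross_table <- function(x) dim(x$entries)

# Map one raw cell to "+", "-" or NA. Footnote asterisks (dagger-style table
# annotations) are stripped; en/em dashes are accepted as minus.
normalize_cell <- function(cell, where) {
  raw <- cell
  cell <- gsub("\\*", "", trimws(cell))
  if (is.na(cell) || cell == "" || cell == "?") return(NA_character_)
  if (cell == "+") return(PLUS)
  if (cell %in% c("-", "–", "—")) return(MINUS)
  stop("unknown cross-table symbol '", raw, "' at ", where)
}

#' Read a cross table from CSV/TSV
#'
#' Expects a header row of column labels and a first column of row labels.
#' Cells may be `+`, ASCII `-`, en-dash, em-dash, `?` or blank; `?`/blank map
#' to missing. Trailing asterisks (footnote markers) are stripped. Any other
#' symbol is an error reporting the offending row and column.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param row_kind `"monokaryon"` (default) or `"dikaryon"`, recycled per row.
#' @param check_symmetry If `TRUE` (default) and the row and column labels
#'   coincide as sets, conflicting symmetric mon-mon cells raise an error.
#' @return A [cross_table()].
#' @export
read_cross_table <- function(file, sep = ",", row_kind = "monokaryon",
                             check_symmetry = TRUE) {
  raw <- utils::read.table(file, sep = sep, header = TRUE, row.names = 1L,
                           colClasses = "character", check.names = FALSE,
                           blank.lines.skip = TRUE, quote = "\"",
                           na.strings = NULL, comment.char = "",
                           fileEncoding = "UTF-8")
  ent <- as.matrix(raw)
  out <- matrix(NA_character_, nrow(ent), ncol(ent), dimnames = dimnames(ent))
  for (i in seq_len(nrow(ent))) {
    for (j in seq_len(ncol(ent))) {
      out[i, j] <- normalize_cell(ent[i, j],
                                  paste0("row '", rownames(ent)[i], "', column '", colnames(ent)[j], "'"))
    }
  }
  tab <- cross_table(out, row_kind = row_kind)
  if (check_symmetry) check_cross_symmetry(tab)
  tab
}

# Symmetry invariant for mon-mon tables whose rows and columns index the same
# strains: where both orientations are recorded they must agree, and the
# diagonal cannot be "+" (self-crosses share both alleles).
check_cross_symmetry <- function(tab) {
  ent <- tab$entries
  common <- intersect(rownames(ent), colnames(ent))
  mono <- rownames(ent)[tab$row_kind == "monokaryon"]
  common <- intersect(common, mono)
  for (r in common) {
    if (!is.na(ent[r, r]) && ent[r, r] == PLUS) {
      stop("self-cross scored '+' for '", r, "': impossible under the tetrapolar model")
    }
    for (s in common) {
      a <- ent[r, s]; b <- ent[s, r]
      if (!is.na(a) && !is.na(b) && a != b) {
        stop("asymmetric mon-mon record: (", r, ", ", s, ") = '", a,
             "' but (", s, ", ", r, ") = '", b, "'")
      }
    }
  }
  invisible(tab)
}

#' Write a cross table to CSV/TSV
#'
#' Emits ASCII `-` for incompatible and empty cells for missing, with the row
#' label in the first column, so that [read_cross_table()] round-trips.
#'
#' @param tab A [cross_table()].
#' @param file Output path.
#' @param sep Field separator.
#' @export
write_cross_table <- function(tab, file, sep = ",") {
  stopifnot(inherits(tab, "cross_table"))
  ent <- tab$entries
  ent[is.na(ent)] <- ""
  df <- data.frame(strain = rownames(ent), ent, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Predict a crossing matrix from known genotypes
#'
#' Forward model for compatibility tables: every cell is computed from the
#' tetrapolar rule ([compatible()] for monokaryon rows, [dimon_compatible()]
#' for dikaryon rows). Deterministic; the experimental tables of a study are
#' reproduced exactly when the genotypes are right.
#'
#' @param rows Named list of `mating_genotype`/`dikaryon` objects (or genotype
#'   strings) for the row strains.
#' @param cols Named list of `mating_genotype` objects or genotype strings for
#'   the column testers. Defaults to `rows` (square self-crossing table).
#' @return A [cross_table()].
#' @examples
#' panel <- spore_types(dikaryon("A1B1", "A2B2"))
#' predict_cross_table(panel)
#' @export
predict_cross_table <- function(rows, cols = rows) {
  rows <- lapply(rows, function(x) if (is_dikaryon(x)) x else as_genotype(x))
  cols <- lapply(cols, as_genotype)
  if (is.null(names(rows)) || is.null(names(cols))) {
    stop("'rows' and 'cols' must be named lists (strain identifiers)")
  }
  ent <- matrix(NA_character_, length(rows), length(cols),
                dimnames = list(names(rows), names(cols)))
  kind <- ifelse(vapply(rows, is_dikaryon, logical(1)), "dikaryon", "monokaryon")
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      ok <- if (kind[i] == "dikaryon") dimon_compatible(rows[[i]], cols[[j]])
            else compatible(rows[[i]], cols[[j]])
      ent[i, j] <- if (ok) PLUS else MINUS
    }
  }
  cross_table(ent, row_kind = kind)
}

#' Count "+" cells of a cross table (optionally a sub-block)
#'
#' @param tab A [cross_table()].
#' @param rows,cols Optional label subsets.
#' @return Integer count of PLUS cells among non-missing entries.
#' @export
count_plus <- function(tab, rows = NULL, cols = NULL) {
  ent <- tab$entries
  if (!is.null(rows)) ent <- ent[rows, , drop = FALSE]
  if (!is.null(cols)) ent <- ent[, cols, drop = FALSE]
  sum(ent == PLUS, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Tester panel specifications
# ---------------------------------------------------------------------------

#' Tester-panel specification
#'
#' Describes the four monobasidiospore testers derived from one dikaryotic
#' isolate, in the conventional order m1 = AxBx, m2 = AxBy, m3 = AyBx,
#' m4 = AyBy. Even without genotype labels the panel structure constrains
#' allele classes: m1/m2 share the matA class, m3/m4 share the other; m1/m3
#' share the matB class, m2/m4 the other; and the two classes at each locus
#' differ.
#'
#' @param isolate Isolate identifier (e.g. `"M-8"`).
#' @param testers Character vector of 4 tester identifiers in m1..m4 order.
#' @param genotypes Optional character vector of 4 genotype strings; when
#'   given they must form the spore set of a single dikaryon in m1..m4 order.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(isolate, testers, genotypes = NULL) {
  stopifnot(is.character(isolate), length(isolate) == 1L,
            is.character(testers), length(testers) == 4L,
            !anyDuplicated(testers))
  if (!is.null(genotypes)) {
    stopifnot(length(genotypes) == 4L)
    g <- lapply(genotypes, as_genotype)
    if (g[[1L]]$a == g[[4L]]$a || g[[1L]]$b == g[[4L]]$b) {
      stop("panel '", isolate, "' genotypes ",
           paste(vapply(g, format, character(1)), collapse = ", "),
           " are not the m1..m4 spore types of one dikaryon")
    }
    expected <- c(paste0(g[[1L]]$a, g[[1L]]$b), paste0(g[[1L]]$a, g[[4L]]$b),
                  paste0(g[[4L]]$a, g[[1L]]$b), paste0(g[[4L]]$a, g[[4L]]$b))
    got <- unname(vapply(g, format, character(1)))
    if (!identical(got, expected)) {
      stop("panel '", isolate, "' genotypes ", paste(got, collapse = ", "),
           " are not the m1..m4 spore types of one dikaryon")
    }
    genotypes <- got
  }
  structure(list(isolate = isolate, testers = testers, genotypes = genotypes),
            class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("<panel_spec> ", x$isolate, ": ", paste(x$testers, collapse = ", "), sep = "")
  if (!is.null(x$genotypes)) cat(" [", paste(x$genotypes, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read tester-panel specifications from YAML
#'
#' The file is a list of panels, each with fields `isolate`, `testers`
#' (4 ids) and optional `genotypes`.
#'
#' @param file Path to a YAML file.
#' @return List of [panel_spec()] objects, named by isolate.
#' @export
read_panels <- function(file) {
  raw <- yaml::read_yaml(file)
  out <- lapply(raw, function(p) {
    panel_spec(p$isolate, as.character(p$testers),
               if (!is.null(p$genotypes)) as.character(p$genotypes))
  })
  names(out) <- vapply(out, function(p) p$isolate, character(1))
  out
}
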