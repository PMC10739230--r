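#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Allele labels
# ---------------------------------------------------------------------------

#' Create an allele label
#'
#' An allele label identifies one allele class at one of the two mating-type
#' loci of a tetrapolar fungus: `matA` (homeodomain transcription-factor
#' cassette) or `matB` (pheromone/receptor locus). Labels are identity-only
#' tokens such as `"A3"` or `"B12"`: equality of labels is the only semantics;
#' the numeric part orders labels for display (natural sort, so `"A2"` sorts
#' before `"A10"`).
#'
#' @param locus `"A"` or `"B"`.
#' @param id Character scalar naming the allele, e.g. `"A3"`. Must start with
#'   the locus letter.
#' @return A character scalar of class `allele_label` with attribute `locus`.
#' @examples
#' allele_label("A", "A3")
#' @export
allele_label <- function(locus, id) {
  locus <- match.arg(locus, c("A", "B"))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (substr(id, 1L, 1L) != locus) {
    stop("allele id '", id, "' does not start with its locus letter '", locus, "'")
  }
  structure(id, locus = locus, class = "allele_label")
}

#' Natural sort of allele labels
#'
#' Orders labels like `A2 < A10` by splitting each label into its alphabetic
#' prefix and numeric suffix. Labels without a numeric suffix sort after
#' numbered ones, alphabetically.
#'
#' @param x Character vector of allele ids (e.g. `c("A10", "A2")`).
#' @return `x` sorted in natural order.
#' @export
allele_sort <- function(x) {
  x <- as.character(x)
  prefix <- sub("([0-9]+)$", "", x)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", x)))
  num[!grepl("[0-9]+$", x)] <- Inf
  x[order(prefix, num, x)]
}

# ---------------------------------------------------------------------------
# Mating genotypes
# ---------------------------------------------------------------------------

#' Create a haploid mating genotype
#'
#' One haploid nucleus carries one allele at each mating-type locus; the pair
#' is written `AxBy` (e.g. `A3B4`). Two monokaryons mate successfully only if
#' they are heteroallelic at *both* loci.
#'
#' @param a matA allele id (character, e.g. `"A3"`).
#' @param b matB allele id (character, e.g. `"B4"`).
#' @return An object of class `mating_genotype`.
#' @seealso [parse_genotype()], [compatible()]
#' @examples
#' mating_genotype("A3", "B3")
#' @export
mating_genotype <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, nzchar(a),
            is.character(b), length(b) == 1L, nzchar(b))
  if (substr(a, 1L, 1L) != "A") stop("matA allele id must start with 'A', got '", a, "'")
  if (substr(b, 1L, 1L) != "B") stop("matB allele id must start with 'B', got '", b, "'")
  structure(list(a = a, b = b), class = "mating_genotype")
}

#' Parse a genotype string such as "A3B4"
#'
#' The inverse of [format.mating_genotype()]: splits the standard `A<i>B<j>`
#' genotype syntax used in crossing-table headers.
#'
#' @param x Character vector of genotype strings.
#' @return A `mating_genotype` for length-1 input, otherwise a list of them.
#' @examples
#' parse_genotype("A3B4")
#' @export
parse_genotype <- function(x) {
  stopifnot(is.character(x), all(nzchar(x)))
  parse1 <- function(s) {
    m <- regmatches(s, regexec("^(A.+?)(B.+)$", s))[[1]]
    if (length(m) != 3L) stop("cannot parse genotype string '", s, "' (expected 'A<i>B<j>')")
    mating_genotype(m[2L], m[3L])
  }
  if (length(x) == 1L) parse1(x) else lapply(x, parse1)
}

#' @export
format.mating_genotype <- function(x, ...) paste0(x$a, x$b)

#' @export
print.mating_genotype <- function(x, ...) {
  cat("<mating genotype>", format(x), "\n")
  invisible(x)
}

#' @export
`==.mating_genotype` <- function(e1, e2) {
  inherits(e1, "mating_genotype") && inherits(e2, "mating_genotype") &&
    e1$a == e2$a && e1$b == e2$b
}

as_genotype <- function(x) {
  if (inherits(x, "mating_genotype")) x else parse_genotype(as.character(x))
}

# ---------------------------------------------------------------------------
# Dikaryons
# ---------------------------------------------------------------------------

#' Create a dikaryon from two compatible haploid nuclei
#'
#' A dikaryon carries two nuclei that are heteroallelic at both mating-type
#' loci; that is the definition of a sexually compatible pair, so the
#' constructor enforces it. A dikaryon is an unordered pair: the two nuclei
#' are stored in canonical (sorted) order so equality is swap-invariant.
#'
#' @param n1,n2 `mating_genotype` objects or genotype strings (`"A1B1"`).
#' @return An object of class `dikaryon` with elements `n1` and `n2`.
#' @examples
#' dikaryon("A1B1", "A2B2")
#' @export
dikaryon <- function(n1, n2) {
  n1 <- as_genotype(n1); n2 <- as_genotype(n2)
  if (n1$a == n2$a || n1$b == n2$b) {
    stop("invalid dikaryon: nuclei ", format(n1), " and ", format(n2),
         " are not heteroallelic at both mating-type loci")
  }
  if (format(n2) < format(n1)) { tmp <- n1; n1 <- n2; n2 <- tmp }
  structure(list(n1 = n1, n2 = n2), class = "dikaryon")
}

#' @export
format.dikaryon <- function(x, ...) paste0(format(x$n1), "+", format(x$n2))

#' @export
print.dikaryon <- function(x, ...) {
  cat("<dikaryon>", format(x), "\n")
  invisible(x)
}

is_dikaryon <- function(x) inherits(x, "dikaryon")

# ---------------------------------------------------------------------------
# Compatibility predicates
# ---------------------------------------------------------------------------

#' Mon-mon sexual compatibility
#'
#' Two monokaryons are sexually compatible — their paired mycelia dikaryotize,
#' scored in practice by clamp connections at the septa — exactly when they
#' carry different alleles at matA *and* different alleles at matB. The
#' predicate is symmetric and irreflexive: a self-cross shares both alleles
#' and is always incompatible (the "-" diagonal of a crossing matrix).
#'
#' @param m1,m2 `mating_genotype` objects or genotype strings.
#' @return `TRUE` if the cross is compatible, else `FALSE`.
#' @examples
#' compatible("A3B3", "A4B4") # TRUE
#' compatible("A3B3", "A3B4") # FALSE, shared matA allele
#' @export
compatible <- function(m1, m2) {
  m1 <- as_genotype(m1); m2 <- as_genotype(m2)
  m1$a != m2$a && m1$b != m2$b
}

#' Di-mon (Buller) compatibility
#'
#' In a dikaryon-by-monokaryon cross the monokaryon is dikaryotized (the
#' Buller phenomenon) when it is compatible with at least one of the
#' dikaryon's two nuclei. The result does not depend on nucleus order.
#'
#' @param d A `dikaryon`.
#' @param m A `mating_genotype` or genotype string.
#' @return `TRUE` if the monokaryon is dikaryotized, else `FALSE`.
#' @examples
#' dimon_compatible(dikaryon("A1B1", "A2B2"), "A3B3") # TRUE
#' @export
dimon_compatible <- function(d, m) {
  if (!is_dikaryon(d)) stop("'d' must be a dikaryon (heteroallelic nucleus pair)")
  m <- as_genotype(m)
  compatible(d$n1, m) || compatible(d$n2, m)
}

#' Meiotic spore mating types of a dikaryon
#'
#' With matA and matB unlinked, meiosis of a dikaryon `AxBx + AyBy` segregates
#' the two loci freely, so its basidiospores fall into exactly four mating
#' types: the two parental (`AxBx`, `AyBy`) and the two recombinant
#' (`AxBy`, `AyBx`) genotypes. These four are the tester panel recovered from
#' one fruiting isolate.
#'
#' @param d A `dikaryon`.
#' @return A list of the 4 `mating_genotype`s, named by genotype string, in
#'   the conventional panel order AxBx, AxBy, AyBx, AyBy (x = the
#'   naturally-first allele of the first nucleus).
#' @examples
#' names(spore_types(dikaryon("A3B3", "A4B4")))
#' @export
spore_types <- function(d) {
  if (!is_dikaryon(d)) stop("'d' must be a dikaryon (heteroallelic nucleus pair)")
  out <- list(
    mating_genotype(d$n1$a, d$n1$b),
    mating_genotype(d$n1$a, d$n2$b),
    mating_genotype(d$n2$a, d$n1$b),
    mating_genotype(d$n2$a, d$n2$b)
  )
  names(out) <- vapply(out, format, character(1))
  out
}
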