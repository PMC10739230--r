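# Bundled crossing-table fixtures for Pleurotus ostreatus natural isolates
# from the Moscow-region collection study: mon-mon crosses of five natural
# tester panels (M-8, M-9, M-13, M-14, M-17) against the reference panel
# M-38, the mutual mon-mon crosses among the natural panels, di-mon crosses
# of twelve further dikaryotic isolates against the M-38 panel, and the
# stated (not tabulated) full compatibility of M-14/M-17 with every other
# natural panel.

#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or vector of file names).
#' @export
tetrapolar_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "tetrapolar", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file '", file, "'")
  path
}

#' Load the bundled oyster-mushroom crossing study
#'
#' @return A list with elements `monmon_reference` (natural testers x M-38
#'   panel, all compatible), `dimon_reference` (12 dikaryotic isolates x
#'   M-38 panel), `monmon_mutual` (mutual crosses among the M-8/M-9/M-13
#'   panels, including the 50%-compatible M-8 x M-13 block), `monmon_stated`
#'   (the M-14/M-17 all-compatible records), and `panels` (six
#'   [panel_spec()]s with published genotype labels).
#' @export
load_crossing_study <- function() {
  list(
    monmon_reference = read_cross_table(tetrapolar_extdata("table1_monmon.csv")),
    dimon_reference = read_cross_table(tetrapolar_extdata("table1_dimon.csv"),
                                       row_kind = "dikaryon"),
    monmon_mutual = read_cross_table(tetrapolar_extdata("table2.csv")),
    monmon_stated = read_cross_table(tetrapolar_extdata("table2_stated.csv")),
    panels = read_panels(tetrapolar_extdata("panels.yaml"))
  )
}

#' Infer minimal allele counts for the bundled crossing study
#'
#' Runs the full pipeline — constraint construction, unit propagation, exact
#' minimisation — on the bundled mon-mon crossing records. With
#' `include_reference = FALSE` (default) only the 20 testers derived from
#' the five natural isolates enter, and the minimal consistent solution has
#' 10 matA and 8 matB classes (the M-8 and M-13 panels are forced by
#' propagation to share their two matB classes). Including the M-38
#' reference panel adds two further classes at each locus.
#'
#' @param include_reference Also include the M-38 panel and its crosses.
#' @return An [minimal_assignment()] result, with the `propagated_constraints`
#'   attached as attribute `"propagated"`.
#' @export
infer_study_alleles <- function(include_reference = FALSE) {
  study <- load_crossing_study()
  tables <- list(study$monmon_mutual, study$monmon_stated)
  panels <- study$panels[c("M-8", "M-9", "M-13", "M-14", "M-17")]
  if (include_reference) {
    tables <- c(tables, list(study$monmon_reference))
    panels <- c(panels, study$panels["M-38"])
  }
  cs <- build_constraints(tables, panels = panels)
  pc <- propagate(cs)
  res <- minimal_assignment(pc)
  attr(res, "propagated") <- pc
  res
}
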