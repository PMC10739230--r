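# Shared generators and independent oracles for the test suite.

# Random small inference instance: k monokaryons with genotypes drawn from
# bounded allele pools, full pairwise crossing table, optionally masked.
# Returns the table, the truth genotypes and (optionally) no panel structure,
# so instances stress the solver beyond the panel-derived case.
random_instance <- function(seed, k = NULL, pool_A = NULL, pool_B = NULL,
                            mask = 0) {
  set.seed(seed)
  if (is.null(k)) k <- sample(4:10, 1)
  if (is.null(pool_A)) pool_A <- sample(2:4, 1)
  if (is.null(pool_B)) pool_B <- sample(2:4, 1)
  g <- lapply(seq_len(k), function(i) {
    mating_genotype(paste0("A", sample.int(pool_A, 1)),
                    paste0("B", sample.int(pool_B, 1)))
  })
  names(g) <- paste0("m", seq_len(k))
  tab <- predict_cross_table(g)
  if (mask > 0) {
    ent <- tab$entries
    off <- which(row(ent) != col(ent))
    drop <- off[stats::runif(length(off)) < mask]
    ent[drop] <- NA_character_
    tab <- cross_table(ent)
  }
  list(table = tab, genotypes = g,
       truth = c(n_A = length(unique(vapply(g, function(x) x$a, character(1)))),
                 n_B = length(unique(vapply(g, function(x) x$b, character(1))))))
}

# Random panel-structured instance (testers derived from dikaryons), for
# recovery checks; always includes panel specs.
random_panel_instance <- function(seed, n_isolates = 2, pool_A = 3, pool_B = 3) {
  cfg <- population_config(n_A_pool = pool_A, n_B_pool = pool_B,
                           n_isolates = n_isolates, seed = seed)
  simulate_population(cfg)
}

# Regex-based motif oracle, independent of motif_scan's position-by-position
# matcher: translates the pattern to a lookahead regex and uses gregexpr.
motif_oracle <- function(seq, pattern) {
  rx <- gsub("X", ".", pattern, fixed = TRUE)
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(seq), perl = TRUE)[[1]]
  starts <- as.integer(m)
  starts[starts > 0]
}

random_protein <- function(len, alphabet = c("A", "R", "N", "W", "F", "Q")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
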