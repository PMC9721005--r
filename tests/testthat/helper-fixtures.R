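# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

# full 10-family genome with per-family random genes
full_genome <- function(genome_id, seed, gene_length = 300,
                        families = mg_families()) {
  genome_mg_set(genome_id, withr::with_seed(seed, vapply(
    families, function(f) paste(sample(c("A", "C", "G", "T"), gene_length,
                                       replace = TRUE), collapse = ""),
    character(1))))
}

# mutate every family of a genome to an exact identity (disjoint per-family
# RNG draws from one seed)
mutated_genome <- function(g, genome_id, identity, seed) {
  withr::with_seed(seed, {
    genome_mg_set(genome_id, vapply(g$members, function(s) {
      mutate_to_identity(s, identity)
    }, character(1)))
  })
}

# a small database of well-separated species plus simple lineages
tiny_db <- function(n_species = 3, genomes_per_species = 1, seed = 42,
                    gene_length = 1000) {
  fx <- make_species_clusters(n_species, genomes_per_species,
                              within_id = 0.99, between_id = 0.85,
                              seed = seed, gene_length = gene_length)
  lineages <- lapply(fx$truth, function(sp) {
    tax_lineage("Bacteria", "Phylum1", "Class1", "Order1", "Family1",
                paste0("Genus_", sp), paste0("Species_", sp))
  })
  db <- build_db(fx$genomes, lineages = lineages)
  list(db = db, fixture = fx, lineages = lineages)
}

# independent global-alignment identity oracle (Biostrings, no fast path)
oracle_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 20, gapExtension = 8)
  Biostrings::pid(al, type = "PID2") / 100
}

# all partitions of items 1..n as label vectors (Bell-number enumeration)
all_partitions <- function(n) {
  if (n == 1) return(list(c(g1 = 1L)))
  out <- list()
  rec <- function(labels, next_label) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- setNames(labels, paste0("i", seq_len(n)))
      return(invisible())
    }
    for (l in seq_len(next_label)) {
      rec(c(labels, l), max(next_label, l + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# brute-force V-measure from explicit contingency-table entropies
oracle_v_measure <- function(truth, pred, beta = 1) {
  pred <- pred[names(truth)]
  n <- length(truth)
  ent <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log(p))
  }
  h_t <- ent(table(truth)); h_p <- ent(table(pred))
  # conditional entropies by explicit enumeration over cluster pairs
  h_t_given_p <- 0; h_p_given_t <- 0
  for (cp in unique(pred)) {
    sub <- truth[pred == cp]
    q <- table(sub) / n
    h_t_given_p <- h_t_given_p - sum(q[q > 0] * log(q[q > 0] / (length(sub) / n)))
  }
  for (ct in unique(truth)) {
    sub <- pred[truth == ct]
    q <- table(sub) / n
    h_p_given_t <- h_p_given_t - sum(q[q > 0] * log(q[q > 0] / (length(sub) / n)))
  }
  h <- if (h_t == 0) 1 else 1 - h_t_given_p / h_t
  cmp <- if (h_p == 0) 1 else 1 - h_p_given_t / h_p
  if (h + cmp == 0) 0 else (1 + beta) * h * cmp / (beta * h + cmp)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  q
}

relab <- function(sample_id, ..., rank = "species") {
  relabund_profile(sample_id, c(...), rank = rank)
}

# aggregate a species-level named abundance vector to every rank via the
# given lineages (independent of aggregate_to_rank, for metric oracles)
rank_profiles <- function(species_ab, lineages) {
  lapply(setNames(tax_ranks(), tax_ranks()), function(r) {
    agg <- numeric(0)
    for (t in names(species_ab)) {
      nm <- lineages[[t]][[r]]
      key <- if (is.na(nm)) paste0("unannotated@", r) else nm
      agg[key] <- sum(agg[key], species_ab[[t]], na.rm = TRUE)
    }
    relabund_profile("s", agg, rank = r)
  })
}
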