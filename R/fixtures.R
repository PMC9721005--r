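## Synthetic-data generators.  All randomness flows from an explicit seed;
## every generator is deterministic given (parameters, seed).  The mutation
## model is substitution-only so that sequence identity can be targeted
## exactly; indels are out of scope (see the methods vignette).

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(length) {
  paste(sample(.BASES, length, replace = TRUE), collapse = "")
}

#' Generate a random marker gene family sequence
#'
#' @param length Sequence length in nt (>= 100).
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
#' @examples
#' nchar(make_marker_family(1000, seed = 1))
make_marker_family <- function(length, seed) {
  if (length < 100) stop("marker genes must be >= 100 nt")
  with_seed_opt(seed, .random_dna(length))
}

## substitute the bases at `positions` with a different base each
.substitute_at <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  old <- chars[positions]
  new <- vapply(old, function(b) sample(setdiff(.BASES, b), 1), character(1),
                USE.NAMES = FALSE)
  chars[positions] <- new
  paste(chars, collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Applies `round((1 - target) * length)` substitutions at positions sampled
#' without replacement, each to a different base, so the realized
#' global-alignment identity equals the target within half a percentage
#' point (exactly, up to rounding, since the mutation model is
#' substitution-only).
#'
#' @param seq DNA string.
#' @param target_identity Target identity in \[0.5, 1\].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Mutated DNA string of the same length.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = NULL) {
  if (target_identity < 0.5 || target_identity > 1) {
    stop("target_identity must lie in [0.5, 1]")
  }
  n <- nchar(seq)
  n_mut <- round((1 - target_identity) * n)
  if (n_mut == 0) return(seq)
  with_seed_opt(seed, .substitute_at(seq, sample.int(n, n_mut)))
}

## mutate at a per-base rate with binomially drawn mutation count
.mutate_at_rate <- function(seq, rate) {
  n <- nchar(seq)
  n_mut <- rbinom(1, n, rate)
  if (n_mut == 0) return(seq)
  .substitute_at(seq, sample.int(n, n_mut))
}

#' Generate planted species clusters of marker gene sets
#'
#' Builds `n_species` founder MG sets whose pairwise identity equals
#' `between_id` exactly, then adds conspecific genomes at identity
#' `within_id` to their founder.  Mutation positions are allocated from
#' disjoint pools, so by construction every within-species pairwise identity
#' exceeds every between-species identity, and clustering at any cutoff in
#' `(between_id, within_id]` recovers the planted labels.
#'
#' @param n_species Number of species.
#' @param genomes_per_species Genomes per species including the founder.
#' @param within_id Founder-to-member identity; must satisfy
#'   `between_id < cutoff <= within_id`.
#' @param between_id Founder-to-founder identity across species.
#' @param seed Integer seed.
#' @param cutoff Species-level cutoff the fixture straddles (default 0.965).
#' @param gene_length Marker gene length in nt (default 1000).
#' @param families Family labels to generate (default all 10).
#' @return List with `genomes` (list of [genome_mg_set()]) and `truth`
#'   (named character vector genome id -> species label).
#' @export
make_species_clusters <- function(n_species, genomes_per_species,
                                  within_id, between_id, seed,
                                  cutoff = 0.965, gene_length = 1000,
                                  families = mg_families()) {
  if (!(between_id < cutoff && cutoff <= within_id)) {
    stop("need between_id < cutoff <= within_id (got ", between_id, " / ",
         cutoff, " / ", within_id, ")")
  }
  n_sp_mut <- round((1 - between_id) / 2 * gene_length)
  n_wi_mut <- round((1 - within_id) * gene_length)
  budget <- n_species * n_sp_mut +
    n_species * (genomes_per_species - 1) * n_wi_mut
  if (budget > gene_length) {
    stop("identity targets too low for disjoint mutation placement; ",
         "increase gene_length")
  }
  with_seed_opt(seed, {
    base <- lapply(families, function(f) .random_dna(gene_length))
    names(base) <- families
    pool <- lapply(families, function(f) sample.int(gene_length))
    names(pool) <- families
    used <- setNames(rep(0L, length(families)), families)
    take <- function(f, n) {
      idx <- pool[[f]][(used[[f]] + 1):(used[[f]] + n)]
      used[[f]] <<- used[[f]] + n
      idx
    }
    genomes <- list()
    truth <- character(0)
    for (i in seq_len(n_species)) {
      sp <- sprintf("s%02d", i)
      founder <- vapply(families, function(f) {
        if (n_sp_mut == 0) base[[f]] else .substitute_at(base[[f]], take(f, n_sp_mut))
      }, character(1))
      for (j in seq_len(genomes_per_species)) {
        gid <- sprintf("%s_g%02d", sp, j)
        members <- if (j == 1) founder else vapply(families, function(f) {
          if (n_wi_mut == 0) founder[[f]] else .substitute_at(founder[[f]], take(f, n_wi_mut))
        }, character(1))
        genomes[[gid]] <- genome_mg_set(gid, members)
        truth[gid] <- sp
      }
    }
    list(genomes = genomes, truth = truth)
  })
}

#' Generate genomes carrying a conserved 16S-like locus
#'
#' Emulates the pattern seen in clades such as the Pelagibacterales, whose
#' conserved ribosomal locus saturates in identity while whole-genome
#' similarity keeps falling: each genome diverges from a common ancestor at
#' its own genome-wide substitution rate, but the embedded locus is mutated
#' at `1/conservation` of that rate, compressing locus identity toward 1.
#' Marker genes evolve at the genome-wide rate and therefore track
#' whole-genome distance.  Mutation counts are drawn binomially, so realized
#' distances carry realistic sampling noise.
#'
#' @param n_genomes Number of genomes.
#' @param genome_divergence_range Length-2 numeric within \[0, 0.3\]:
#'   per-genome divergence from the ancestor is spaced evenly across this
#'   range.
#' @param seed Integer seed.
#' @param genome_length Backbone length in nt (default 30000).
#' @param locus_length Conserved locus length (default 1500).
#' @param gene_length Marker gene length (default 1000).
#' @param conservation Fold reduction of the locus mutation rate (default 5).
#' @return List with `genomes` (named character: full genome sequences,
#'   locus embedded mid-backbone), `loci`, `mg_sets` (list of
#'   [genome_mg_set()]), and `divergence` (named numeric).
#' @export
make_16s_like_genomes <- function(n_genomes, genome_divergence_range = c(0, 0.3),
                                  seed = 1, genome_length = 30000,
                                  locus_length = 1500, gene_length = 1000,
                                  conservation = 5) {
  r <- genome_divergence_range
  if (length(r) != 2 || any(r < 0) || any(r > 0.3) || r[1] > r[2]) {
    stop("genome_divergence_range must be within [0, 0.3]")
  }
  d <- if (n_genomes == 1) r[1] else seq(r[1], r[2], length.out = n_genomes)
  with_seed_opt(seed, {
    backbone <- .random_dna(genome_length)
    locus0 <- .random_dna(locus_length)
    genes0 <- vapply(mg_families(), function(f) .random_dna(gene_length),
                     character(1))
    half <- genome_length %/% 2
    left0 <- substr(backbone, 1, half)
    right0 <- substr(backbone, half + 1, genome_length)
    ids <- sprintf("g%03d", seq_len(n_genomes))
    genomes <- character(0); loci <- character(0); mg_sets <- list()
    for (i in seq_len(n_genomes)) {
      locus_i <- .mutate_at_rate(locus0, d[i] / conservation)
      left_i <- .mutate_at_rate(left0, d[i])
      right_i <- .mutate_at_rate(right0, d[i])
      genomes[ids[i]] <- paste0(left_i, locus_i, right_i)
      loci[ids[i]] <- locus_i
      mg_sets[[ids[i]]] <- genome_mg_set(
        ids[i], vapply(genes0, function(g) .mutate_at_rate(g, d[i]),
                       character(1))
      )
    }
    list(genomes = genomes, loci = loci, mg_sets = mg_sets,
         divergence = setNames(d, ids))
  })
}

#' Simulate metagenomic inserts from a database community
#'
#' Inserts are drawn from the member marker gene sequences of the specified
#' mOTUs with probability proportional to abundance x gene length, uniform
#' start positions, per-base substitution errors, and random strand.
#'
#' @param db An [mg_database()].
#' @param spec A [community_spec()].
#' @return List with `reads` (data.frame: insert_id, seq) and `truth`
#'   (the ground-truth [relabund_profile()], unassigned fraction 0).
#' @export
simulate_inserts <- function(db, spec) {
  stopifnot(inherits(db, "mg_database"), inherits(spec, "community_spec"))
  missing <- setdiff(spec$species, db_motu_ids(db, include_unassigned = TRUE))
  if (length(missing) > 0) {
    stop("species missing from database: ", paste(missing, collapse = ", "))
  }
  ## flatten the source pool: one row per (motu, family, member sequence)
  pool <- do.call(rbind, lapply(spec$species, function(m) {
    e <- db$entries[[m]]
    if (length(e$sequences) == 0) stop("species ", m, " has no marker genes")
    do.call(rbind, lapply(names(e$sequences), function(f) {
      data.frame(motu_id = m, family = f, seq = unname(e$sequences[[f]]),
                 len = nchar(e$sequences[[f]]), stringsAsFactors = FALSE)
    }))
  }))
  if (spec$read_length > min(pool$len)) {
    stop("read_length exceeds the shortest marker gene (", min(pool$len), " nt)")
  }
  truth_ab <- c(spec$abundances, setNames(0, UNASSIGNED_ID))
  truth <- relabund_profile(paste0("truth_", spec$seed), truth_ab, rank = "motu")
  if (spec$n_inserts == 0) {
    return(list(reads = data.frame(insert_id = character(0), seq = character(0),
                                   stringsAsFactors = FALSE),
                truth = truth))
  }
  ## per-sequence weight: species abundance split over its per-family copies,
  ## scaled by gene length
  w <- spec$abundances[pool$motu_id] * pool$len
  copies <- stats::ave(pool$len, pool$motu_id, pool$family, FUN = length)
  w <- w / copies
  with_seed_opt(spec$seed, {
    src <- sample.int(nrow(pool), spec$n_inserts, replace = TRUE, prob = w)
    start <- vapply(pool$len[src] - spec$read_length + 1L,
                    function(m) sample.int(m, 1), integer(1))
    reads <- substr(pool$seq[src], start, start + spec$read_length - 1L)
    if (spec$error_rate > 0) {
      nerr <- rbinom(spec$n_inserts, spec$read_length, spec$error_rate)
      mut <- which(nerr > 0)
      for (i in mut) {
        reads[i] <- .substitute_at(reads[i], sample.int(spec$read_length, nerr[i]))
      }
    }
    flip <- runif(spec$n_inserts) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    list(reads = data.frame(
           insert_id = sprintf("insert_%06d", seq_len(spec$n_inserts)),
           seq = reads, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a two-group cohort with planted fold changes
#'
#' Baseline taxon weights are log-normal; per-sample abundances multiply the
#' baseline by log-normal noise; group-B means are multiplied by the planted
#' fold changes; every sample is then renormalized to sum to 1 (so planted
#' effects are slightly compressed by compositionality, as in real data).
#' The truth is recorded pre-normalization.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param n_taxa Number of taxa.
#' @param planted Named numeric vector taxon -> fold change (> 0) applied to
#'   group B.  Taxon names must be among `t001..t<n_taxa>`.
#' @param seed Integer seed.
#' @param noise_sdlog Log-normal noise sd on the log scale (default 0.5).
#' @param planted_baseline Pre-normalization baseline share given to planted
#'   taxa (default 1e-3); differential taxa in host-associated communities
#'   are typically low-abundance, and a low baseline keeps the planted fold
#'   change nearly free of compositional squeeze.
#' @return List with `profiles` (list of [relabund_profile()]), `design`
#'   (data.frame: sample_id, group in A/B), and `truth` (the planted map).
#' @export
make_two_group_cohort <- function(n_per_group, n_taxa, planted = numeric(0),
                                  seed = 1, noise_sdlog = 0.5,
                                  planted_baseline = 1e-3) {
  if (n_per_group < 3) stop("need at least 3 samples per group")
  if (length(planted) > 0) {
    if (is.null(names(planted))) stop("planted must be named by taxon")
    if (any(planted <= 0)) stop("planted fold changes must be > 0")
  }
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  bad <- setdiff(names(planted), taxa)
  if (length(bad) > 0) stop("planted taxa not in cohort: ", paste(bad, collapse = ", "))
  with_seed_opt(seed, {
    base <- rlnorm(n_taxa, meanlog = 0, sdlog = 1)
    base <- base / sum(base)
    names(base) <- taxa
    if (length(planted) > 0) {
      keep <- 1 - planted_baseline * length(planted)
      base[setdiff(taxa, names(planted))] <-
        base[setdiff(taxa, names(planted))] * keep /
        sum(base[setdiff(taxa, names(planted))])
      base[names(planted)] <- planted_baseline
    }
    fc <- setNames(rep(1, n_taxa), taxa)
    fc[names(planted)] <- planted
    sample_ids <- c(sprintf("A%02d", seq_len(n_per_group)),
                    sprintf("B%02d", seq_len(n_per_group)))
    groups <- rep(c("A", "B"), each = n_per_group)
    profiles <- lapply(seq_along(sample_ids), function(i) {
      mu <- if (groups[i] == "B") base * fc else base
      x <- mu * rlnorm(n_taxa, meanlog = -noise_sdlog^2 / 2, sdlog = noise_sdlog)
      relabund_profile(sample_ids[i], x / sum(x), rank = "species")
    })
    names(profiles) <- sample_ids
    list(profiles = profiles,
         design = data.frame(sample_id = sample_ids, group = groups,
                             stringsAsFactors = FALSE),
         truth = planted)
  })
}
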