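## Core domain types, kept as light S3 structures with strict validators.
## Sequences are plain upper-case character strings over {A,C,G,T,N};
## Biostrings objects are created only at I/O and alignment boundaries.

.DNA_CHARS <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || anyNA(seq)) stop(what, " must be a character string")
  ok <- grepl("^[ACGTN]+$", seq)
  if (!all(ok)) stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(seq)
}

#' Taxonomic ranks used throughout the package
#'
#' @return Character vector: domain, phylum, class, order, family, genus,
#'   species (highest to lowest).
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct a taxonomic lineage
#'
#' A lineage is a named character vector over the seven ranks returned by
#' [tax_ranks()], with `NA` for unknown names.  Once a rank is `NA`, all
#' lower ranks must be `NA` as well.
#'
#' @param ... Rank names in order (domain first), or a single character
#'   vector.  Shorter inputs are padded with `NA` at the lower ranks.
#' @return Named character vector of length 7 with class `tax_lineage`.
#' @export
#' @examples
#' tax_lineage("Bacteria", "Proteobacteria")
tax_lineage <- function(...) {
  x <- unlist(list(...), use.names = FALSE)
  if (is.null(x)) x <- character(0)
  x <- as.character(x)
  if (length(x) > 7) stop("a lineage has at most 7 ranks")
  x <- c(x, rep(NA_character_, 7 - length(x)))
  names(x) <- tax_ranks()
  na <- is.na(x) | x == "" | x == "NA"
  x[na] <- NA_character_
  if (any(na)) {
    first_na <- which(na)[1]
    if (any(!na[first_na:7])) {
      stop("invalid lineage: named rank below an NA rank")
    }
  }
  structure(x, class = "tax_lineage")
}

#' Construct a genome marker gene set
#'
#' The unit of database membership: a genome's marker genes keyed by family.
#' Single-copy contract: at most one sequence per family (duplicates must be
#' resolved upstream, see [read_mg_fasta()]).
#'
#' @param genome_id Genome identifier (non-empty string).
#' @param members Named character vector of DNA sequences; names are family
#'   labels from [mg_families()].  1--10 distinct families, each sequence
#'   at least 100 nt.
#' @return Object of class `genome_mg_set`.
#' @export
genome_mg_set <- function(genome_id, members) {
  if (!is.character(genome_id) || length(genome_id) != 1 || !nzchar(genome_id)) {
    stop("genome_id must be a non-empty string")
  }
  members <- unlist(members)
  fams <- names(members)
  if (is.null(fams) || any(!nzchar(fams))) stop("members must be named by family")
  .check_family(fams)
  if (anyDuplicated(fams)) stop("duplicate family in genome ", genome_id,
                                " (single-copy contract)")
  if (length(members) < 1) stop("a genome needs at least one marker gene")
  members <- toupper(members)
  .check_dna(members, paste0("marker gene of ", genome_id))
  if (any(nchar(members) < 100)) {
    stop("marker genes must be >= 100 nt (genome ", genome_id, ")")
  }
  structure(list(genome_id = genome_id, members = members),
            class = "genome_mg_set")
}

#' @export
print.genome_mg_set <- function(x, ...) {
  cat("<genome_mg_set>", x$genome_id, "-", length(x$members), "families:",
      paste(names(x$members), collapse = " "), "\n")
  invisible(x)
}

n_families <- function(g) length(g$members)

#' Construct a mOTU database entry
#'
#' @param motu_id Entry identifier.
#' @param category One of `ref`, `meta`, `ext`, `unassigned`.
#' @param genomes Character vector of member genome ids (empty for the
#'   unassigned entry).
#' @param sequences Named list, family -> named character vector of member
#'   sequences (names are sequence/genome ids).
#' @param taxonomy A [tax_lineage()].
#' @param consistency Named character vector over [tax_ranks()] with values
#'   in `agreeing`, `majority`, `not_agreeing`, `not_annotated`.
#' @return Object of class `motu_entry`.
#' @export
motu_entry <- function(motu_id, category, genomes = character(0),
                       sequences = list(), taxonomy = tax_lineage(),
                       consistency = NULL) {
  category <- match.arg(category, c("ref", "meta", "ext", "unassigned"))
  if (category == "unassigned") {
    if (length(genomes) > 0) stop("the unassigned entry has no genomes")
    if (!all(is.na(taxonomy))) stop("the unassigned entry has no taxonomy")
  } else if (length(genomes) < 1) {
    stop("non-unassigned entries need >= 1 genome")
  }
  if (length(sequences) > 0) .check_family(names(sequences))
  if (is.null(consistency)) {
    consistency <- setNames(rep("not_annotated", 7), tax_ranks())
  }
  stopifnot(all(consistency %in%
                  c("agreeing", "majority", "not_agreeing", "not_annotated")))
  structure(list(motu_id = motu_id, category = category,
                 genomes = unique(genomes), sequences = sequences,
                 taxonomy = taxonomy, consistency = consistency),
            class = "motu_entry")
}

UNASSIGNED_ID <- "unassigned"

#' Construct a marker gene database
#'
#' Holds mOTU entries (ref/meta/ext plus exactly one pooled `unassigned`
#' entry), the per-family identity cutoffs that define species-level units,
#' the mapping prefilter identity, and the genome admission threshold.
#'
#' @param entries List of [motu_entry()] objects.  An unassigned entry is
#'   created automatically if absent.
#' @param cutoffs Named numeric vector of per-family identity cutoffs in
#'   (0, 1]; defaults to the species-level value 0.965 for all ten families.
#' @param prefilter_id Identity prefilter used when mapping new marker genes
#'   against the database (default 0.80).
#' @param min_families Minimum number of distinct families a genome must
#'   carry to be admitted (default 6 of 10).
#' @param version Free-form database version string.
#' @return Object of class `mg_database`.
#' @export
mg_database <- function(entries = list(), cutoffs = default_cutoffs(),
                        prefilter_id = 0.80, min_families = 6L,
                        version = "1.0") {
  if (length(entries) > 0 && is.null(names(entries))) {
    names(entries) <- vapply(entries, function(e) e$motu_id, character(1))
  }
  stopifnot(all(vapply(entries, inherits, logical(1), "motu_entry")))
  ids <- names(entries)
  if (anyDuplicated(ids)) stop("duplicate motu_id in database")
  cats <- vapply(entries, function(e) e$category, character(1))
  if (sum(cats == "unassigned") > 1) stop("exactly one unassigned entry allowed")
  if (!any(cats == "unassigned")) {
    entries[[UNASSIGNED_ID]] <- motu_entry(UNASSIGNED_ID, "unassigned")
  }
  .check_family(names(cutoffs))
  if (length(cutoffs) != 10) stop("cutoffs must cover all 10 families")
  if (any(cutoffs <= 0 | cutoffs > 1)) stop("cutoffs must lie in (0, 1]")
  stopifnot(prefilter_id > 0, prefilter_id <= 1, min_families >= 1)
  structure(list(entries = entries, cutoffs = cutoffs,
                 prefilter_id = prefilter_id,
                 min_families = as.integer(min_families), version = version),
            class = "mg_database")
}

#' Default per-family identity cutoffs
#'
#' A uniform species-level cutoff of 96.5% marker gene identity for all ten
#' families.  Per-family values can be loaded from a table at database build
#' time ([build_db()], `cutoffs.tsv` in the on-disk layout).
#'
#' @param value Cutoff applied to every family (default 0.965).
#' @return Named numeric vector over [mg_families()].
#' @export
default_cutoffs <- function(value = 0.965) {
  setNames(rep(value, 10), mg_families())
}

#' @export
print.mg_database <- function(x, ...) {
  cats <- vapply(x$entries, function(e) e$category, character(1))
  cat("<mg_database> version", x$version, "-", length(x$entries), "entries (",
      sum(cats == "ref"), "ref,", sum(cats == "meta"), "meta,",
      sum(cats == "ext"), "ext + unassigned )\n")
  cat("  cutoffs:", paste0(range(x$cutoffs) * 100, "%", collapse = "-"),
      "| prefilter:", x$prefilter_id, "| min families:", x$min_families, "\n")
  invisible(x)
}

db_motu_ids <- function(db, include_unassigned = FALSE) {
  ids <- names(db$entries)
  if (!include_unassigned) {
    cats <- vapply(db$entries, function(e) e$category, character(1))
    ids <- ids[cats != "unassigned"]
  }
  ids
}

db_unassigned_id <- function(db) {
  cats <- vapply(db$entries, function(e) e$category, character(1))
  names(db$entries)[cats == "unassigned"][1]
}

#' Construct a per-sample count profile
#'
#' @param sample_id Sample identifier.
#' @param counts Named non-negative integer vector of insert counts per
#'   mOTU.  An `unassigned` key is always carried (added as 0 if missing).
#' @return Object of class `count_profile`.
#' @export
count_profile <- function(sample_id, counts) {
  counts <- unlist(counts)
  if (length(counts) > 0 && is.null(names(counts))) stop("counts must be named")
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (!UNASSIGNED_ID %in% names(counts)) counts[UNASSIGNED_ID] <- 0L
  structure(list(sample_id = sample_id, counts = counts,
                 total_inserts = sum(counts)),
            class = "count_profile")
}

#' Construct a per-sample relative abundance profile
#'
#' Fractions are non-negative and sum to 1 within 1e-9, including the
#' `unassigned` fraction.
#'
#' @param sample_id Sample identifier.
#' @param abundances Named numeric vector of fractions.
#' @param rank Taxonomic rank of the taxa, or `"motu"` (default).
#' @return Object of class `relabund_profile`.
#' @export
relabund_profile <- function(sample_id, abundances, rank = "motu") {
  abundances <- unlist(abundances)
  if (is.null(names(abundances))) stop("abundances must be named")
  if (any(is.na(abundances)) || any(abundances < 0)) {
    stop("abundances must be non-negative")
  }
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must sum to 1 (got ", format(sum(abundances)), ")")
  }
  if (!rank %in% c("motu", tax_ranks())) stop("unknown rank: ", rank)
  structure(list(sample_id = sample_id, rank = rank, abundances = abundances),
            class = "relabund_profile")
}

#' Specify a synthetic community
#'
#' Ground-truth community description used by [simulate_inserts()].
#'
#' @param species Character vector of mOTU ids present in the community.
#' @param abundances Relative abundances summing to 1.
#' @param n_inserts Number of inserts to simulate.
#' @param read_length Read length in nt (default 150).
#' @param error_rate Per-base substitution probability (default 0.005,
#'   i.e. 0.5%).
#' @param seed Integer seed; all simulation randomness flows from it.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(species, abundances, n_inserts,
                           read_length = 150L, error_rate = 0.005, seed = 1L) {
  stopifnot(length(species) == length(abundances), n_inserts >= 0,
            read_length >= 20, error_rate >= 0, error_rate < 1)
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  structure(list(species = as.character(species),
                 abundances = setNames(as.numeric(abundances), species),
                 n_inserts = as.integer(n_inserts),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

## run code under a fixed seed without disturbing the caller's RNG;
## seed = NULL means "use the current RNG stream"
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
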