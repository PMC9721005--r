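## Database construction and extension.
##
## Pipeline (mirrors the published database build): genomes carrying at
## least 6 of the 10 marker gene families are admitted; admitted genomes are
## mapped against the existing database (identity prefilter 0.8, both
## strands) and assigned to the mOTU with the highest mean per-family
## best-hit identity, provided at least `min_assign_families` families each
## meet their family-specific cutoff; unassigned genomes are clustered de
## novo into new ext-mOTUs by greedy centroid clustering; marker genes of
## rejected genomes that fail all cutoffs update the pooled unassigned
## entry.

#' Genome admission filter
#'
#' A genome is admitted to database construction iff it carries at least
#' `min_families` of the 10 marker gene families.
#'
#' @param g A [genome_mg_set()].
#' @param min_families Default 6.
#' @return Logical.
#' @export
#' @examples
#' g <- genome_mg_set("g1", setNames(
#'   replicate(6, make_marker_family(200, seed = 1)), mg_families()[1:6]))
#' admit_genome(g)
admit_genome <- function(g, min_families = 6) {
  n_families(g) >= min_families
}

#' Map a genome's marker genes against the database
#'
#' For each marker gene, reports all database sequences of the same family
#' with global-alignment identity at or above the prefilter (default 0.80),
#' both strands considered.
#'
#' @param g A [genome_mg_set()].
#' @param db An [mg_database()].
#' @param prefilter_id Identity prefilter; defaults to `db$prefilter_id`.
#' @param include_unassigned Also report hits to the unassigned entry's
#'   sequences (default `FALSE`).
#' @return data.frame with columns `family`, `motu_id`, `seq_id`,
#'   `identity`; zero rows if nothing passes the prefilter.
#' @export
map_mgs_to_db <- function(g, db, prefilter_id = db$prefilter_id,
                          include_unassigned = FALSE) {
  ids <- db_motu_ids(db, include_unassigned = include_unassigned)
  out <- list()
  for (m in ids) {
    e <- db$entries[[m]]
    for (f in intersect(names(g$members), names(e$sequences))) {
      targets <- e$sequences[[f]]
      idv <- vapply(targets, function(s) {
        dna_identity(g$members[[f]], s, strand_both = TRUE)
      }, numeric(1))
      keep <- idv >= prefilter_id
      if (any(keep)) {
        out[[length(out) + 1]] <- data.frame(
          family = f, motu_id = m, seq_id = names(targets)[keep],
          identity = unname(idv[keep]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(family = character(0), motu_id = character(0),
                      seq_id = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assign a genome to an existing mOTU
#'
#' The genome goes to the mOTU maximizing the mean per-family best-hit
#' identity, provided at least `min_assign_families` families each meet
#' their family cutoff; ties are broken by the lexicographically smaller
#' motu_id.  Returns `NA` when no mOTU qualifies.
#'
#' @param g A [genome_mg_set()]; must pass [admit_genome()].
#' @param db An [mg_database()].
#' @param min_assign_families Minimum families passing their cutoff
#'   (default 3).
#' @return A motu_id, or `NA_character_`.
#' @export
assign_genome <- function(g, db, min_assign_families = 3) {
  hits <- map_mgs_to_db(g, db)
  if (nrow(hits) == 0) return(NA_character_)
  ## best hit per (motu, family)
  key <- paste(hits$motu_id, hits$family, sep = "\r")
  ord <- order(key, -hits$identity)
  best <- hits[ord[!duplicated(key[ord])], , drop = FALSE]
  scores <- vapply(split(best, best$motu_id), function(h) {
    n_pass <- sum(h$identity >= db$cutoffs[h$family])
    if (n_pass < min_assign_families) return(NA_real_)
    mean(h$identity)
  }, numeric(1))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(NA_character_)
  cand <- names(scores)[scores == max(scores)]
  sort(cand)[1]
}

#' De novo greedy centroid clustering of unassigned genomes
#'
#' Genomes are sorted by family count (descending), then genome_id; each
#' genome joins the first centroid whose mean marker gene identity meets the
#' (mean of per-family) cutoff, otherwise it founds a new centroid.
#' Deterministic given the input.
#'
#' @param gs List of [genome_mg_set()] (all unassigned by
#'   [assign_genome()]).
#' @param cutoffs Per-family cutoffs, as in [default_cutoffs()].
#' @param min_shared Minimum shared families for a comparison (default 2);
#'   pairs sharing fewer never merge.
#' @param id_prefix Prefix for new entry ids (default `"ext_mOTU_"`).
#' @param start_index First index used for naming (default 1).
#' @param category Category of the created entries (default `"ext"`).
#' @return List of new [motu_entry()] objects (empty input gives an empty
#'   list).
#' @export
cluster_new_genomes <- function(gs, cutoffs = default_cutoffs(),
                                min_shared = 2, id_prefix = "ext_mOTU_",
                                start_index = 1, category = "ext") {
  if (length(gs) == 0) return(list())
  ids <- vapply(gs, function(g) g$genome_id, character(1))
  names(gs) <- ids
  ord <- order(-vapply(gs, n_families, integer(1)), ids)
  gs <- gs[ord]
  centroids <- integer(0)          # indices into gs
  members <- list()                # per centroid: member indices
  for (i in seq_along(gs)) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      cg <- gs[[centroids[ci]]]
      shared <- intersect(names(cg$members), names(gs[[i]]$members))
      if (length(shared) < min_shared) next
      id <- pairwise_mg_identity(gs[[i]], cg, min_shared = min_shared)
      if (id$mean >= mean(cutoffs[shared])) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      members[[length(centroids)]] <- i
    }
  }
  lapply(seq_along(centroids), function(ci) {
    gm <- gs[members[[ci]]]
    seqs <- list()
    for (g in gm) {
      for (f in names(g$members)) {
        seqs[[f]] <- c(seqs[[f]], setNames(g$members[[f]], g$genome_id))
      }
    }
    motu_entry(sprintf("%s%05d", id_prefix, start_index + ci - 1L),
               category = category,
               genomes = vapply(gm, function(g) g$genome_id, character(1)),
               sequences = seqs)
  })
}

#' Consensus taxonomic annotation with per-rank consistency
#'
#' At each rank the name held by more than half of the annotated marker
#' genes is assigned.  Consistency categories: `agreeing` (unanimous),
#' `majority` (more than half), `not_agreeing` (no name reaches a majority;
#' name set to `NA`), `not_annotated` (no marker gene annotated at that
#' rank).  Once a rank resolves to `NA`, all lower ranks are forced `NA`.
#'
#' @param lineages List of [tax_lineage()] (one per annotated marker gene,
#'   or per member genome).
#' @return List with `taxonomy` (a [tax_lineage()]) and `consistency`
#'   (named character over [tax_ranks()]).
#' @export
annotate_consensus <- function(lineages) {
  if (length(lineages) == 0) stop("need at least one lineage")
  mat <- do.call(rbind, lapply(lineages, function(l) unclass(l)[tax_ranks()]))
  name <- setNames(rep(NA_character_, 7), tax_ranks())
  cons <- setNames(rep("not_annotated", 7), tax_ranks())
  blocked <- FALSE
  for (r in tax_ranks()) {
    vals <- mat[, r]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      cons[r] <- "not_annotated"
      blocked <- TRUE
      next
    }
    tab <- sort(table(vals), decreasing = TRUE)
    if (blocked) {
      cons[r] <- "not_agreeing"
      next
    }
    if (length(tab) == 1) {
      name[r] <- names(tab)[1]
      cons[r] <- "agreeing"
    } else if (tab[1] > length(vals) / 2) {
      name[r] <- names(tab)[1]
      cons[r] <- "majority"
    } else {
      cons[r] <- "not_agreeing"
      blocked <- TRUE
    }
  }
  list(taxonomy = tax_lineage(unname(name)), consistency = cons)
}

#' Update the pooled unassigned entry
#'
#' Leftover marker genes (those failing all family cutoffs against the
#' database entries) are clustered per family at the family cutoff by
#' greedy centroid clustering, seeded with the existing unassigned
#' representatives; one representative (the longest member, i.e. the
#' centroid after length-descending ordering) per new cluster is appended.
#'
#' @param db An [mg_database()].
#' @param leftover_mgs data.frame with columns `genome_id`, `family`,
#'   `seq`.
#' @return The updated [mg_database()].
#' @export
update_unassigned <- function(db, leftover_mgs) {
  if (is.null(leftover_mgs) || nrow(leftover_mgs) == 0) return(db)
  .check_family(leftover_mgs$family)
  uid <- db_unassigned_id(db)
  entry <- db$entries[[uid]]
  for (f in unique(leftover_mgs$family)) {
    rows <- leftover_mgs[leftover_mgs$family == f, , drop = FALSE]
    ord <- order(-nchar(rows$seq), rows$genome_id)
    rows <- rows[ord, , drop = FALSE]
    reps <- entry$sequences[[f]]            # existing representatives
    n_existing <- length(reps)
    for (i in seq_len(nrow(rows))) {
      joined <- FALSE
      for (r in seq_along(reps)) {
        if (dna_identity(rows$seq[i], reps[[r]], strand_both = TRUE) >=
            db$cutoffs[[f]]) {
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        reps <- c(reps, setNames(rows$seq[i],
                                 sprintf("%s_%s_%04d", UNASSIGNED_ID, f,
                                         length(reps) + 1L)))
      }
    }
    if (length(reps) > n_existing) entry$sequences[[f]] <- reps
  }
  db$entries[[uid]] <- entry
  db
}

#' Extend a database with new genomes
#'
#' Full extension pipeline: admission filter, assignment of admitted
#' genomes to existing mOTUs (assigned genomes are recorded but their
#' sequences are not added, since the species is already represented), de
#' novo clustering of the remainder into new ext-mOTUs, and an update of
#' the unassigned entry with marker genes of rejected genomes that fail all
#' cutoffs.  Every input genome has exactly one fate: `rejected`,
#' `assigned`, or `new_ext`.  Extension is idempotent: re-extending with
#' the same genomes adds nothing.
#'
#' @param db An [mg_database()].
#' @param gs List of [genome_mg_set()].
#' @param lineages Optional named list genome_id -> [tax_lineage()] used to
#'   annotate new entries by [annotate_consensus()].
#' @param min_assign_families Passed to [assign_genome()].
#' @return List with `db` (the extended database) and `report` (data.frame:
#'   `genome_id`, `fate`, `motu_id`).
#' @export
extend_database <- function(db, gs, lineages = NULL, min_assign_families = 3) {
  stopifnot(inherits(db, "mg_database"))
  if (length(gs) == 0) {
    return(list(db = db, report = data.frame(genome_id = character(0),
                                             fate = character(0),
                                             motu_id = character(0),
                                             stringsAsFactors = FALSE)))
  }
  ids <- vapply(gs, function(g) g$genome_id, character(1))
  names(gs) <- ids
  fate <- setNames(rep("rejected", length(gs)), ids)
  target <- setNames(rep(NA_character_, length(gs)), ids)
  admitted <- vapply(gs, admit_genome, logical(1),
                     min_families = db$min_families)
  for (gid in ids[admitted]) {
    m <- assign_genome(gs[[gid]], db, min_assign_families = min_assign_families)
    if (!is.na(m)) {
      fate[gid] <- "assigned"
      target[gid] <- m
      db$entries[[m]]$genomes <- unique(c(db$entries[[m]]$genomes, gid))
    } else {
      fate[gid] <- "unplaced"
    }
  }
  ## de novo clustering of admitted-but-unplaced genomes
  new_gs <- gs[fate == "unplaced"]
  existing_ext <- sum(vapply(db$entries, function(e) e$category == "ext",
                             logical(1)))
  new_entries <- cluster_new_genomes(new_gs, cutoffs = db$cutoffs,
                                     start_index = existing_ext + 1L)
  for (e in new_entries) {
    if (!is.null(lineages)) {
      lin <- lineages[intersect(e$genomes, names(lineages))]
      if (length(lin) > 0) {
        ann <- annotate_consensus(unname(lin))
        e$taxonomy <- ann$taxonomy
        e$consistency <- ann$consistency
      }
    }
    db$entries[[e$motu_id]] <- e
    fate[e$genomes] <- "new_ext"
    target[e$genomes] <- e$motu_id
  }
  ## leftovers: marker genes of rejected genomes failing all family cutoffs
  rejected <- gs[fate == "rejected"]
  if (length(rejected) > 0) {
    leftovers <- list()
    for (g in rejected) {
      hits <- map_mgs_to_db(g, db, include_unassigned = TRUE)
      for (f in names(g$members)) {
        fh <- hits[hits$family == f, , drop = FALSE]
        if (nrow(fh) == 0 || max(fh$identity) < db$cutoffs[[f]]) {
          leftovers[[length(leftovers) + 1]] <- data.frame(
            genome_id = g$genome_id, family = f, seq = g$members[[f]],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(leftovers) > 0) {
      db <- update_unassigned(db, do.call(rbind, leftovers))
    }
  }
  list(db = db,
       report = data.frame(genome_id = ids, fate = unname(fate[ids]),
                           motu_id = unname(target[ids]),
                           stringsAsFactors = FALSE))
}

#' Build a database from scratch
#'
#' Admission filter followed by de novo clustering and consensus
#' annotation.
#'
#' @param gs List of [genome_mg_set()].
#' @param lineages Optional named list genome_id -> [tax_lineage()].
#' @param cutoffs Per-family cutoffs (default [default_cutoffs()]).
#' @param category Category for the created entries (default `"ref"`).
#' @param id_prefix Entry id prefix (default derived from `category`).
#' @param ... Passed to [mg_database()].
#' @return An [mg_database()].
#' @export
build_db <- function(gs, lineages = NULL, cutoffs = default_cutoffs(),
                     category = "ref",
                     id_prefix = paste0(category, "_mOTU_"), ...) {
  admitted <- gs[vapply(gs, admit_genome, logical(1))]
  entries <- cluster_new_genomes(admitted, cutoffs = cutoffs,
                                 id_prefix = id_prefix, category = category)
  entries <- lapply(entries, function(e) {
    if (!is.null(lineages)) {
      lin <- lineages[intersect(e$genomes, names(lineages))]
      if (length(lin) > 0) {
        ann <- annotate_consensus(unname(lin))
        e$taxonomy <- ann$taxonomy
        e$consistency <- ann$consistency
      }
    }
    e
  })
  mg_database(entries, cutoffs = cutoffs, ...)
}
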