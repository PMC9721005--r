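## Insert profiling.
##
## Reads are mapped to the database with a k-mer seed index (both strands)
## followed by ungapped extension along the best-voted diagonal; the
## identity of the clipped window is the hit identity.  An insert (one
## fragment; paired mates share an insert_id) is resolved to the best hit
## by identity, ties broken by longer aligned length then lexicographic
## motu_id.  Hits passing the family cutoff count for that mOTU; hits at or
## above the report floor but below the cutoff -- and hits to the
## unassigned entry's sequences -- count as "unassigned"; inserts without
## hits are discarded.

#' Build the k-mer seed index over a database
#'
#' @param db An [mg_database()].
#' @param k Seed k-mer size (default 14).
#' @return An index object consumed by [align_inserts()].
#' @export
build_read_index <- function(db, k = 14) {
  seq_tab <- list()
  for (m in names(db$entries)) {
    e <- db$entries[[m]]
    for (f in names(e$sequences)) {
      for (si in seq_along(e$sequences[[f]])) {
        seq_tab[[length(seq_tab) + 1]] <- data.frame(
          motu_id = m, family = f,
          seq_id = names(e$sequences[[f]])[si],
          seq = unname(e$sequences[[f]][si]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(seq_tab) == 0) stop("empty database: no marker gene sequences")
  seq_tab <- do.call(rbind, seq_tab)
  seq_tab$len <- nchar(seq_tab$seq)
  seq_tab$seq_idx <- seq_len(nrow(seq_tab))
  kl <- lapply(seq_len(nrow(seq_tab)), function(i) {
    n <- seq_tab$len[i]
    pos <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(seq_tab$seq[i], pos, pos + k - 1L),
                           seq_idx = i, pos = pos)
  })
  index <- data.table::rbindlist(kl)
  data.table::setkey(index, kmer)
  structure(list(index = index, seq_tab = seq_tab, k = k),
            class = "read_index")
}

#' Align inserts against the marker gene database
#'
#' @param reads data.frame with `insert_id`, `seq`; paired mates share an
#'   `insert_id`.
#' @param db An [mg_database()], or a prebuilt [build_read_index()].
#' @param min_identity Report floor (default 0.93).
#' @param min_aln_len Minimum aligned length in nt (default 45).
#' @param seed_step Spacing of seed positions along the read (default 10).
#' @param max_diags Diagonals evaluated per read and strand (default 8).
#' @return data.frame of hits: `insert_id`, `motu_id`, `family`,
#'   `identity`, `aligned_length` (best evidence per insert and database
#'   sequence).
#' @export
align_inserts <- function(reads, db, min_identity = 0.93, min_aln_len = 45,
                          seed_step = 10, max_diags = 8) {
  idx <- if (inherits(db, "read_index")) db else build_read_index(db)
  k <- idx$k
  seq_tab <- idx$seq_tab
  if (nrow(reads) == 0) {
    return(data.frame(insert_id = character(0), motu_id = character(0),
                      family = character(0), identity = numeric(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE))
  }
  hit_list <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") reads$seq else revcomp(reads$seq)
    lens <- nchar(seqs)
    max_start <- max(lens) - k + 1L
    if (max_start < 1) next
    seed_pos <- unique(c(seq(1L, max_start, by = seed_step),
                         max_start))
    seeds <- list()
    for (p in seed_pos) {
      ok <- which(lens - k + 1L >= p)
      if (length(ok) == 0) next
      seeds[[length(seeds) + 1]] <- data.table::data.table(
        read_idx = ok, rpos = p, kmer = substring(seqs[ok], p, p + k - 1L))
    }
    seeds <- data.table::rbindlist(seeds)
    cand <- idx$index[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(cand) == 0) next
    cand[, diag_ := pos - rpos]
    votes <- cand[, .(votes = .N), by = .(read_idx, seq_idx, diag_)]
    data.table::setorder(votes, read_idx, -votes)
    votes <- votes[, utils::head(.SD, max_diags), by = read_idx]
    ## ungapped extension along each candidate diagonal, clipped to the
    ## subject; identity over the overlapping window
    ri <- votes$read_idx
    si <- votes$seq_idx
    q_start <- pmax(1L, 1L - votes$diag_)
    q_end <- pmin(lens[ri], seq_tab$len[si] - votes$diag_)
    aln_len <- q_end - q_start + 1L
    keep <- which(aln_len >= min_aln_len)
    if (length(keep) == 0) next
    ident <- numeric(length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      qs <- substr(seqs[ri[i]], q_start[i], q_end[i])
      ss <- substr(seq_tab$seq[si[i]], q_start[i] + votes$diag_[i],
                   q_end[i] + votes$diag_[i])
      ident[j] <- hamming_identity(qs, ss)
    }
    ok <- ident >= min_identity
    if (!any(ok)) next
    hit_list[[length(hit_list) + 1]] <- data.table::data.table(
      insert_id = reads$insert_id[ri[keep[ok]]],
      seq_idx = si[keep[ok]], identity = ident[ok],
      aligned_length = aln_len[keep[ok]])
  }
  if (length(hit_list) == 0) {
    return(data.frame(insert_id = character(0), motu_id = character(0),
                      family = character(0), identity = numeric(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE))
  }
  hits <- data.table::rbindlist(hit_list)
  ## best evidence per (insert, database sequence) across mates/strands/diagonals
  data.table::setorder(hits, insert_id, seq_idx, -identity, -aligned_length)
  hits <- hits[!duplicated(hits[, .(insert_id, seq_idx)])]
  out <- data.frame(insert_id = hits$insert_id,
                    motu_id = seq_tab$motu_id[hits$seq_idx],
                    family = seq_tab$family[hits$seq_idx],
                    identity = hits$identity,
                    aligned_length = hits$aligned_length,
                    stringsAsFactors = FALSE)
  out
}

#' Resolve insert-level hits to mOTU assignments
#'
#' @param hits Hit table from [align_inserts()].
#' @param db The [mg_database()] (for cutoffs and the unassigned id).
#' @param insert_ids All insert ids in the sample; inserts without hits are
#'   reported as `discarded`.
#' @return data.frame: `insert_id`, `motu_id` (a database id,
#'   `"unassigned"`, or `"discarded"`), `family` (`NA` for discarded).
#' @export
assign_inserts <- function(hits, db, insert_ids = unique(hits$insert_id)) {
  uid <- db_unassigned_id(db)
  res_id <- setNames(rep("discarded", length(insert_ids)), insert_ids)
  res_fam <- setNames(rep(NA_character_, length(insert_ids)), insert_ids)
  if (nrow(hits) > 0) {
    ord <- order(hits$insert_id, -hits$identity, -hits$aligned_length,
                 hits$motu_id)
    best <- hits[ord[!duplicated(hits$insert_id[ord])], , drop = FALSE]
    assigned <- ifelse(
      best$motu_id == uid, UNASSIGNED_ID,
      ifelse(best$identity >= db$cutoffs[best$family],
             best$motu_id, UNASSIGNED_ID))
    res_id[best$insert_id] <- assigned
    res_fam[best$insert_id] <- best$family
  }
  data.frame(insert_id = insert_ids, motu_id = unname(res_id[insert_ids]),
             family = unname(res_fam[insert_ids]), stringsAsFactors = FALSE)
}

#' Quantify assignments into a profile
#'
#' Counts mode returns integer insert counts per mOTU (discarded inserts
#' excluded; the unassigned key is always present).  Relative abundance
#' mode computes, per mOTU, the mean over its families of length-normalized
#' counts (inserts assigned to the family divided by the total family
#' sequence length in kb) and normalizes the scores, including the
#' unassigned score, to sum to 1.  The unassigned entry uses the database-
#' wide mean per-entry family length where it holds no sequences of its own.
#'
#' @param assignments data.frame from [assign_inserts()].
#' @param db An [mg_database()].
#' @param mode `"counts"` or `"relabund"`.
#' @param sample_id Sample identifier (default `"sample"`).
#' @return A [count_profile()] or [relabund_profile()].
#' @export
quantify <- function(assignments, db, mode = c("counts", "relabund"),
                     sample_id = "sample") {
  mode <- match.arg(mode)
  a <- assignments[assignments$motu_id != "discarded", , drop = FALSE]
  if (mode == "counts") {
    counts <- table(a$motu_id)
    return(count_profile(sample_id, setNames(as.integer(counts), names(counts))))
  }
  if (nrow(a) == 0) stop("no assigned inserts; cannot compute relative abundances")
  ## per-entry, per-family sequence length (kb) and counts
  fam_count <- table(a$motu_id, a$family)
  motus <- unique(a$motu_id)
  entry_fam_len <- function(e, f) sum(nchar(e$sequences[[f]])) / 1000
  ## db-wide mean per-entry family length, as effective length for
  ## cutoff-failed "unassigned" mass
  all_lens <- list()
  for (e in db$entries) {
    for (f in names(e$sequences)) {
      all_lens[[f]] <- c(all_lens[[f]], sum(nchar(e$sequences[[f]])) / 1000)
    }
  }
  mean_len <- vapply(all_lens, mean, numeric(1))
  scores <- vapply(motus, function(m) {
    if (m == UNASSIGNED_ID) {
      e <- db$entries[[db_unassigned_id(db)]]
      fams <- unique(a$family[a$motu_id == m])
      per_fam <- vapply(fams, function(f) {
        len <- if (!is.null(e$sequences[[f]])) entry_fam_len(e, f)
               else mean_len[[f]]
        fam_count[m, f] / len
      }, numeric(1))
      return(mean(per_fam))
    }
    e <- db$entries[[m]]
    fams <- names(e$sequences)
    per_fam <- vapply(fams, function(f) {
      cnt <- if (f %in% colnames(fam_count)) fam_count[m, f] else 0
      cnt / entry_fam_len(e, f)
    }, numeric(1))
    mean(per_fam)
  }, numeric(1))
  if (!UNASSIGNED_ID %in% motus) scores[UNASSIGNED_ID] <- 0
  relabund_profile(sample_id, scores / sum(scores), rank = "motu")
}

#' Profile a sample end to end
#'
#' Convenience wrapper: [align_inserts()] then [assign_inserts()] then
#' [quantify()].
#'
#' @inheritParams align_inserts
#' @inheritParams quantify
#' @param index Optional prebuilt [build_read_index()] over `db`.
#' @param ... Passed to [align_inserts()].
#' @return A [count_profile()] or [relabund_profile()].
#' @export
profile_sample <- function(reads, db, mode = c("counts", "relabund"),
                           sample_id = "sample", index = NULL, ...) {
  stopifnot(inherits(db, "mg_database"))
  if (is.null(index)) index <- build_read_index(db)
  hits <- align_inserts(reads, index, ...)
  asg <- assign_inserts(hits, db, insert_ids = unique(reads$insert_id))
  quantify(asg, db, mode = mode, sample_id = sample_id)
}

#' Aggregate a mOTU-level profile to a taxonomic rank
#'
#' Abundances are summed by lineage name at the rank; mass of taxa without
#' an annotation at that rank is reported under `unannotated@<rank>`; the
#' unassigned fraction is carried through unchanged.  The total still sums
#' to 1.
#'
#' @param profile A [relabund_profile()] at rank `"motu"` (profiles already
#'   at the target rank are returned unchanged).
#' @param db The [mg_database()] providing entry taxonomies.
#' @param rank One of [tax_ranks()].
#' @return A [relabund_profile()] at `rank`.
#' @export
aggregate_to_rank <- function(profile, db, rank) {
  if (!rank %in% tax_ranks()) stop("unknown rank: ", rank)
  if (profile$rank == rank) return(profile)
  if (profile$rank != "motu") {
    stop("can only aggregate motu-level profiles (got rank ", profile$rank, ")")
  }
  ab <- profile$abundances
  out <- numeric(0)
  add <- function(out, key, v) {
    out[key] <- (if (key %in% names(out)) out[[key]] else 0) + v
    out
  }
  for (t in names(ab)) {
    if (ab[[t]] == 0 && t != UNASSIGNED_ID) next
    if (t == UNASSIGNED_ID) {
      out <- add(out, UNASSIGNED_ID, ab[[t]])
      next
    }
    lin <- if (t %in% names(db$entries)) db$entries[[t]]$taxonomy else tax_lineage()
    nm <- lin[[rank]]
    key <- if (is.na(nm)) paste0("unannotated@", rank) else nm
    out <- add(out, key, ab[[t]])
  }
  relabund_profile(profile$sample_id, out, rank = rank)
}

#' Rarefy a count profile to fixed depth
#'
#' Subsamples insert counts without replacement (multivariate
#' hypergeometric, `vegan::rrarefy` semantics) so the output total equals
#' `depth` exactly.  A depth above the available total is an error.
#'
#' @param counts A [count_profile()].
#' @param depth Target depth (default 5000).
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return A rarefied [count_profile()].
#' @export
rarefy <- function(counts, depth = 5000, seed = NULL) {
  stopifnot(inherits(counts, "count_profile"))
  if (depth > counts$total_inserts) {
    stop("rarefaction depth ", depth, " exceeds total inserts ",
         counts$total_inserts)
  }
  x <- counts$counts
  ## vegan warns on any minimum count above 1; the inputs here are real
  ## insert counts, so that advisory is muffled
  sub <- with_seed_opt(seed, withCallingHandlers(
    vegan::rrarefy(x, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  count_profile(counts$sample_id, setNames(as.integer(sub[1, ]), names(x)))
}

#' Sample quality control on mapped insert depth
#'
#' Samples with fewer than `min_inserts` mapped inserts are dropped; the
#' boundary is strict ("less than"), so exactly `min_inserts` is kept.
#'
#' @param profile A [count_profile()].
#' @param min_inserts Default 5000.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
sample_qc <- function(profile, min_inserts = 5000) {
  stopifnot(inherits(profile, "count_profile"))
  profile$total_inserts >= min_inserts
}

#' Taxa detected by prevalence across a cohort
#'
#' A taxon is detected when the fraction of samples in which it has nonzero
#' abundance strictly exceeds the threshold.
#'
#' @param cohort List of [relabund_profile()] (or [count_profile()])
#'   objects.
#' @param threshold Prevalence threshold (default 0.001, i.e. 0.1%).
#' @return Character vector of detected taxa.
#' @export
prevalence_detected <- function(cohort, threshold = 0.001) {
  if (length(cohort) == 0) stop("need at least one sample")
  vals <- lapply(cohort, function(p) {
    if (inherits(p, "count_profile")) p$counts else p$abundances
  })
  taxa <- unique(unlist(lapply(vals, names)))
  prev <- vapply(taxa, function(t) {
    mean(vapply(vals, function(v) t %in% names(v) && v[[t]] > 0, logical(1)))
  }, numeric(1))
  names(prev)[prev > threshold]
}

#' Shannon diversity index of a profile
#'
#' Computes `-sum(p * log(p))` in nats over the positive fractions,
#' optionally excluding the unassigned fraction (with renormalization).
#'
#' @param profile A [relabund_profile()].
#' @param exclude_unassigned Drop the unassigned fraction and renormalize
#'   before computing (default `FALSE`).
#' @return Shannon index in nats.
#' @export
shannon_index <- function(profile, exclude_unassigned = FALSE) {
  ab <- profile$abundances
  if (exclude_unassigned) ab <- ab[setdiff(names(ab), UNASSIGNED_ID)]
  ab <- ab[ab > 0]
  if (length(ab) == 0) stop("empty profile")
  ab <- ab / sum(ab)
  unname(vegan::diversity(ab, index = "shannon"))
}
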