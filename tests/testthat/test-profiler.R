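# Insert profiling: seeded alignment, insert resolution against cutoffs,
# quantification, rank aggregation, rarefaction, QC, prevalence detection,
# and Shannon diversity.

make_profiler_db <- function() {
  td <- tiny_db(n_species = 3, gene_length = 600, seed = 83)
  td
}

test_that("insert alignment finds verbatim copies and rejects noise", {
  td <- make_profiler_db()
  db <- td$db
  m1 <- names(db$entries)[1]
  src <- db$entries[[m1]]$sequences$COG0012[[1]]
  reads <- data.frame(insert_id = c("r1", "r2"),
                      seq = c(substr(src, 11, 160),
                              make_marker_family(150, seed = 999)),
                      stringsAsFactors = FALSE)
  hits <- align_inserts(reads, db)
  h1 <- hits[hits$insert_id == "r1", ]
  expect_true(any(h1$motu_id == m1 & h1$identity == 1.0))
  expect_equal(nrow(hits[hits$insert_id == "r2", ]), 0)
})

test_that("hit identity matches the exhaustive alignment oracle", {
  td <- make_profiler_db()
  db <- td$db
  m1 <- names(db$entries)[1]
  src <- db$entries[[m1]]$sequences$COG0016[[1]]
  insert <- mutate_to_identity(substr(src, 51, 250), 0.95, seed = 7)
  hits <- align_inserts(data.frame(insert_id = "q", seq = insert), db)
  best <- max(hits$identity)
  # exhaustive Needleman-Wunsch (pattern-global) over every db sequence
  all_seqs <- unlist(lapply(db$entries, function(e) unlist(e$sequences)))
  oracle <- max(vapply(all_seqs, function(s) {
    a1 <- Biostrings::pairwiseAlignment(Biostrings::DNAString(insert),
                                        Biostrings::DNAString(s),
                                        type = "global-local")
    Biostrings::pid(a1, "PID2") / 100
  }, numeric(1)))
  expect_equal(best, oracle, tolerance = 0.01)
  expect_equal(best, 0.95, tolerance = 0.01)
})

test_that("insert resolution follows floor and family cutoffs", {
  td <- make_profiler_db()
  db <- td$db
  m1 <- names(db$entries)[1]
  src <- db$entries[[m1]]$sequences$COG0012[[1]]
  reads <- data.frame(
    insert_id = c("hi", "mid", "none"),
    seq = c(mutate_to_identity(substr(src, 1, 200), 0.99, seed = 1),
            mutate_to_identity(substr(src, 1, 200), 0.945, seed = 2),
            make_marker_family(200, seed = 3)),
    stringsAsFactors = FALSE)
  hits <- align_inserts(reads, db)
  asg <- assign_inserts(hits, db, insert_ids = reads$insert_id)
  res <- setNames(asg$motu_id, asg$insert_id)
  expect_equal(unname(res[["hi"]]), m1)      # 0.99 >= cutoff 0.965
  expect_equal(unname(res[["mid"]]), "unassigned")  # floor <= 0.945 < cutoff
  expect_equal(unname(res[["none"]]), "discarded")
  # hits to unassigned-entry sequences count as unassigned
  un_seq <- make_marker_family(600, seed = 4)
  db2 <- update_unassigned(db, data.frame(genome_id = "x", family = "COG0018",
                                          seq = un_seq))
  r2 <- data.frame(insert_id = "u", seq = substr(un_seq, 1, 200))
  asg2 <- assign_inserts(align_inserts(r2, db2), db2, insert_ids = "u")
  expect_equal(asg2$motu_id, "unassigned")
})

test_that("profiling is invariant to read order and reverse complement", {
  td <- make_profiler_db()
  db <- td$db
  sp <- setdiff(names(db$entries), "unassigned")[1:2]
  sim <- simulate_inserts(db, community_spec(sp, c(0.7, 0.3), 400, seed = 9))
  p1 <- profile_sample(sim$reads, db, mode = "counts")
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  p2 <- profile_sample(shuffled, db, mode = "counts")
  expect_equal(p1$counts[sort(names(p1$counts))],
               p2$counts[sort(names(p2$counts))])
  flipped <- sim$reads
  flipped$seq <- revcomp(flipped$seq)
  p3 <- profile_sample(flipped, db, mode = "counts")
  expect_equal(p1$counts[sort(names(p1$counts))],
               p3$counts[sort(names(p3$counts))])
})

test_that("quantification normalizes length-weighted family counts", {
  td <- make_profiler_db()
  db <- td$db
  sp <- setdiff(names(db$entries), "unassigned")
  # counts {A:30, B:60, unassigned:10} with equal gene lengths
  asg <- data.frame(
    insert_id = sprintf("i%03d", 1:100),
    motu_id = c(rep(sp[1], 30), rep(sp[2], 60), rep("unassigned", 10)),
    family = rep(mg_families(), 10),
    stringsAsFactors = FALSE)
  cp <- quantify(asg, db, mode = "counts")
  expect_equal(unname(cp$counts[c(sp[1], sp[2], "unassigned")]),
               c(30L, 60L, 10L))
  rp <- quantify(asg, db, mode = "relabund")
  expect_equal(unname(rp$abundances[c(sp[1], sp[2], "unassigned")]),
               c(0.3, 0.6, 0.1), tolerance = 1e-9)
  # single-mOTU community
  asg1 <- asg[1:30, ]
  rp1 <- quantify(asg1, db, mode = "relabund")
  expect_equal(unname(rp1$abundances[sp[1]]), 1.0)
  expect_error(quantify(asg[0, ], db, mode = "relabund"), "no assigned")
})

test_that("rank aggregation conserves mass and reports unannotated", {
  td <- make_profiler_db()
  db <- td$db
  sp <- setdiff(names(db$entries), "unassigned")
  p <- relabund_profile("s", setNames(c(0.6, 0.4), sp[1:2]), rank = "motu")
  # same phylum in the tiny fixture
  agg <- aggregate_to_rank(p, db, "phylum")
  expect_equal(unname(agg$abundances[["Phylum1"]]), 1.0)
  # species differ
  aggs <- aggregate_to_rank(p, db, "species")
  expect_length(setdiff(names(aggs$abundances), "unassigned"), 2)
  expect_equal(sum(aggs$abundances), 1)
  # NA-at-rank mass goes to unannotated@rank
  db$entries[[sp[1]]]$taxonomy <- tax_lineage("Bacteria")
  agg2 <- aggregate_to_rank(p, db, "genus")
  expect_equal(unname(agg2$abundances[["unannotated@genus"]]), 0.6)
  # idempotence at the target rank
  expect_equal(aggregate_to_rank(agg, db, "phylum"), agg)
  expect_error(aggregate_to_rank(p, db, "tribe"), "unknown rank")
})

test_that("rarefaction subsamples to exact depth without replacement", {
  counts <- count_profile("s", c(A = 12000L, B = 6000L, C = 2000L))
  r <- rarefy(counts, depth = 5000, seed = 1)
  expect_equal(r$total_inserts, 5000L)
  expect_true(all(r$counts <= counts$counts[names(r$counts)]))
  expect_identical(rarefy(counts, depth = 5000, seed = 1)$counts, r$counts)
  expect_error(rarefy(counts, depth = 30000, seed = 1), "exceeds")
  single <- count_profile("s", c(A = 9000L))
  expect_equal(unname(rarefy(single, 5000, seed = 2)$counts[["A"]]), 5000L)
  # expectation matches the hypergeometric mean: E[count_i] = depth * p_i
  sums <- rowMeans(vapply(1:400, function(s) {
    rarefy(counts, 5000, seed = s)$counts[c("A", "B", "C")]
  }, numeric(3)))
  expected <- 5000 * c(12000, 6000, 2000) / 20000
  # 3 standard errors of the Monte-Carlo mean (hypergeometric variance)
  n <- 20000; k <- 5000
  v <- k * (c(12000, 6000, 2000) / n) * (1 - c(12000, 6000, 2000) / n) *
    (n - k) / (n - 1)
  expect_true(all(abs(sums - expected) < 3 * sqrt(v / 400)))
})

test_that("sample QC drops strictly below 5000 inserts", {
  mk <- function(n) count_profile("s", c(A = as.integer(n)))
  expect_false(sample_qc(mk(4999)))
  expect_true(sample_qc(mk(5000)))
  expect_false(sample_qc(mk(0)))
})

test_that("prevalence detection uses a strict threshold", {
  mk <- function(ab) relabund_profile("s", c(A = ab, B = 1 - ab))
  everywhere <- replicate(10, mk(0.5), simplify = FALSE)
  expect_true("A" %in% prevalence_detected(everywhere))
  absent <- replicate(10, mk(0), simplify = FALSE)
  expect_false("A" %in% prevalence_detected(absent))
  # 1000 samples with exactly one occurrence: prevalence == 0.1%, strict >
  one_in <- c(list(mk(0.5)), replicate(999, mk(0), simplify = FALSE))
  expect_false("A" %in% prevalence_detected(one_in, threshold = 0.001))
  two_in <- c(list(mk(0.5), mk(0.5)), replicate(998, mk(0), simplify = FALSE))
  expect_true("A" %in% prevalence_detected(two_in, threshold = 0.001))
})

test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(relabund_profile("s", c(A = 1))), 0)
  expect_equal(shannon_index(relabund_profile("s", c(A = 0.5, B = 0.5))),
               log(2), tolerance = 1e-12)
  k <- 7
  unif <- relabund_profile("s", setNames(rep(1 / k, k), letters[1:k]))
  expect_equal(shannon_index(unif), log(k), tolerance = 1e-12)
  # excluding the unassigned fraction renormalizes first
  p <- relabund_profile("s", c(A = 0.45, B = 0.45, unassigned = 0.1))
  expect_equal(shannon_index(p, exclude_unassigned = TRUE), log(2),
               tolerance = 1e-12)
  expect_error(shannon_index(relabund_profile("s", c(unassigned = 1)),
                             exclude_unassigned = TRUE), "empty")
})
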