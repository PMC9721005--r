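# Database construction and extension: admission, mapping, assignment,
# greedy clustering, consensus annotation, the unassigned entry, and the
# idempotence of extension.

test_that("genome admission flips at 6 of 10 families", {
  mk <- function(n) full_genome("g", seed = 1, families = mg_families()[1:n])
  expect_false(admit_genome(mk(5)))
  expect_true(admit_genome(mk(6)))
  expect_true(admit_genome(mk(10)))
})

test_that("pairwise MG identity averages shared families", {
  g1 <- full_genome("a", seed = 1, gene_length = 500)
  g2 <- genome_mg_set("b", c(
    g1$members[1],                                     # identical: 1.00
    COG0016 = mutate_to_identity(g1$members[["COG0016"]], 0.90, seed = 3)))
  res <- pairwise_mg_identity(g1, g2)
  expect_equal(unname(res$per_family), c(1.0, 0.9), tolerance = 1e-9)
  expect_equal(res$mean, 0.95, tolerance = 1e-9)
  expect_equal(pairwise_mg_identity(g1, g1)$mean, 1.0)
  g3 <- genome_mg_set("c", g1$members["COG0012"])
  expect_error(pairwise_mg_identity(g1, g3, min_shared = 2), "share")
})

test_that("mapping respects the 0.8 prefilter and both strands", {
  td <- tiny_db(n_species = 2, gene_length = 600)
  db <- td$db
  m1 <- names(db$entries)[1]
  g_exact <- genome_mg_set("q", vapply(db$entries[[m1]]$sequences, `[[`,
                                       character(1), 1))
  hits <- map_mgs_to_db(g_exact, db)
  self <- hits[hits$motu_id == m1, ]
  expect_true(all(self$identity == 1.0))
  # reverse-complemented query gives the same hits
  g_rc <- genome_mg_set("q", vapply(g_exact$members, revcomp, character(1)))
  hits_rc <- map_mgs_to_db(g_rc, db)
  expect_equal(hits_rc[order(hits_rc$family, hits_rc$motu_id), c(1, 2, 4)],
               hits[order(hits$family, hits$motu_id), c(1, 2, 4)],
               ignore_attr = TRUE)
  # a genome at 0.70 to everything passes no prefilter
  g_far <- genome_mg_set("far", vapply(seq_along(g_exact$members), function(i) {
    mutate_to_identity(g_exact$members[[i]], 0.70, seed = 100 + i)
  }, character(1)) |> setNames(names(g_exact$members)))
  expect_equal(nrow(map_mgs_to_db(g_far, db)), 0)
})

test_that("genome assignment picks the best mOTU and breaks ties low", {
  td <- tiny_db(n_species = 2, gene_length = 600)
  db <- td$db
  m1 <- names(db$entries)[1]
  g_exact <- genome_mg_set("q", vapply(db$entries[[m1]]$sequences, `[[`,
                                       character(1), 1))
  expect_equal(assign_genome(g_exact, db), m1)
  # below cutoff everywhere: no assignment
  g_90 <- mutated_genome(g_exact, "q90", 0.90, seed = 11)
  expect_true(is.na(assign_genome(g_90, db)))
  # equidistant above cutoff to two entries: lexicographically smaller wins
  base <- full_genome("b", seed = 21, gene_length = 600)
  twin_db <- mg_database(list(
    motu_entry("mB", "ref", "b", lapply(base$members, function(s) c(b = s))),
    motu_entry("mA", "ref", "b2", lapply(base$members, function(s) c(b2 = s)))))
  q <- mutated_genome(base, "q", 0.98, seed = 22)
  expect_equal(assign_genome(q, twin_db), "mA")
})

test_that("greedy centroid clustering follows the documented rule", {
  base <- full_genome("A", seed = 31, gene_length = 1000)
  # 3 identical genomes -> one cluster
  gs3 <- list(base, genome_mg_set("B", base$members),
              genome_mg_set("C", base$members))
  cl <- cluster_new_genomes(gs3)
  expect_length(cl, 1)
  expect_equal(sort(cl[[1]]$genomes), c("A", "B", "C"))
  # pairwise 0.85 under cutoff 0.965 -> singletons
  far <- list(base, mutated_genome(base, "B", 0.85, seed = 32))
  expect_length(cluster_new_genomes(far), 2)
  # chain A-B 0.97, B-C 0.97, A-C 0.94 (disjoint mutation sets), order A,B,C:
  # A founds, B joins A, C fails against centroid A -> clusters {A,B}, {C}
  B <- withr::with_seed(33, genome_mg_set("B", vapply(base$members, function(s)
    mgotu:::.substitute_at(s, 1:30), character(1))))
  C <- withr::with_seed(34, genome_mg_set("C", vapply(B$members, function(s)
    mgotu:::.substitute_at(s, 31:60), character(1))))
  expect_equal(pairwise_mg_identity(base, B)$mean, 0.97, tolerance = 1e-9)
  expect_equal(pairwise_mg_identity(B, C)$mean, 0.97, tolerance = 1e-9)
  expect_equal(pairwise_mg_identity(base, C)$mean, 0.94, tolerance = 1e-9)
  cl <- cluster_new_genomes(list(base, B, C))
  expect_length(cl, 2)
  expect_equal(sort(cl[[1]]$genomes), c("A", "B"))
  expect_equal(cl[[2]]$genomes, "C")
  expect_length(cluster_new_genomes(list()), 0)
})

test_that("cluster count is monotone in the cutoff", {
  fx <- make_species_clusters(4, 2, within_id = 0.98, between_id = 0.88,
                              seed = 41, gene_length = 600)
  n_at <- function(cut) length(cluster_new_genomes(fx$genomes,
                                                   cutoffs = default_cutoffs(cut)))
  expect_equal(n_at(1.0), 8)       # every distinct MG set its own cluster
  expect_lte(n_at(0.965), n_at(0.99))
  expect_lte(n_at(0.90), n_at(0.965))
  expect_equal(n_at(0.85), 1)
})

test_that("consensus annotation applies the majority rule per rank", {
  lin <- function(g, s) tax_lineage("Bacteria", "P", "C", "O", "F", g, s)
  # unanimous at all ranks
  ann <- annotate_consensus(rep(list(lin("G1", "S1")), 10))
  expect_equal(unname(unclass(ann$taxonomy)["species"]), "S1")
  expect_true(all(ann$consistency == "agreeing"))
  # 6 vs 4 at genus: majority
  ann <- annotate_consensus(c(rep(list(lin("G1", "S1")), 6),
                              rep(list(lin("G2", "S2")), 4)))
  expect_equal(unname(unclass(ann$taxonomy)["genus"]), "G1")
  expect_equal(unname(ann$consistency["genus"]), "majority")
  # 5 vs 5 at genus: not agreeing, species forced NA
  ann <- annotate_consensus(c(rep(list(lin("G1", "S1")), 5),
                              rep(list(lin("G2", "S2")), 5)))
  expect_true(is.na(unclass(ann$taxonomy)["genus"]))
  expect_equal(unname(ann$consistency["genus"]), "not_agreeing")
  expect_true(is.na(unclass(ann$taxonomy)["species"]))
  # nothing annotated below domain
  ann <- annotate_consensus(list(tax_lineage("Bacteria")))
  expect_equal(unname(ann$consistency["phylum"]), "not_annotated")
})

test_that("the unassigned entry collects one representative per cluster", {
  db <- mg_database()
  s <- make_marker_family(600, seed = 51)
  left5 <- data.frame(genome_id = paste0("g", 1:5), family = "COG0012",
                      seq = s, stringsAsFactors = FALSE)
  db1 <- update_unassigned(db, left5)
  expect_length(db1$entries$unassigned$sequences$COG0012, 1)
  # two leftovers at 0.80 identity: two representatives
  left2 <- data.frame(genome_id = c("h1", "h2"), family = "COG0016",
                      seq = c(s, mutate_to_identity(s, 0.80, seed = 52)),
                      stringsAsFactors = FALSE)
  db2 <- update_unassigned(db1, left2)
  expect_length(db2$entries$unassigned$sequences$COG0016, 2)
  # a leftover identical to an existing representative adds nothing
  db3 <- update_unassigned(db2, left5[1, ])
  expect_length(db3$entries$unassigned$sequences$COG0012, 1)
})

test_that("database extension assigns, clusters, and is idempotent", {
  td <- tiny_db(n_species = 2, gene_length = 600)
  db <- td$db
  # new distant genomes -> ext-mOTUs; a 5-family genome -> rejected
  novel <- list(full_genome("n1", seed = 61, gene_length = 600),
                full_genome("n2", seed = 62, gene_length = 600))
  small <- full_genome("n3", seed = 63, gene_length = 600,
                       families = mg_families()[1:5])
  rep1 <- genome_mg_set("dup1", vapply(db$entries[[1]]$sequences, `[[`,
                                       character(1), 1))
  res <- extend_database(db, c(novel, list(small, rep1)))
  rep_fates <- setNames(res$report$fate, res$report$genome_id)
  expect_equal(unname(rep_fates[c("n1", "n2")]), c("new_ext", "new_ext"))
  expect_equal(unname(rep_fates[["n3"]]), "rejected")
  expect_equal(unname(rep_fates[["dup1"]]), "assigned")
  expect_true(all(res$report$fate %in% c("rejected", "assigned", "new_ext")))
  cats <- vapply(res$db$entries, function(e) e$category, character(1))
  expect_equal(sum(cats == "ext"), 2)
  # the rejected genome's MGs went to the unassigned entry
  un <- res$db$entries$unassigned
  expect_equal(sum(lengths(un$sequences)), 5)
  # idempotence: extending again with the same genomes adds nothing
  res2 <- extend_database(res$db, c(novel, list(small, rep1)))
  expect_equal(sum(res2$report$fate == "new_ext"), 0)
  expect_equal(sort(names(res2$db$entries)), sort(names(res$db$entries)))
  expect_equal(sum(lengths(res2$db$entries$unassigned$sequences)), 5)
  # extending an empty database with distant genomes founds one mOTU each
  res3 <- extend_database(mg_database(), novel)
  expect_equal(sum(res3$report$fate == "new_ext"), 2)
  cats3 <- vapply(res3$db$entries, function(e) e$category, character(1))
  expect_equal(sum(cats3 == "ext"), 2)
})

test_that("planted clusters straddling the cutoff are recovered exactly", {
  fx <- make_species_clusters(3, 3, within_id = 0.97, between_id = 0.85,
                              seed = 71, gene_length = 800)
  entries <- cluster_new_genomes(fx$genomes)
  pred <- unlist(lapply(entries, function(e) {
    setNames(rep(e$motu_id, length(e$genomes)), e$genomes)
  }))
  vm <- v_measure(fx$truth, pred[names(fx$truth)])
  expect_equal(vm$v, 1.0)
})
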