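## Clustering-congruence machinery: MinHash (Mash-like) genome sketch
## distances, greedy identity clustering of conserved loci, ANI clustering,
## the V-measure, and distance-distance correlations between marker gene,
## locus and whole-genome distances.

.HASH_P <- 2147483647  # 2^31 - 1

## canonical k-mer values of a sequence as exact doubles (4^k < 2^53 for
## k <= 21), then scrambled with a seeded affine hash mod 2^31 - 1.
## k-mers containing N are skipped.
.kmer_hashes <- function(seq, k, a, b) {
  if (nchar(seq) < k) stop("sequence shorter than k (", k, ")")
  d <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1
  n <- length(d) - k + 1
  m <- stats::embed(d, k)  # row i = d[i+k-1], d[i+k-2], ..., d[i]
  fwd <- as.vector(m %*% 4^(0:(k - 1)))          # d[i+j] * 4^j
  rcv <- as.vector((3 - m) %*% 4^((k - 1):0))
  v <- pmin(fwd, rcv)
  v <- v[!is.na(v)]
  unique(((v %% .HASH_P) * a + b) %% .HASH_P)
}

.hash_params <- function(seed) {
  with_seed_opt(seed, sample.int(2^20, 2))
}

#' Bottom-s MinHash sketch of a genome
#'
#' @param seq Genome DNA string.
#' @param k K-mer size (default 21).
#' @param sketch_size Sketch size s (default 1000).
#' @param seed Seed selecting the hash function.
#' @return Sorted numeric vector of at most `sketch_size` hashes.
#' @export
minhash_sketch <- function(seq, k = 21, sketch_size = 1000, seed = 1) {
  ab <- .hash_params(seed)
  h <- sort(.kmer_hashes(toupper(seq), k, ab[1], ab[2]))
  h[seq_len(min(sketch_size, length(h)))]
}

.sketch_stats <- function(sa, sb, k, sketch_size) {
  u <- sort(unique(c(sa, sb)))
  u <- u[seq_len(min(sketch_size, length(u)))]
  shared <- sum(u %in% sa & u %in% sb)
  j <- shared / length(u)
  d <- if (j <= 0) 1 else min(1, -(1 / k) * log(2 * j / (1 + j)))
  list(jaccard = j, mash_distance = d, ani_estimate = 1 - d)
}

#' MinHash sketch distance between two genomes
#'
#' Bottom-s MinHash over canonical k-mers; the Jaccard index is estimated
#' from the bottom-s of the merged sketch and converted to a Mash distance
#' `-(1/k) * log(2j / (1 + j))`, with `ani_estimate = 1 - mash_distance`.
#'
#' @param genome_a,genome_b DNA strings (intended for genomes of at least
#'   5 kb; shorter than `k` is an error).
#' @param k K-mer size (default 21).
#' @param sketch_size Sketch size (default 1000).
#' @param seed Seed selecting the hash function (default 1).
#' @return List with `jaccard`, `mash_distance`, `ani_estimate`.
#' @export
sketch_distance <- function(genome_a, genome_b, k = 21, sketch_size = 1000,
                            seed = 1) {
  sa <- minhash_sketch(genome_a, k, sketch_size, seed)
  sb <- minhash_sketch(genome_b, k, sketch_size, seed)
  .sketch_stats(sa, sb, k, sketch_size)
}

#' Greedy centroid clustering by sequence identity
#'
#' Inputs are sorted by length (descending), then id; each sequence joins
#' the first centroid whose global-alignment identity meets the cutoff,
#' otherwise it founds a new cluster.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param cutoff Identity cutoff in (0, 1\].
#' @param strand_both Consider both strands (default `TRUE`).
#' @return Named character vector item -> cluster label (the centroid's
#'   id), a `ClusterAssignment`.
#' @export
identity_cluster <- function(seqs, cutoff, strand_both = TRUE) {
  if (length(seqs) == 0) stop("empty input")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  ids <- names(seqs)
  if (is.null(ids)) stop("seqs must be named")
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  centroid <- character(0)
  labels <- setNames(character(length(ids)), ids)
  for (i in seq_along(ids)) {
    placed <- NA_character_
    for (c_id in centroid) {
      if (dna_identity(seqs[[i]], seqs[[c_id]], strand_both = strand_both) >=
          cutoff) {
        placed <- c_id
        break
      }
    }
    if (is.na(placed)) {
      centroid <- c(centroid, ids[i])
      placed <- ids[i]
    }
    labels[ids[i]] <- placed
  }
  labels
}

#' Greedy centroid clustering by ANI estimate
#'
#' @param genomes Named character vector of genome sequences.
#' @param cutoff ANI cutoff (default 0.95, the conventional species
#'   boundary).
#' @param k,sketch_size,seed Sketch parameters (see [sketch_distance()]).
#' @return Named character vector item -> cluster label.
#' @export
ani_cluster <- function(genomes, cutoff = 0.95, k = 21, sketch_size = 1000,
                        seed = 1) {
  if (length(genomes) == 0) stop("empty input")
  ids <- names(genomes)
  sketches <- lapply(genomes, minhash_sketch, k = k,
                     sketch_size = sketch_size, seed = seed)
  ord <- order(-nchar(genomes), ids)
  ids <- ids[ord]
  centroid <- character(0)
  labels <- setNames(character(length(ids)), ids)
  for (i in seq_along(ids)) {
    placed <- NA_character_
    for (c_id in centroid) {
      st <- .sketch_stats(sketches[[ids[i]]], sketches[[c_id]], k, sketch_size)
      if (st$ani_estimate >= cutoff) {
        placed <- c_id
        break
      }
    }
    if (is.na(placed)) {
      centroid <- c(centroid, ids[i])
      placed <- ids[i]
    }
    labels[ids[i]] <- placed
  }
  labels
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' V-measure between two clusterings
#'
#' Entropy-based agreement between a reference (`truth`) and a predicted
#' clustering over the same items: homogeneity
#' `h = 1 - H(truth | pred) / H(truth)`, completeness
#' `c = 1 - H(pred | truth) / H(pred)`, and
#' `V = (1 + beta) h c / (beta h + c)`.  By convention `h = 1` when
#' `H(truth) = 0` and `c = 1` when `H(pred) = 0`.
#'
#' @param truth,pred Named vectors item -> cluster label over the same
#'   item set.
#' @param beta Weight of homogeneity vs completeness (default 1).
#' @return List with `homogeneity`, `completeness`, `v`.
#' @export
v_measure <- function(truth, pred, beta = 1) {
  if (is.null(names(truth)) || is.null(names(pred))) {
    stop("truth and pred must be named by item")
  }
  if (!setequal(names(truth), names(pred)) ||
      length(truth) != length(pred)) {
    stop("truth and pred must cover the same item set")
  }
  pred <- pred[names(truth)]
  n <- length(truth)
  tab <- table(truth, pred)
  p_joint <- tab / n
  p_t <- rowSums(p_joint)
  p_p <- colSums(p_joint)
  h_t <- .entropy(p_t)
  h_p <- .entropy(p_p)
  h_tp <- -sum(p_joint[p_joint > 0] *
                 log(p_joint[p_joint > 0] /
                       rep(p_p, each = nrow(p_joint))[p_joint > 0]))
  h_pt <- -sum(p_joint[p_joint > 0] *
                 log(p_joint[p_joint > 0] /
                       p_t[row(p_joint)][p_joint > 0]))
  h <- if (h_t == 0) 1 else 1 - h_tp / h_t
  cmp <- if (h_p == 0) 1 else 1 - h_pt / h_p
  v <- if (h + cmp == 0) 0 else (1 + beta) * h * cmp / (beta * h + cmp)
  list(homogeneity = h, completeness = cmp, v = v)
}

#' Distance-distance correlations of marker genes and a conserved locus
#'
#' For every genome pair, computes the whole-genome sketch distance, the
#' mean marker gene distance (1 - identity, averaged across the shared
#' families), and the conserved-locus distance, then the least-squares
#' r-squared of each against the genome distance.  Degenerate inputs (zero
#' variance) yield `NA` r-squared.
#'
#' @param genomes Named character vector of genome sequences (>= 3).
#' @param mg_sets Named list of [genome_mg_set()], same names.
#' @param loci Named character vector of locus sequences, same names.
#' @param k,sketch_size,seed Sketch parameters (default k = 12, suited to
#'   the divergence range of the fixtures).
#' @return List with `pairs` (data.frame: `a`, `b`, `genome_dist`,
#'   `mean_mg_dist`, `locus_dist`), `r2_mg`, `r2_locus`.
#' @export
distance_correlation_table <- function(genomes, mg_sets, loci, k = 12,
                                       sketch_size = 1000, seed = 1) {
  ids <- names(genomes)
  if (length(ids) < 3) stop("need at least 3 genomes")
  stopifnot(setequal(ids, names(mg_sets)), setequal(ids, names(loci)))
  sketches <- lapply(genomes, minhash_sketch, k = k,
                     sketch_size = sketch_size, seed = seed)
  pairs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    gd <- .sketch_stats(sketches[[a]], sketches[[b]], k, sketch_size)$mash_distance
    md <- 1 - pairwise_mg_identity(mg_sets[[a]], mg_sets[[b]])$mean
    ld <- 1 - dna_identity(loci[[a]], loci[[b]])
    data.frame(a = a, b = b, genome_dist = gd, mean_mg_dist = md,
               locus_dist = ld, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  r2 <- function(y) {
    if (var(tab$genome_dist) == 0 || var(y) == 0) return(NA_real_)
    cor(tab$genome_dist, y)^2
  }
  list(pairs = tab, r2_mg = r2(tab$mean_mg_dist), r2_locus = r2(tab$locus_dist))
}
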