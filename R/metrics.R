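## Profile quality metrics in the style of the CAMI/OPAL benchmarking
## framework: presence/absence F1, L1 norm error, completeness and purity,
## weighted UniFrac error over the taxonomy tree (unit branch lengths), the
## sum-of-ranks composite, and Spearman congruence with a reference
## profiler.  The unassigned fraction and unannotated@rank mass are
## excluded before metric computation (gold standards enumerate named taxa
## only); L1 renormalizes over the named taxa by default.

.named_abundances <- function(profile) {
  ab <- if (inherits(profile, "relabund_profile")) profile$abundances
        else unlist(profile)
  drop <- names(ab) == UNASSIGNED_ID | startsWith(names(ab), "unannotated@")
  ab[!drop]
}

#' Presence/absence precision, recall and F1
#'
#' Computed over the sets of named taxa with positive abundance;
#' `F1 = 2PR/(P+R)`, and 0 when there are no true positives.
#'
#' @param pred,gold [relabund_profile()] objects at the same rank (the
#'   unassigned fraction is excluded).
#' @return List with `precision`, `recall`, `f1`.
#' @export
presence_absence_f1 <- function(pred, gold) {
  ps <- names(.named_abundances(pred)[.named_abundances(pred) > 0])
  gs <- names(.named_abundances(gold)[.named_abundances(gold) > 0])
  if (length(gs) == 0) stop("empty gold standard")
  tp <- length(intersect(ps, gs))
  precision <- if (length(ps) == 0) 0 else tp / length(ps)
  recall <- tp / length(gs)
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' L1 norm error between two profiles
#'
#' Sum of absolute abundance differences over the union of named taxa,
#' after renormalizing each profile over its named taxa; range \[0, 2\].
#'
#' @param pred,gold [relabund_profile()] objects at the same rank.
#' @param renormalize Renormalize named-taxon abundances to sum to 1
#'   (default `TRUE`, matching comparison against gold standards without an
#'   unassigned fraction).
#' @return L1 error.
#' @export
l1_norm_error <- function(pred, gold, renormalize = TRUE) {
  pa <- .named_abundances(pred)
  ga <- .named_abundances(gold)
  if (renormalize) {
    if (sum(pa) > 0) pa <- pa / sum(pa)
    if (sum(ga) > 0) ga <- ga / sum(ga)
  }
  taxa <- union(names(pa), names(ga))
  p <- setNames(rep(0, length(taxa)), taxa); p[names(pa)] <- pa
  g <- setNames(rep(0, length(taxa)), taxa); g[names(ga)] <- ga
  sum(abs(p - g))
}

#' Completeness and purity of a predicted profile
#'
#' Completeness is the recall of gold taxa; purity the precision of the
#' predictions after dropping those below `filter_threshold`.  An empty
#' prediction yields purity 0 with a warning.
#'
#' @param pred,gold [relabund_profile()] objects at the same rank.
#' @param filter_threshold Predictions at or below this abundance are
#'   dropped before computing purity (default 0).
#' @return List with `completeness`, `purity`.
#' @export
completeness_purity <- function(pred, gold, filter_threshold = 0) {
  pa <- .named_abundances(pred)
  pa <- pa[pa > filter_threshold]
  gs <- names(.named_abundances(gold)[.named_abundances(gold) > 0])
  tp <- length(intersect(names(pa), gs))
  completeness <- if (length(gs) == 0) 0 else tp / length(gs)
  if (length(pa) == 0) {
    warning("empty prediction: purity undefined, reported as 0")
    return(list(completeness = completeness, purity = 0))
  }
  list(completeness = completeness, purity = tp / length(pa))
}

## build the taxonomy tree node table from a set of lineages; each node is
## (rank, name) with an edge of unit length to its parent.  A name observed
## under two different parents at the same rank is an error.
.lineage_nodes <- function(lineages) {
  nodes <- list()  # key -> parent key
  for (lin in lineages) {
    v <- unclass(lin)[tax_ranks()]
    parent <- "root"
    for (r_i in seq_along(tax_ranks())) {
      if (is.na(v[r_i])) break
      key <- paste(tax_ranks()[r_i], v[r_i], sep = ":")
      if (!is.null(nodes[[key]]) && nodes[[key]] != parent) {
        stop("inconsistent lineages: ", v[r_i], " occurs under two parents")
      }
      nodes[[key]] <- parent
      parent <- key
    }
  }
  nodes
}

#' Weighted UniFrac error over the taxonomy
#'
#' The taxonomy tree is built from the union of lineages with unit branch
#' lengths between consecutive ranks; the error is the sum over edges of
#' `branch_length * |pred_subtree_mass - gold_subtree_mass|`, with subtree
#' masses read off the rank-resolved profiles.  Unassigned and
#' unannotated mass carries no taxonomy path and does not contribute.
#'
#' @param pred_ranks,gold_ranks Named lists rank -> [relabund_profile()]
#'   over the seven ranks (missing ranks are an error).
#' @param lineages List of [tax_lineage()] covering the union of taxa.
#' @return Weighted UniFrac error.
#' @export
weighted_unifrac_error <- function(pred_ranks, gold_ranks, lineages) {
  missing <- setdiff(tax_ranks(), union(names(pred_ranks), names(gold_ranks)))
  if (length(missing) > 0) stop("missing ranks: ", paste(missing, collapse = ", "))
  nodes <- .lineage_nodes(lineages)
  mass <- function(profs, rank, name) {
    p <- profs[[rank]]
    if (is.null(p)) return(0)
    ab <- .named_abundances(p)
    if (name %in% names(ab)) ab[[name]] else 0
  }
  err <- 0
  for (key in names(nodes)) {
    rk <- sub(":.*$", "", key)
    nm <- sub("^[^:]+:", "", key)
    err <- err + abs(mass(pred_ranks, rk, nm) - mass(gold_ranks, rk, nm))
  }
  err
}

#' OPAL-style sum of ranks across tools
#'
#' For every (sample, rank, metric) cell the tools are ranked, 0 = best,
#' ties sharing the mean of their positions; the score of a tool is the sum
#' over all cells, lower meaning better.
#'
#' @param metrics Long data.frame with columns `tool`, `sample`, `rank`,
#'   `metric`, `value`; every tool must cover every (sample, rank, metric)
#'   cell.
#' @param higher_better Named logical vector by metric; `TRUE` if larger
#'   values are better (e.g. completeness, purity, f1) and `FALSE` for
#'   error metrics (l1, unifrac).
#' @return data.frame with `tool`, `score`, sorted by score.
#' @export
opal_sum_of_scores <- function(metrics,
                               higher_better = c(completeness = TRUE,
                                                 purity = TRUE, f1 = TRUE,
                                                 l1 = FALSE, unifrac = FALSE)) {
  req <- c("tool", "sample", "rank", "metric", "value")
  if (!all(req %in% names(metrics))) {
    stop("metrics needs columns: ", paste(req, collapse = ", "))
  }
  tools <- sort(unique(metrics$tool))
  if (length(tools) < 2) stop("need at least 2 tools")
  unknown <- setdiff(unique(metrics$metric), names(higher_better))
  if (length(unknown) > 0) {
    stop("no direction for metric(s): ", paste(unknown, collapse = ", "))
  }
  cell <- paste(metrics$sample, metrics$rank, metrics$metric, sep = "\r")
  counts <- table(cell)
  if (any(counts != length(tools)) ||
      anyDuplicated(paste(cell, metrics$tool))) {
    stop("missing cells: every tool must cover every (sample, rank, metric)")
  }
  scores <- setNames(rep(0, length(tools)), tools)
  for (cl in unique(cell)) {
    rows <- metrics[cell == cl, , drop = FALSE]
    v <- rows$value
    if (higher_better[[rows$metric[1]]]) v <- -v
    r <- rank(v, ties.method = "average") - 1
    scores[rows$tool] <- scores[rows$tool] + r
  }
  out <- data.frame(tool = names(scores), score = unname(scores),
                    stringsAsFactors = FALSE)
  out[order(out$score, out$tool), , drop = FALSE]
}

#' Spearman congruence with a reference profiler
#'
#' Taxa are union-aligned with zero fill, the per-sample abundance vectors
#' concatenated across samples, and the Spearman rho of the concatenated
#' vectors returned.  Constant vectors yield `NA`.
#'
#' @param pred_profiles,ref_profiles Named lists (by sample) of
#'   [relabund_profile()] at a common rank; at least 2 samples, matched by
#'   name.
#' @return Spearman rho, or `NA`.
#' @export
spearman_vs_reference <- function(pred_profiles, ref_profiles) {
  samples <- names(pred_profiles)
  if (length(samples) < 2) stop("need at least 2 samples")
  if (!setequal(samples, names(ref_profiles))) {
    stop("sample sets differ between prediction and reference")
  }
  px <- c(); rx <- c()
  for (s in samples) {
    pa <- .named_abundances(pred_profiles[[s]])
    ra <- .named_abundances(ref_profiles[[s]])
    taxa <- union(names(pa), names(ra))
    p <- setNames(rep(0, length(taxa)), taxa); p[names(pa)] <- pa
    r <- setNames(rep(0, length(taxa)), taxa); r[names(ra)] <- ra
    px <- c(px, p); rx <- c(rx, r)
  }
  if (var(px) == 0 || var(rx) == 0) return(NA_real_)
  suppressWarnings(cor(px, rx, method = "spearman"))
}
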