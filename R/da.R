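## Differential abundance workflow: max-abundance filter, two-sided
## Wilcoxon rank-sum per taxon, Benjamini-Hochberg correction at 5% FDR,
## and the generalized fold change (gFC) effect size -- the mean difference
## of log10 group quantiles over a 0.1..0.9 grid with a 1e-5 pseudo-count.
## A taxon is called significant when q < alpha AND |gFC| > gfc_min; a gFC
## of 1 corresponds to a tenfold shift.

.cohort_matrix <- function(profiles, drop_unassigned = TRUE) {
  vals <- lapply(profiles, function(p) {
    if (inherits(p, "relabund_profile")) p$abundances else unlist(p)
  })
  taxa <- unique(unlist(lapply(vals, names)))
  if (drop_unassigned) taxa <- setdiff(taxa, UNASSIGNED_ID)
  m <- matrix(0, nrow = length(taxa), ncol = length(vals),
              dimnames = list(taxa, names(profiles)))
  for (j in seq_along(vals)) {
    common <- intersect(taxa, names(vals[[j]]))
    m[common, j] <- vals[[j]][common]
  }
  m
}

#' Maximum-abundance filter
#'
#' Keeps taxa whose relative abundance strictly exceeds the threshold in at
#' least one sample (default 0.1%).
#'
#' @param cohort List of [relabund_profile()] objects.
#' @param threshold Default 0.001.
#' @return Character vector of retained taxa.
#' @export
abundance_filter <- function(cohort, threshold = 0.001) {
  if (length(cohort) == 0) stop("need at least one sample")
  m <- .cohort_matrix(cohort)
  rownames(m)[apply(m, 1, max) > threshold]
}

#' Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' Two-sided Wilcoxon rank-sum per taxon between the two design groups:
#' exact when both groups have at most 25 samples and the taxon has no
#' tied values, normal approximation with continuity and tie correction
#' otherwise.  P-values are BH-adjusted.
#'
#' @param cohort List of [relabund_profile()] objects, named by sample.
#' @param design data.frame with `sample_id`, `group` (exactly two
#'   levels, each with >= 3 samples).
#' @param taxa Taxa to test (default: all named taxa in the cohort).
#' @return data.frame with `taxon`, `p`, `q`.
#' @export
wilcoxon_bh <- function(cohort, design, taxa = NULL) {
  m <- .cohort_matrix(cohort)
  groups <- sort(unique(design$group))
  if (length(groups) != 2) stop("design must have exactly two groups")
  ga <- design$sample_id[design$group == groups[1]]
  gb <- design$sample_id[design$group == groups[2]]
  if (length(ga) < 3 || length(gb) < 3) stop("each group needs >= 3 samples")
  if (!all(c(ga, gb) %in% colnames(m))) stop("design samples missing from cohort")
  if (is.null(taxa)) taxa <- rownames(m)
  p <- vapply(taxa, function(t) {
    x <- m[t, ga]; y <- m[t, gb]
    exact <- length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE)$p.value)
  }, numeric(1))
  data.frame(taxon = taxa, p = unname(p),
             q = unname(p.adjust(p, method = "BH")),
             stringsAsFactors = FALSE)
}

#' Generalized fold change
#'
#' Mean, over a quantile grid, of the difference of log10 quantiles of the
#' two groups (plus a pseudo-count): positive values mean higher abundance
#' in group B.  A value of 1 corresponds to a tenfold shift.  Quantiles use
#' linear (type 7) interpolation.
#'
#' @param group_a,group_b Numeric abundance vectors (non-empty).
#' @param probs Quantile grid (default `seq(0.1, 0.9, 0.1)`).
#' @param pseudo Pseudo-count (default 1e-5).
#' @return The gFC in log10 units.
#' @export
#' @examples
#' a <- c(0.001, 0.002, 0.004)
#' generalized_fold_change(a, 10 * a, pseudo = 0)  # exactly 1
generalized_fold_change <- function(group_a, group_b,
                                    probs = seq(0.1, 0.9, by = 0.1),
                                    pseudo = 1e-5) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  qa <- quantile(group_a, probs = probs, type = 7, names = FALSE)
  qb <- quantile(group_b, probs = probs, type = 7, names = FALSE)
  mean(log10(qb + pseudo) - log10(qa + pseudo))
}

#' Run the full differential abundance workflow
#'
#' Abundance filter, Wilcoxon rank-sum, BH correction, and gFC; a taxon is
#' significant iff `q < alpha` and `|gfc| > gfc_min`.  Deterministic given
#' the input.
#'
#' @param cohort List of [relabund_profile()] objects, named by sample.
#' @param design data.frame with `sample_id`, `group` (two levels; gFC is
#'   oriented so that positive means higher in the second sorted level).
#' @param alpha FDR level (default 0.05).
#' @param gfc_min Effect size threshold in log10 units (default 1.0, i.e.
#'   tenfold).
#' @param threshold Abundance filter threshold (default 0.001).
#' @param probs,pseudo Passed to [generalized_fold_change()].
#' @return data.frame with `taxon`, `gfc`, `p`, `q`, `significant`,
#'   ordered by `q`.
#' @export
run_da <- function(cohort, design, alpha = 0.05, gfc_min = 1.0,
                   threshold = 0.001, probs = seq(0.1, 0.9, by = 0.1),
                   pseudo = 1e-5) {
  taxa <- abundance_filter(cohort, threshold = threshold)
  if (length(taxa) == 0) {
    return(data.frame(taxon = character(0), gfc = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  tests <- wilcoxon_bh(cohort, design, taxa = taxa)
  m <- .cohort_matrix(cohort)
  groups <- sort(unique(design$group))
  ga <- design$sample_id[design$group == groups[1]]
  gb <- design$sample_id[design$group == groups[2]]
  gfc <- vapply(taxa, function(t) {
    generalized_fold_change(m[t, ga], m[t, gb], probs = probs, pseudo = pseudo)
  }, numeric(1))
  out <- data.frame(taxon = tests$taxon, gfc = unname(gfc[tests$taxon]),
                    p = tests$p, q = tests$q, stringsAsFactors = FALSE)
  out$significant <- out$q < alpha & abs(out$gfc) > gfc_min
  out[order(out$q, out$taxon), , drop = FALSE]
}
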