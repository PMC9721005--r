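## Profile I/O: a simple three-column TSV (taxon_id, lineage, value) with
## header comments carrying sample metadata, and the Bioboxes/CAMI profiling
## format.  The unassigned fraction is written as taxon_id "-1" in the TSV
## (mOTU convention) and omitted from CAMI rows, which require a taxonomy
## path.

.lineage_string <- function(lin) {
  if (is.null(lin)) return("-")
  paste(ifelse(is.na(lin), "NA", lin), collapse = ";")
}

.parse_lineage_string <- function(s) {
  if (is.na(s) || s == "-") return(NULL)
  tax_lineage(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Write a profile to TSV
#'
#' Columns: `taxon_id`, `lineage` (semicolon-joined 7 ranks or `-`),
#' `value` (integer counts or abundance fraction).  The unassigned row uses
#' taxon_id `-1`.  Header comment lines record sample id, profile type and
#' rank so that [read_profile_tsv()] round-trips exactly.
#'
#' @param profile A [count_profile()] or [relabund_profile()].
#' @param path Output file.
#' @param db Optional [mg_database()] used to fill the lineage column.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, db = NULL) {
  is_counts <- inherits(profile, "count_profile")
  if (!is_counts && !inherits(profile, "relabund_profile")) {
    stop("profile must be a count_profile or relabund_profile")
  }
  vals <- if (is_counts) profile$counts else profile$abundances
  taxa <- names(vals)
  ord <- c(sort(setdiff(taxa, UNASSIGNED_ID)),
           intersect(UNASSIGNED_ID, taxa))
  vals <- vals[ord]
  lineage <- vapply(ord, function(t) {
    if (t == UNASSIGNED_ID) return("-")
    if (!is.null(db) && t %in% names(db$entries)) {
      .lineage_string(db$entries[[t]]$taxonomy)
    } else "-"
  }, character(1))
  taxon_id <- ifelse(ord == UNASSIGNED_ID, "-1", ord)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample_id=", profile$sample_id),
               paste0("# type=", if (is_counts) "counts" else "relabund"),
               paste0("# rank=", if (is_counts) "motu" else profile$rank),
               "# taxon_id\tlineage\tvalue"), con)
  df <- data.frame(taxon_id = taxon_id, lineage = lineage,
                   value = if (is_counts) format(vals, scientific = FALSE, trim = TRUE)
                           else format(vals, digits = 17, trim = TRUE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a profile TSV written by [write_profile_tsv()]
#'
#' @param path Input file.
#' @return A [count_profile()] or [relabund_profile()], per the file header.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) == 0) stop("missing header '", key, "' in ", path)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  sample_id <- get("sample_id"); type <- get("type"); rank <- get("rank")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  taxon <- vapply(parts, `[`, character(1), 1)
  value <- as.numeric(vapply(parts, `[`, character(1), 3))
  taxon[taxon == "-1"] <- UNASSIGNED_ID
  vals <- setNames(value, taxon)
  if (type == "counts") count_profile(sample_id, vals)
  else relabund_profile(sample_id, vals, rank = rank)
}

#' Write rank-resolved profiles in CAMI (Bioboxes) profiling format
#'
#' Emits `@SampleID`, `@Version`, `@Ranks` headers and one data row per
#' taxon and rank: `TAXID RANK TAXPATH TAXPATHSN PERCENTAGE`.  Taxon names
#' double as free-form taxids; TAXPATH is the pipe-joined name path.  The
#' unassigned fraction and `unannotated@rank` mass carry no taxonomy path
#' and are omitted, so per-rank percentages sum to at most 100.
#'
#' @param profiles_by_rank Named list rank -> [relabund_profile()], covering
#'   all seven ranks of [tax_ranks()].
#' @param path Output file.
#' @param sample_id Sample identifier.
#' @param lineages List of [tax_lineage()] covering every named taxon (e.g.
#'   from the database entries).
#' @return `path`, invisibly.
#' @export
write_cami_profile <- function(profiles_by_rank, path, sample_id, lineages) {
  missing <- setdiff(tax_ranks(), names(profiles_by_rank))
  if (length(missing) > 0) {
    stop("missing rank profile(s): ", paste(missing, collapse = ", "))
  }
  ## name -> path lookup per rank
  lin_mat <- do.call(rbind, lapply(lineages, function(l) unclass(l)[tax_ranks()]))
  rows <- character(0)
  for (r_i in seq_along(tax_ranks())) {
    r <- tax_ranks()[r_i]
    p <- profiles_by_rank[[r]]
    ab <- p$abundances
    taxa <- setdiff(names(ab), c(UNASSIGNED_ID, paste0("unannotated@", r)))
    for (t in taxa) {
      if (ab[[t]] <= 0) next
      hit <- which(lin_mat[, r_i] == t)
      if (length(hit) == 0) stop("no lineage for taxon ", t, " at rank ", r)
      pathv <- lin_mat[hit[1], seq_len(r_i)]
      rows <- c(rows, paste(t, r, paste(pathv, collapse = "|"),
                            paste(pathv, collapse = "|"),
                            format(ab[[t]] * 100, digits = 12, trim = TRUE),
                            sep = "\t"))
    }
  }
  writeLines(c(paste0("@SampleID:", sample_id),
               "@Version:0.9.1",
               paste0("@Ranks:", paste(tax_ranks(), collapse = "|")),
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
               rows), path)
  invisible(path)
}

#' Read a CAMI (Bioboxes) profiling file
#'
#' @param path Input file.
#' @return List with `sample_id`, `profiles_by_rank` (named list rank ->
#'   named abundance fractions; no unassigned key), and `lineages` (named
#'   list taxon-at-deepest-rank -> [tax_lineage()]).
#' @export
read_cami_profile <- function(path) {
  lines <- readLines(path)
  sample_id <- sub("^@SampleID:", "", grep("^@SampleID:", lines, value = TRUE)[1])
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  profiles <- setNames(vector("list", 7), tax_ranks())
  lineages <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    taxid <- f[1]; rank <- f[2]; taxpath <- f[3]; pct <- as.numeric(f[5])
    profiles[[rank]] <- c(profiles[[rank]], setNames(pct / 100, taxid))
    pathv <- strsplit(taxpath, "|", fixed = TRUE)[[1]]
    lineages[[taxid]] <- tax_lineage(pathv)
  }
  list(sample_id = sample_id, profiles_by_rank = profiles, lineages = lineages)
}
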