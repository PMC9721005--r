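## On-disk database layout (original to this package; the released mOTUs
## database layout is not documented in the literature we follow):
##   <dir>/VERSION        key=value: version, prefilter_id, min_families
##   <dir>/entries.tsv    motu_id, category, genomes (comma-joined)
##   <dir>/cutoffs.tsv    family, cutoff
##   <dir>/taxonomy.tsv   motu_id, 7 rank columns, 7 consistency columns
##   <dir>/<family>.fna   per-family FASTA, headers "motu_id|seq_id|family"

#' Write a database to a directory
#'
#' @param db An [mg_database()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  stopifnot(inherits(db, "mg_database"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(paste0("version=", db$version),
               paste0("prefilter_id=", format(db$prefilter_id, digits = 15)),
               paste0("min_families=", db$min_families)),
             file.path(dir, "VERSION"))
  ids <- names(db$entries)
  entries <- data.frame(
    motu_id = ids,
    category = vapply(db$entries, function(e) e$category, character(1)),
    genomes = vapply(db$entries, function(e) paste(e$genomes, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  write.table(entries, file.path(dir, "entries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(family = names(db$cutoffs),
                         cutoff = format(db$cutoffs, digits = 15)),
              file.path(dir, "cutoffs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tax <- do.call(rbind, lapply(db$entries, function(e) {
    data.frame(motu_id = e$motu_id,
               t(ifelse(is.na(e$taxonomy), "NA", unclass(e$taxonomy))),
               t(e$consistency), stringsAsFactors = FALSE)
  }))
  colnames(tax) <- c("motu_id", tax_ranks(),
                     paste0("consistency_", tax_ranks()))
  write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (f in mg_families()) {
    seqs <- unlist(lapply(unname(db$entries), function(e) {
      s <- e$sequences[[f]]
      if (is.null(s)) return(NULL)
      setNames(s, paste(e$motu_id, names(s), f, sep = "|"))
    }))
    if (length(seqs) > 0) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                  file.path(dir, paste0(f, ".fna")))
    }
  }
  invisible(dir)
}

#' Read a database directory written by [write_db()]
#'
#' @param dir Database directory.
#' @return An [mg_database()].
#' @export
read_db <- function(dir) {
  meta <- readLines(file.path(dir, "VERSION"))
  getm <- function(key) sub(paste0("^", key, "="), "",
                            grep(paste0("^", key, "="), meta, value = TRUE)[1])
  entries_df <- read.delim(file.path(dir, "entries.tsv"),
                           stringsAsFactors = FALSE, colClasses = "character")
  cut_df <- read.delim(file.path(dir, "cutoffs.tsv"), stringsAsFactors = FALSE)
  tax_df <- read.delim(file.path(dir, "taxonomy.tsv"),
                       stringsAsFactors = FALSE, colClasses = "character")
  seqs <- list()
  for (f in mg_families()) {
    p <- file.path(dir, paste0(f, ".fna"))
    if (!file.exists(p)) next
    x <- Biostrings::readDNAStringSet(p)
    parts <- strsplit(sub("\\s.*$", "", names(x)), "|", fixed = TRUE)
    seqs[[f]] <- data.frame(
      motu_id = vapply(parts, `[`, character(1), 1),
      seq_id = vapply(parts, `[`, character(1), 2),
      seq = as.character(x), stringsAsFactors = FALSE
    )
  }
  entries <- list()
  for (i in seq_len(nrow(entries_df))) {
    id <- entries_df$motu_id[i]
    genomes <- entries_df$genomes[i]
    genomes <- if (is.na(genomes) || genomes == "") character(0)
               else strsplit(genomes, ",", fixed = TRUE)[[1]]
    sq <- list()
    for (f in names(seqs)) {
      rows <- seqs[[f]][seqs[[f]]$motu_id == id, , drop = FALSE]
      if (nrow(rows) > 0) sq[[f]] <- setNames(rows$seq, rows$seq_id)
    }
    ti <- match(id, tax_df$motu_id)
    lin <- tax_lineage()
    cons <- NULL
    if (!is.na(ti)) {
      lin <- tax_lineage(unlist(tax_df[ti, tax_ranks()]))
      cons <- setNames(unlist(tax_df[ti, paste0("consistency_", tax_ranks())]),
                       tax_ranks())
    }
    entries[[id]] <- motu_entry(id, entries_df$category[i], genomes, sq,
                                lin, cons)
  }
  mg_database(entries,
              cutoffs = setNames(as.numeric(cut_df$cutoff), cut_df$family),
              prefilter_id = as.numeric(getm("prefilter_id")),
              min_families = as.integer(getm("min_families")),
              version = getm("version"))
}
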