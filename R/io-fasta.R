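## FASTA I/O for marker genes and reads, via Biostrings.
## Marker gene header grammar: "genome_id|family" (family one of the ten
## labels from mg_families()).

#' Read per-genome marker genes from FASTA
#'
#' Headers must follow the grammar `genome_id|family`.  Sequences are
#' grouped by genome and families validated against [mg_families()].
#' Duplicate (genome, family) pairs violate the single-copy contract and
#' are handled per `dup_policy`.
#'
#' @param path FASTA file.
#' @param dup_policy `"error"` (default), `"longest"` (keep the longer
#'   sequence), or `"drop_genome"` (discard the offending genome).
#' @return Named list of [genome_mg_set()] objects.
#' @export
read_mg_fasta <- function(path, dup_policy = c("error", "longest", "drop_genome")) {
  dup_policy <- match.arg(dup_policy)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no sequences in ", path)
  hdr <- sub("\\s.*$", "", names(x))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed header (expected 'genome_id|family'): ", hdr[which(bad)[1]])
  }
  genome <- vapply(parts, `[`, character(1), 1)
  fam <- vapply(parts, `[`, character(1), 2)
  .check_family(fam)
  seqs <- toupper(as.character(x))
  drop_genomes <- character(0)
  key <- paste(genome, fam, sep = "|")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    if (dup_policy == "error") {
      stop("duplicate (genome, family) pair: ", dup_keys[1],
           " (set dup_policy to resolve)")
    }
    if (dup_policy == "drop_genome") {
      drop_genomes <- unique(sub("\\|.*$", "", dup_keys))
    } else {
      ## keep the longest sequence per (genome, family)
      ord <- order(key, -nchar(seqs))
      keep <- ord[!duplicated(key[ord])]
      keep <- sort(keep)
      genome <- genome[keep]; fam <- fam[keep]; seqs <- seqs[keep]
    }
  }
  out <- list()
  for (g in setdiff(unique(genome), drop_genomes)) {
    i <- which(genome == g)
    out[[g]] <- genome_mg_set(g, setNames(seqs[i], fam[i]))
  }
  out
}

#' Write marker gene sets to FASTA
#'
#' @param sets List of [genome_mg_set()] objects.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_mg_fasta <- function(sets, path) {
  seqs <- unlist(lapply(unname(sets), function(g) {
    setNames(g$members, paste(g$genome_id, names(g$members), sep = "|"))
  }))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read simulated or sequenced reads
#'
#' @param path FASTA or FASTQ file (format detected from the extension;
#'   `.fastq`/`.fq` is read as FASTQ).
#' @return data.frame with columns `insert_id`, `seq`.  Paired mates should
#'   share an `insert_id` (read via two files and [rbind()]).
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(insert_id = sub("\\s.*$", "", names(x)),
             seq = toupper(as.character(x)), stringsAsFactors = FALSE)
}

#' Write reads to FASTA
#'
#' @param reads data.frame with `insert_id`, `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$insert_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
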