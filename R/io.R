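# Readers/writers for the formats every other module touches. All
# downstream code consumes the containers built here (sequence-record
# data frames, read sets, metadata tables), never raw files.
# Coordinates everywhere in the package are 0-based, half-open; strand is
# encoded as "+"/"-".

#' Construct a sequence-record table
#'
#' The atom of every search stage: a data frame with one row per sequence
#' and columns `id`, `seq`, `alphabet` (`"protein"` or `"dna"`) and a
#' free-text `source` provenance tag. Sequences are uppercased; ids must
#' be unique and non-empty, sequences non-empty, and DNA restricted to
#' `A,C,G,T,N`.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of residue strings.
#' @param alphabet `"protein"` or `"dna"` (recycled).
#' @param source provenance tag (recycled).
#' @return a `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, seq, alphabet = c("protein", "dna"),
                        source = "") {
  alphabet <- match.arg(alphabet)
  x <- data.frame(id = as.character(id),
                  seq = toupper(as.character(seq)),
                  alphabet = alphabet,
                  source = source,
                  stringsAsFactors = FALSE)
  validate_seq_records(x)
  class(x) <- c("seq_records", "data.frame")
  x
}

validate_seq_records <- function(x) {
  if (any(is.na(x$id) | x$id == ""))
    stop("sequence ids must be non-empty")
  dup <- x$id[duplicated(x$id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(nchar(x$seq) == 0))
    stop("empty sequence for id(s): ",
         paste(x$id[nchar(x$seq) == 0], collapse = ", "))
  is_dna <- x$alphabet == "dna"
  if (any(is_dna)) {
    bad <- grepl("[^ACGTN]", x$seq[is_dna])
    if (any(bad))
      stop("non-ACGTN characters in dna record(s): ",
           paste(x$id[is_dna][bad], collapse = ", "))
  }
  invisible(x)
}

#' Read a FASTA file into a sequence-record table
#'
#' @param path file path.
#' @param alphabet `"protein"` or `"dna"`.
#' @param source provenance tag stored on every record (defaults to the
#'   file name).
#' @return a [seq_records] table.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       source = basename(path)) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) fasta_parse_error(path, e))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty)) {
    ln <- fasta_header_line(path, names(set)[empty[1]])
    stop(sprintf("empty sequence for record '%s' (line %d) in %s",
                 ids[empty[1]], ln, path))
  }
  if (any(ids == ""))
    stop("malformed (empty) FASTA header in ", path)
  seq_records(ids, seqs, alphabet, source)
}

fasta_parse_error <- function(path, e) {
  # locate the first structurally bad line for the error message
  lines <- readLines(path, warn = FALSE)
  bad <- which(!grepl("^>", lines) & seq_along(lines) == 1)
  ln <- if (length(bad)) bad[1] else 1L
  stop(sprintf("malformed FASTA at %s (near line %d): %s",
               path, ln, conditionMessage(e)))
}

fasta_header_line <- function(path, header) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(lines == paste0(">", header))
  if (length(hit)) hit[1] else 1L
}

#' Write a sequence-record table as FASTA
#'
#' @param records a [seq_records] table.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  validate_seq_records(records)
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a read set
#'
#' @param path file path.
#' @param sample_id sample label (defaults to the file name).
#' @param modality `"metagenome"` or `"metatranscriptome"`.
#' @return a `read_set`: list with `sample_id`, `reads` (data frame with
#'   `id`, `seq`, `qual`), `modality` and `total_reads` (the pre-filtering
#'   read count).
#' @export
read_fastq <- function(path, sample_id = basename(path),
                       modality = c("metagenome", "metatranscriptome")) {
  modality <- match.arg(modality)
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  reads <- data.frame(id = sub("\\s.*$", "", names(set)),
                      seq = as.character(set),
                      qual = as.character(S4Vectors::mcols(set)$qualities),
                      stringsAsFactors = FALSE)
  read_set(sample_id, reads, modality)
}

#' @rdname read_fastq
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @export
read_set <- function(sample_id, reads,
                     modality = c("metagenome", "metatranscriptome")) {
  modality <- match.arg(modality)
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch in read set ", sample_id)
  structure(list(sample_id = sample_id, reads = reads, modality = modality,
                 total_reads = nrow(reads)),
            class = "read_set")
}

#' Write a read set as FASTQ (Phred+33)
#' @param rs a `read_set`.
#' @param path output path.
#' @export
write_fastq <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(rs$reads))
    writeLines(paste0("@", rs$reads$id, "\n", rs$reads$seq, "\n+\n",
                      rs$reads$qual), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with a header containing at least `sample_id` and
#' `group`; optional bile-acid concentration columns `CA`, `CDCA`, `DCA`,
#' `LCA` (all must be non-negative when present). Missing concentration
#' columns stay absent rather than being filled with zeros.
#'
#' @param path file path.
#' @return a `data.frame` with one row per sample.
#' @export
read_metadata_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(x)
}

validate_metadata <- function(x) {
  if (!"sample_id" %in% names(x)) stop("metadata lacks a sample_id column")
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  for (ba in intersect(c("CA", "CDCA", "DCA", "LCA"), names(x))) {
    v <- x[[ba]]
    if (any(!is.na(v) & v < 0))
      stop("negative ", ba, " concentration for sample(s): ",
           paste(x$sample_id[!is.na(v) & v < 0], collapse = ", "))
  }
  x
}

#' @rdname read_metadata_table
#' @param meta metadata data frame.
#' @export
write_metadata_table <- function(meta, path) {
  validate_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Newick serialization for phylogenetic trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that add
#' the structural checks the pipeline relies on (non-empty tree, branch
#' lengths present).
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return `write_newick`: a single Newick string. `read_newick`: a
#'   `phylo` object.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0)
    stop("not a valid tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  ape::write.tree(tree)
}

#' @rdname write_newick
#' @param text a Newick string.
#' @export
read_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("unparseable Newick string")
  tr
}

#' Read a YAML run-configuration file
#' @param path YAML file path.
#' @return a named list; see [default_config()] for the recognized keys.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}
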