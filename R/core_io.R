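#' Construct a set of sequencing reads
#'
#' Reads are stored as a data frame with one row per read and columns `id`,
#' `seq` (uppercase ACGTN), `qual` (phred+33 encoded string, same length as
#' `seq`) and `mate` (one of `"R1"`, `"R2"`, `"merged"`, `"single"`).
#' Constructing an object that violates these invariants fails immediately.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences over A, C, G, T, N.
#' @param qual phred+33 quality strings, same lengths as `seq`, phred 0-60.
#' @param mate mate label, recycled; one of R1, R2, merged, single.
#' @return A `venom_reads` data frame.
#' @examples
#' new_reads("r1", "ACGT", "IIII")
#' @export
new_reads <- function(id, seq, qual, mate = "single") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  qual <- as.character(qual)
  if (length(seq) != length(id) || length(qual) != length(id)) {
    stop("id, seq and qual must have equal lengths")
  }
  mate <- rep_len(as.character(mate), length(id))
  x <- data.frame(id = id, seq = seq, qual = qual, mate = mate)
  class(x) <- c("venom_reads", "data.frame")
  validate_reads(x)
}

#' @rdname new_reads
#' @param x a `venom_reads` object to validate.
#' @export
validate_reads <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "seq", "qual", "mate") %in% names(x)))
  if (any(nchar(x$seq) == 0)) stop("reads must have non-empty sequences")
  if (any(nchar(x$seq) != nchar(x$qual))) {
    bad <- which(nchar(x$seq) != nchar(x$qual))[1]
    stop("read ", bad, " ('", x$id[bad], "'): sequence and quality lengths differ")
  }
  if (any(grepl("[^ACGTN]", x$seq))) {
    bad <- which(grepl("[^ACGTN]", x$seq))[1]
    stop("read ", bad, " ('", x$id[bad], "'): sequence contains characters outside ACGTN")
  }
  bad_mate <- !x$mate %in% c("R1", "R2", "merged", "single")
  if (any(bad_mate)) stop("invalid mate label: ", x$mate[which(bad_mate)[1]])
  if (nrow(x) > 0) {
    qr <- range(utf8ToInt(paste(x$qual, collapse = ""))) - 33L
    if (qr[1] < 0 || qr[2] > 60) {
      stop("phred qualities must lie in [0, 60] (phred+33 encoding)")
    }
  }
  x
}

#' Decode per-base phred qualities
#'
#' @param reads a `venom_reads` object.
#' @return A list of integer vectors, one per read.
#' @export
read_qualities <- function(reads) {
  lapply(reads$qual, function(q) utf8ToInt(q) - 33L)
}

#' Reverse complement
#'
#' @param seq character vector of ACGTN sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  cpp_revcomp(toupper(as.character(seq)))
}

#' Read a FASTQ file (phred+33)
#'
#' Strict 4-line-per-record parser. Malformed input (record count not a
#' multiple of four, missing `@`/`+` markers, sequence/quality length
#' mismatch) raises an error naming the offending record.
#'
#' @param path path to a FASTQ file (plain or gzipped).
#' @param mate mate label to assign (default `"single"`).
#' @return A `venom_reads` data frame.
#' @export
read_fastq <- function(path, mate = "single") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(new_reads(character(), character(), character(), character()))
  }
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (after record ", length(lines) %/% 4, ")")
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": separator line does not start with '+'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1],
         ": sequence and quality lengths differ (", nchar(seq[bad[1]]),
         " vs ", nchar(qual[bad[1]]), ")")
  }
  id <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[`, character(1), 1))
  new_reads(id, seq, qual, mate)
}

#' Write reads to a FASTQ file (phred+33)
#'
#' @param reads a `venom_reads` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings with the toolkit's alphabet contract:
#' sequences are uppercased and any character outside A, C, G, T, N is an
#' error. `read_fasta(write_fasta(x))` round-trips ids and sequences
#' exactly (up to line wrapping).
#'
#' @param path path to a FASTA file.
#' @return `read_fasta`: a data frame with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  seq <- toupper(as.character(ss))
  bad <- which(grepl("[^ACGTN]", seq))
  if (length(bad)) {
    stop("FASTA record ", bad[1], " ('", names(ss)[bad[1]],
         "'): characters outside ACGTN")
  }
  id <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1)
  data.frame(id = id, seq = unname(seq))
}

#' @rdname read_fasta
#' @param records a data frame with columns `id` and `seq` (a `venom_contigs`
#'   object works as-is, its `seq` column is used).
#' @param width line-wrap width.
#' @return `write_fasta`: `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (any(grepl("[^ACGTN]", toupper(records$seq)))) {
    stop("sequences contain characters outside ACGTN")
  }
  ss <- Biostrings::DNAStringSet(toupper(records$seq))
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct assembled contigs
#'
#' @param id,seq contig identifiers and sequences (ACGT).
#' @param source_method assembler label.
#' @param seed_id optional originating seed read id.
#' @param replicate_support optional non-negative replicate support count.
#' @return A `venom_contigs` data frame.
#' @export
new_contigs <- function(id, seq, source_method = "extender",
                        seed_id = NA_character_, replicate_support = NA_integer_) {
  seq <- toupper(as.character(seq))
  if (any(nchar(seq) == 0)) stop("contigs must have non-empty sequences")
  if (any(grepl("[^ACGT]", seq))) stop("contig sequences must be over ACGT")
  rs <- as.integer(replicate_support)
  if (any(!is.na(rs) & rs < 0)) stop("replicate_support must be >= 0")
  x <- data.frame(id = as.character(id), seq = seq,
                  source_method = rep_len(as.character(source_method), length(seq)),
                  seed_id = rep_len(as.character(seed_id), length(seq)),
                  replicate_support = rep_len(rs, length(seq)))
  class(x) <- c("venom_contigs", "data.frame")
  x
}

#' Curated toxin reference
#'
#' A toxin reference is a set of coding sequences with unique names and
#' non-empty family labels, e.g. the SVMP/SVSP/CTL repertoires used to
#' annotate snake venom-gland assemblies. The FASTA header dialect is
#' `>NAME family=FAMILY`.
#'
#' @param name unique entry names (e.g. `"SVMP-2"`).
#' @param family family labels (e.g. `"SVMP"`).
#' @param cds coding sequences over ACGT (partial CDS permitted).
#' @return A `toxin_reference` data frame with columns name, family, cds.
#' @export
toxin_reference <- function(name, family, cds) {
  name <- as.character(name)
  family <- as.character(family)
  cds <- toupper(as.character(cds))
  if (anyDuplicated(name)) stop("toxin reference names must be unique")
  if (any(!nzchar(family))) stop("toxin reference families must be non-empty")
  if (any(nchar(cds) == 0) || any(grepl("[^ACGT]", cds))) {
    stop("reference coding sequences must be non-empty and over ACGT")
  }
  x <- data.frame(name = name, family = family, cds = cds)
  class(x) <- c("toxin_reference", "data.frame")
  x
}

#' @rdname toxin_reference
#' @param path path to a reference FASTA with `>NAME family=FAMILY` headers.
#' @export
read_toxin_reference <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  name <- vapply(strsplit(hdr, "[ \t]"), `[`, character(1), 1)
  fam <- rep(NA_character_, length(hdr))
  m <- regmatches(hdr, regexpr("family=[^ \t]+", hdr))
  has <- grepl("family=", hdr)
  if (!all(has)) {
    stop("reference record ", which(!has)[1], ": missing 'family=' tag")
  }
  fam[has] <- sub("^family=", "", m)
  toxin_reference(name, fam, as.character(ss))
}

#' @rdname toxin_reference
#' @param ref a `toxin_reference` object.
#' @export
write_toxin_reference <- function(ref, path) {
  stopifnot(inherits(ref, "toxin_reference"))
  ss <- Biostrings::DNAStringSet(ref$cds)
  names(ss) <- paste0(ref$name, " family=", ref$family)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
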