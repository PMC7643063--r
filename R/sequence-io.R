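#' Read genome sequences from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped, mixed-case) FASTA file,
#' uppercases soft-masked bases, removes every symbol outside
#' \code{A,C,G,T} (Ns, IUPAC ambiguity codes, gaps) and returns one
#' [GenomeRecord-class] per record with the number of dropped symbols logged.
#'
#' @param path path to a FASTA file.
#' @return a list of [GenomeRecord-class] objects, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgT", ">y", "ACNNGT"), fa)
#' recs <- readGenomeFasta(fa)
#' genomeSeq(recs[[2]])   # "ACGT", two Ns dropped
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    raw <- toupper(as.character(set[[i]]))
    out[[i]] <- cleanGenomeRecord(ids[i], raw)
  }
  out
}

#' Build a GenomeRecord from a raw sequence string
#'
#' @param id record identifier.
#' @param seq raw sequence; lowercase is uppercased, non-ACGT removed.
#' @return a [GenomeRecord-class].
#' @export
cleanGenomeRecord <- function(id, seq) {
  raw <- toupper(seq)
  clean <- gsub("[^ACGT]", "", raw)
  if (nchar(clean) == 0L)
    stop("record '", id, "' is empty after removing non-ACGT symbols")
  new("GenomeRecord", id = id, seq = clean,
      G = nchar(clean), nDropped = nchar(raw) - nchar(clean))
}

#' Concatenate the records of one genome file into a single record
#'
#' Multi-replicon genomes (chromosome plus plasmids) are concatenated in file
#' order; the combined record keeps the first record's id unless \code{id} is
#' given.
#'
#' @param records list of [GenomeRecord-class] from one genome.
#' @param id optional identifier for the combined record.
#' @return a single [GenomeRecord-class].
#' @export
concatGenomeRecords <- function(records, id = NULL) {
  stopifnot(length(records) >= 1L)
  if (is.null(id)) id <- records[[1L]]@id
  new("GenomeRecord", id = id,
      seq = paste(vapply(records, genomeSeq, character(1)), collapse = ""),
      G = sum(vapply(records, genomeLength, integer(1))),
      nDropped = sum(vapply(records, function(r) r@nDropped, integer(1))))
}

#' Recode DNA into a binary alphabet
#'
#' Maps the four nucleotides onto two-letter alphabets: \code{SW} groups the
#' strong pair C,G as S against the weak pair A,T as W; \code{RY} groups the
#' purines A,G as R against the pyrimidines C,T as Y; \code{KM} groups A,C as
#' K against G,T as M.
#'
#' @param seq character scalar over \code{A,C,G,T}.
#' @param scheme one of \code{"SW"}, \code{"RY"}, \code{"KM"}.
#' @return character scalar of the same length over the binary alphabet.
#' @examples
#' recodeSequence("ACGT", "SW")  # "WSSW"
#' @export
recodeSequence <- function(seq, scheme = c("SW", "RY", "KM")) {
  scheme <- match.arg(scheme)
  if (grepl("[^ACGT]", seq)) stop("sequence must be over {A,C,G,T}")
  switch(scheme,
    SW = chartr("ACGT", "WSSW", seq),
    RY = chartr("ACGT", "RYRY", seq),
    KM = chartr("ACGT", "KKMM", seq))
}

binaryAlphabet <- function(scheme) {
  switch(scheme,
    SW = c("S", "W"), RY = c("R", "Y"), KM = c("K", "M"),
    stop("unknown scheme: ", scheme))
}

#' Symbol composition of a sequence
#'
#' @param seq non-empty character scalar.
#' @param alphabet symbol set; defaults to \code{A,C,G,T}.
#' @return named numeric vector of relative frequencies summing to 1.
#' @examples
#' composition("GGCC")  # GC fraction 1
#' @export
composition <- function(seq, alphabet = DNA_ALPHABET) {
  if (!nzchar(seq)) stop("empty sequence")
  sym <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(sym), alphabet)
  if (length(bad))
    stop("symbols outside alphabet: ", paste(bad, collapse = ","))
  cnt <- vapply(alphabet, function(a) sum(sym == a), numeric(1))
  cnt / length(sym)
}

#' %GC of a genome record
#'
#' @param record a [GenomeRecord-class].
#' @return GC percentage in \code{[0, 100]}.
#' @export
percentGC <- function(record) {
  f <- composition(genomeSeq(record))
  100 * (f[["C"]] + f[["G"]])
}

#' Write a sequence-cleaning report
#'
#' One TSV row per record: id, original length, cleaned length G, dropped
#' symbol count.
#'
#' @param records list of [GenomeRecord-class].
#' @param path output TSV path.
#' @return invisibly, the report data.frame.
#' @export
writeCleaningReport <- function(records, path) {
  rep <- data.frame(
    id = vapply(records, function(r) r@id, character(1)),
    original_length = vapply(records, function(r) r@G + r@nDropped, integer(1)),
    G = vapply(records, genomeLength, integer(1)),
    n_dropped = vapply(records, function(r) r@nDropped, integer(1)))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Reverse complement of a genome record
#'
#' @param record a [GenomeRecord-class].
#' @return a [GenomeRecord-class] with the reverse-complemented sequence.
#' @export
reverseComplement <- function(record) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genomeSeq(record))))
  new("GenomeRecord", id = record@id, seq = rc, G = record@G,
      nDropped = record@nDropped)
}
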