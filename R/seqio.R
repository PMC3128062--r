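# FASTA input and symbol filtering. Modeling runs on the retained A/C/G/T
# stream only; original coordinates are kept so profiles can be reported in
# the coordinates of the unfiltered sequence.

DNA_LETTERS <- c("A", "C", "G", "T")

#' Read a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file and returns the raw sequence
#' text of each record with line wrapping removed and case preserved.
#' Non-ACGT symbols are kept; use [filter_sequence()] to map to symbol codes.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, names taken from
#'   the header lines (first whitespace-delimited word retained in full).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "AC", "GT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop("input-format error: empty FASTA file: ", path)
  if (!startsWith(trimws(first), ">"))
    stop("input-format error: file does not start with a FASTA header: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("input-format error: no FASTA records in ", path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Map sequence text to a filtered 2-bit symbol stream
#'
#' Folds case, maps A/C/G/T to the symbol codes 0/1/2/3 and drops every other
#' character (N runs, IUPAC ambiguity codes, gaps) while recording the 1-based
#' original coordinate of each retained base. The dropped positions are not
#' modeled and are not represented in encoded bitstreams.
#'
#' @param raw A single character string of sequence text.
#' @param record_id Identifier carried along with the stream.
#' @return A `FilteredSequence`: list with `record_id`, `codes` (integer
#'   vector in 0..3), `positions` (1-based original coordinates, strictly
#'   increasing) and `original_length`.
#' @examples
#' filter_sequence("ANNGt")
#' @export
filter_sequence <- function(raw, record_id = "") {
  stopifnot(is.character(raw), length(raw) == 1L)
  bytes <- charToRaw(raw)
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  lut[as.integer(charToRaw("acgt")) + 1L] <- 0:3
  codes <- lut[as.integer(bytes) + 1L]
  keep <- !is.na(codes)
  structure(
    list(record_id = as.character(record_id),
         codes = codes[keep],
         positions = which(keep),
         original_length = length(bytes)),
    class = "FilteredSequence")
}

#' @export
print.FilteredSequence <- function(x, ...) {
  cat(sprintf("FilteredSequence '%s': %d retained bases of %d original\n",
              x$record_id, length(x$codes), x$original_length))
  invisible(x)
}

#' Convert symbol codes back to DNA letters
#'
#' @param codes Integer vector with values in 0..3 (A, C, G, T).
#' @return A single character string.
#' @export
codes_to_dna <- function(codes) {
  stopifnot(all(codes %in% 0:3))
  paste(DNA_LETTERS[codes + 1L], collapse = "")
}

#' Convert a DNA string to symbol codes
#'
#' Strict counterpart of [filter_sequence()]: every character must be one of
#' A/C/G/T (either case).
#'
#' @param dna A single character string.
#' @return Integer vector of codes in 0..3.
#' @export
dna_to_codes <- function(dna) {
  fs <- filter_sequence(dna)
  if (length(fs$codes) != nchar(dna))
    stop("sequence contains non-ACGT characters")
  fs$codes
}

#' Write records to a FASTA file
#'
#' @param seqs Named character vector of sequence text.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# internal: coerce user input (FilteredSequence / character / codes) to a
# FilteredSequence
as_filtered <- function(x, record_id = "seq") {
  if (inherits(x, "FilteredSequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(filter_sequence(x, record_id))
  if (is.numeric(x)) {
    codes <- as.integer(x)
    stopifnot(all(codes %in% 0:3))
    return(structure(list(record_id = record_id, codes = codes,
                          positions = seq_along(codes),
                          original_length = length(codes)),
                     class = "FilteredSequence"))
  }
  stop("cannot interpret input as a DNA symbol stream")
}
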