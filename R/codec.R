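# Arithmetic-coded container format. The coder is driven by the same count
# tables as the competition engine: per block, the depth index is coded with
# the adaptive side model, then the block's symbols with the winning model.
# Probabilities are quantised deterministically to 16-bit frequencies, so the
# actual stream exceeds the ideal (-log2 p) total only by the quantisation
# redundancy plus coder flush (a few bits per record).

CONTAINER_MAGIC <- charToRaw("DFCM")
CONTAINER_VERSION <- 1L

write_one <- function(con, what, size = NA_integer_) {
  writeBin(what, con, size = size, endian = "little")
}

serialize_container <- function(cfg, records) {
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  write_one(con, CONTAINER_MAGIC)
  write_one(con, as.integer(CONTAINER_VERSION), size = 1L)
  write_one(con, length(cfg$depths), size = 1L)
  write_one(con, cfg$depths, size = 1L)
  write_one(con, cfg$block_size, size = 4L)
  write_one(con, c(cfg$alpha_low, cfg$alpha_high, cfg$side_alpha))
  write_one(con, c(cfg$alpha_threshold, cfg$side_order, cfg$hash_threshold), size = 4L)
  write_one(con, as.integer(cfg$use_ir), size = 1L)
  write_one(con, length(records), size = 4L)
  for (rec in records) {
    id <- charToRaw(rec$record_id)
    write_one(con, length(id), size = 4L)
    write_one(con, id)
    write_one(con, as.numeric(rec$n_symbols))
    write_one(con, as.numeric(rec$payload_bits))
    write_one(con, length(rec$payload), size = 4L)
    write_one(con, rec$payload)
    write_one(con, cpp_fnv1a(rec$payload))
  }
  rawConnectionValue(con)
}

read_exact <- function(con, what, n, size = NA_integer_) {
  out <- readBin(con, what, n = n, size = size, endian = "little",
                 signed = !(identical(what, integer()) && identical(size, 1L)))
  if ((identical(what, raw()) && length(out) != n) ||
      (!identical(what, raw()) && length(out) != n))
    stop("corrupted or truncated container: unexpected end of data")
  out
}

deserialize_container <- function(bytes) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  magic <- read_exact(con, raw(), 4L)
  if (!identical(magic, CONTAINER_MAGIC))
    stop("not a dnafcm container (bad magic bytes)")
  version <- read_exact(con, integer(), 1L, size = 1L)
  if (version != CONTAINER_VERSION)
    stop("container version mismatch: got ", version,
         ", this build reads version ", CONTAINER_VERSION)
  nd <- read_exact(con, integer(), 1L, size = 1L)
  depths <- read_exact(con, integer(), nd, size = 1L)
  block_size <- read_exact(con, integer(), 1L, size = 4L)
  a <- read_exact(con, numeric(), 3L)
  ints <- read_exact(con, integer(), 3L, size = 4L)
  use_ir <- read_exact(con, integer(), 1L, size = 1L)
  cfg <- competition_config(depths = depths, block_size = block_size,
                            alpha_low = a[1], alpha_high = a[2],
                            alpha_threshold = ints[1], side_order = ints[2],
                            side_alpha = a[3], use_ir = use_ir == 1L,
                            hash_threshold = ints[3])
  nrec <- read_exact(con, integer(), 1L, size = 4L)
  records <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    idlen <- read_exact(con, integer(), 1L, size = 4L)
    id <- rawToChar(read_exact(con, raw(), idlen))
    n_symbols <- read_exact(con, numeric(), 1L)
    payload_bits <- read_exact(con, numeric(), 1L)
    plen <- read_exact(con, integer(), 1L, size = 4L)
    payload <- read_exact(con, raw(), plen)
    checksum <- read_exact(con, numeric(), 1L)
    if (!isTRUE(all.equal(checksum, cpp_fnv1a(payload))))
      stop("corrupted container: payload checksum mismatch for record '", id, "'")
    records[[i]] <- list(record_id = id, n_symbols = n_symbols,
                         payload_bits = payload_bits, payload = payload)
  }
  if (length(readBin(con, raw(), 1L)) != 0L)
    stop("corrupted container: trailing bytes after last record")
  list(cfg = cfg, records = records)
}

#' Encode sequences into an arithmetic-coded container
#'
#' Runs the competition engine and drives an adaptive arithmetic coder with
#' its probability estimates. Models are reset at each record boundary. Only
#' the retained A/C/G/T stream is coded; non-ACGT symbols are not represented
#' (see [filter_sequence()]).
#'
#' @param x Input sequences: a `FilteredSequence`, a list of them, a named
#'   character vector of DNA strings, or the path of a FASTA file.
#' @param cfg A [competition_config()].
#' @param file Optional output path; the raw container is written there.
#' @return A `BitstreamContainer`: list with `raw` (the serialized bytes),
#'   `cfg`, and a per-record summary data frame (`records`) holding
#'   `n_symbols`, ideal `symbol_bits` and `side_bits`, and actual
#'   `payload_bits`.
#' @seealso [fcm_decode()]
#' @export
fcm_encode <- function(x, cfg = competition_config(), file = NULL) {
  seqs <- as_filtered_list(x)
  alphas <- alpha_for_depth(cfg$depths, cfg)
  recs <- lapply(seqs, function(fs) {
    r <- cpp_encode(fs$codes, cfg$depths, alphas, cfg$block_size,
                    cfg$side_order, cfg$side_alpha, cfg$use_ir,
                    cfg$hash_threshold)
    list(record_id = fs$record_id, n_symbols = length(fs$codes),
         payload_bits = r$payload_bits, payload = r$payload,
         symbol_bits = r$symbol_bits, side_bits = r$side_bits)
  })
  bytes <- serialize_container(cfg, recs)
  if (!is.null(file)) {
    ok <- FALSE
    tryCatch({
      writeBin(bytes, file)
      ok <- TRUE
    }, finally = if (!ok && file.exists(file)) unlink(file))
  }
  summary <- data.frame(
    record_id = vapply(recs, `[[`, "", "record_id"),
    n_symbols = vapply(recs, `[[`, 0, "n_symbols"),
    symbol_bits = vapply(recs, `[[`, 0, "symbol_bits"),
    side_bits = vapply(recs, `[[`, 0, "side_bits"),
    payload_bits = vapply(recs, `[[`, 0, "payload_bits"))
  structure(list(raw = bytes, cfg = cfg, records = summary),
            class = "BitstreamContainer")
}

#' @export
print.BitstreamContainer <- function(x, ...) {
  n <- sum(x$records$n_symbols)
  bits <- sum(x$records$payload_bits)
  cat(sprintf("BitstreamContainer: %d record(s), %d bases, %d container bytes (%.4f payload bpb)\n",
              nrow(x$records), n, length(x$raw), if (n > 0) bits / n else 0))
  invisible(x)
}

#' Decode an arithmetic-coded container
#'
#' Mirrors the encoder exactly: same warm-up contexts, same count updates,
#' same side model. Corruption is detected by a per-record checksum before
#' decoding starts.
#'
#' @param x A `BitstreamContainer`, a raw vector, or the path of a container
#'   file written by [fcm_encode()].
#' @return A list of `FilteredSequence` objects (codes only; positions are
#'   `1..n`), with the recovered [competition_config()] attached as attribute
#'   `"cfg"`.
#' @export
fcm_decode <- function(x) {
  bytes <- if (inherits(x, "BitstreamContainer")) x$raw
           else if (is.raw(x)) x
           else readBin(x, raw(), n = file.size(x))
  parsed <- deserialize_container(bytes)
  cfg <- parsed$cfg
  alphas <- alpha_for_depth(cfg$depths, cfg)
  out <- lapply(parsed$records, function(rec) {
    codes <- cpp_decode(rec$payload, rec$n_symbols, cfg$depths, alphas,
                        cfg$block_size, cfg$side_order, cfg$side_alpha,
                        cfg$use_ir, cfg$hash_threshold)
    as_filtered(codes, record_id = rec$record_id)
  })
  names(out) <- vapply(parsed$records, `[[`, "", "record_id")
  attr(out, "cfg") <- cfg
  out
}

as_filtered_list <- function(x) {
  if (inherits(x, "FilteredSequence")) return(list(x))
  if (is.list(x)) return(lapply(x, as_filtered))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    raws <- read_fasta(x)
    return(mapply(filter_sequence, raws, names(raws), SIMPLIFY = FALSE))
  }
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    return(mapply(filter_sequence, x, ids, SIMPLIFY = FALSE))
  }
  list(as_filtered(x))
}
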