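#' Read FASTQ records into a tibble
#'
#' Parses single-end reads from a 4-line FASTQ file, plain or
#' gzip-compressed (compression is detected from the magic bytes, not the
#' file name). Reads are taken in file order; `limit` caps the number of
#' records, which is how the predictor samples the head of a library.
#'
#' @param path Path to a FASTQ file, or `"-"` for standard input.
#' @param limit Maximum number of records to return (`Inf` for all).
#' @return A tibble with one row per read and columns `read_id`, `bases`
#'   (uppercased, alphabet `A`/`C`/`G`/`T`/`N`) and `quals` (raw quality
#'   string, same width as `bases`).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "acgt", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, limit = Inf) {
  stopifnot(is.character(path), length(path) == 1, limit >= 0)
  con <- if (identical(path, "-")) {
    file("stdin", open = "r")
  } else {
    if (!file.exists(path)) {
      stop("FASTQ file not found: ", path, call. = FALSE)
    }
    # gzfile() reads plain text transparently and sniffs the gzip magic bytes
    gzfile(path, open = "rt")
  }
  on.exit(close(con), add = TRUE)

  chunk_records <- 65536L
  pieces <- list()
  n_seen <- 0L
  lines_before <- 0L
  repeat {
    want <- if (is.finite(limit)) min(chunk_records, limit - n_seen) else chunk_records
    if (want <= 0) break
    lines <- readLines(con, n = 4L * want)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      stop("malformed FASTQ: truncated record starting at line ",
           lines_before + 4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
    }
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- lines[idx + 1L]
    plus <- lines[idx + 2L]
    quals <- lines[idx + 3L]

    bad_hdr <- which(!startsWith(hdr, "@"))
    if (length(bad_hdr) > 0L) {
      stop("malformed FASTQ: expected '@' header at line ",
           lines_before + 4L * (bad_hdr[1] - 1L) + 1L, call. = FALSE)
    }
    bad_plus <- which(!startsWith(plus, "+"))
    if (length(bad_plus) > 0L) {
      stop("malformed FASTQ: expected '+' separator at line ",
           lines_before + 4L * (bad_plus[1] - 1L) + 3L, call. = FALSE)
    }
    bad_len <- which(nchar(seqs) != nchar(quals))
    if (length(bad_len) > 0L) {
      stop("malformed FASTQ: sequence/quality length mismatch at line ",
           lines_before + 4L * (bad_len[1] - 1L) + 2L, call. = FALSE)
    }
    seqs <- toupper(seqs)
    bad_alpha <- which(grepl("[^ACGTN]", seqs))
    if (length(bad_alpha) > 0L) {
      stop("malformed FASTQ: non-ACGTN base at line ",
           lines_before + 4L * (bad_alpha[1] - 1L) + 2L, call. = FALSE)
    }

    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      read_id = sub("^@", "", sub("[ \t].*$", "", hdr)),
      bases = seqs,
      quals = quals
    )
    n_seen <- n_seen + length(idx)
    lines_before <- lines_before + length(lines)
    if (length(lines) < 4L * want) break
  }
  if (length(pieces) == 0L) {
    return(tibble::tibble(read_id = character(), bases = character(),
                          quals = character()))
  }
  dplyr::bind_rows(pieces)
}

#' Write reads to a FASTQ file
#'
#' Emits standard 4-line FASTQ that round-trips bit-exactly through
#' [read_fastq()].
#'
#' @param reads Tibble with columns `read_id`, `bases`, `quals`.
#' @param path Output file path.
#' @param gzip Compress the output with gzip.
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(reads, path, gzip = FALSE) {
  validate_reads(reads)
  con <- if (gzip) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  if (nrow(reads) > 0L) {
    lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                             "+", reads$quals))
    writeLines(lines, con)
  }
  invisible(nrow(reads))
}

validate_reads <- function(reads) {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "bases", "quals") %in% names(reads))) {
    stop("`reads` must be a data frame with columns read_id, bases, quals",
         call. = FALSE)
  }
  if (any(nchar(reads$bases) != nchar(reads$quals))) {
    stop("bases and quals must have equal length in every read", call. = FALSE)
  }
  invisible(reads)
}

#' Detect the Phred quality encoding offset
#'
#' Public small RNA libraries from the early Illumina era mix Phred+33 and
#' Phred+64 encodings. The minimum-code rule is decisive: any quality
#' character with ASCII code below 64 can only occur under the +33 encoding.
#'
#' @param reads Tibble of reads (see [read_fastq()]).
#' @return `33L` or `64L`.
#' @export
detect_phred_offset <- function(reads) {
  validate_reads(reads)
  quals <- reads$quals[nchar(reads$quals) > 0L]
  if (length(quals) == 0L) {
    stop("no quality strings present; pass the Phred offset explicitly",
         call. = FALSE)
  }
  codes <- utf8ToInt(paste(quals, collapse = ""))
  if (min(codes) < 64L) 33L else 64L
}

phred_scores <- function(qual, offset) {
  q <- utf8ToInt(qual) - offset
  if (any(q < 0L)) {
    stop("quality character below the declared Phred offset (", offset,
         "); wrong encoding?", call. = FALSE)
  }
  q
}

# Mott 3' trim of a single quality vector: running sum of (cutoff - q) from
# the 3' end; trim the suffix where the sum is maximal and positive. Ties go
# to the shortest suffix (retain more bases).
mott_keep_length <- function(q, cutoff) {
  n <- length(q)
  if (n == 0L) return(0L)
  cs <- cumsum(cutoff - rev(q))
  m <- which.max(cs)
  if (cs[m] > 0) n - m else n
}

#' Mott quality trimming
#'
#' Trims low-quality 3' ends with the Mott algorithm: scanning from the 3'
#' end, a running sum of `cutoff - q` is maintained and the read is truncated
#' at the position where that sum is maximal and positive. If the sum never
#' becomes positive the read is returned unchanged. The output is always a
#' (possibly empty) prefix of the input; empty reads are kept in the tibble
#' so the caller decides whether to filter them.
#'
#' Quality trimming is deliberately not part of the default prediction
#' pipeline: raw reads retain more adapter sequence and predict better. It
#' is exposed for users who want cleansed output trimmed as well.
#'
#' @param reads Tibble of reads.
#' @param cutoff Phred quality cutoff (commonly 10 or 20).
#' @param offset Phred offset, `33`, `64` or `"auto"`.
#' @return The reads tibble with trimmed `bases` and `quals`.
#' @export
mott_trim <- function(reads, cutoff, offset = "auto") {
  validate_reads(reads)
  stopifnot(cutoff >= 0)
  if (nrow(reads) == 0L) return(reads)
  if (identical(offset, "auto")) offset <- detect_phred_offset(reads)
  offset <- as.integer(offset)
  stopifnot(offset %in% c(33L, 64L))
  keep <- vapply(reads$quals, function(qual) {
    mott_keep_length(phred_scores(qual, offset), cutoff)
  }, integer(1), USE.NAMES = FALSE)
  dplyr::mutate(reads,
    bases = substr(.data$bases, 1L, keep),
    quals = substr(.data$quals, 1L, keep)
  )
}
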