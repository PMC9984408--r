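#' Read an amplicon FASTQ file
#'
#' Reads a (optionally gzip-compressed) FASTQ file into an `amplicon_reads`
#' object: three parallel vectors of identifiers, sequences, and Phred+33
#' quality strings. Records are validated as they are read; a malformed record
#' (truncated, missing `+` separator, or sequence/quality length mismatch)
#' raises an error naming the 1-based record index.
#'
#' @param path path to a FASTQ file (`.gz` accepted).
#' @return an `amplicon_reads` object (list with `id`, `seq`, `qual`).
#' @seealso [write_fastq()], [trim_adapters()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(amplicon_reads(character(), character(), character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4L + 1L)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) stop("malformed FASTQ: record ", bad[1L], " does not start with '@'")
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) stop("malformed FASTQ: record ", bad[1L], " missing '+' separator")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ: sequence/quality length mismatch at record ", bad[1L])
  }
  ids <- sub("^@", "", hdr)
  amplicon_reads(ids, toupper(seqs), quals)
}

#' Construct an amplicon read set
#'
#' @param id,seq,qual equal-length character vectors: read identifiers, DNA
#'   sequences over A/C/G/T/N, and Phred+33 quality strings (`nchar(qual)`
#'   must equal `nchar(seq)` element-wise).
#' @return an `amplicon_reads` object.
#' @export
amplicon_reads <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence/quality length mismatch")
  }
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = as.character(qual)),
            class = "amplicon_reads")
}

#' @export
length.amplicon_reads <- function(x) length(x$id)

#' @export
`[.amplicon_reads` <- function(x, i) {
  amplicon_reads(x$id[i], x$seq[i], x$qual[i])
}

#' @export
print.amplicon_reads <- function(x, ...) {
  cat("<amplicon_reads> ", length(x), " reads\n", sep = "")
  if (length(x)) {
    n <- min(3L, length(x))
    for (i in seq_len(n)) {
      cat("  ", x$id[i], ": ", substr(x$seq[i], 1L, 50L),
          if (nchar(x$seq[i]) > 50L) "..." else "", "\n", sep = "")
    }
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
#' @examples
#' phred_scores("IIII")  # 40 40 40 40
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# mean Phred per read, vectorized
.mean_phred <- function(qual) {
  vapply(qual, function(q) if (nchar(q)) mean(utf8ToInt(q)) - 33 else 0,
         numeric(1), USE.NAMES = FALSE)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: writing a just-read conforming file reproduces it
#' byte for byte.
#'
#' @param reads an `amplicon_reads` object.
#' @param path output path (`.gz` to compress).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "amplicon_reads"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(reads)) {
    out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}
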