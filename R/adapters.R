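#' Library adapter pair for amplicon HTS reads
#'
#' The defaults are the constant adapter sequences appended to the site-specific
#' PCR primers used to build the amplicon sequencing libraries (forward
#' `GGAGTGAGTACGGTGTGC`, backward `GAGTTGGATGCTGGATGG`). Reads therefore start
#' with the forward adapter and end with the reverse complement of the backward
#' adapter, possibly truncated at either end.
#'
#' @param forward,backward adapter sequences, written 5'->3' as on the primers.
#' @param min_overlap minimum length of an end-anchored partial adapter match
#'   (>= 5) for it to be trimmed.
#' @return an `adapter_pair` object.
#' @export
adapter_pair <- function(forward = "GGAGTGAGTACGGTGTGC",
                         backward = "GAGTTGGATGCTGGATGG",
                         min_overlap = 8L) {
  stopifnot(nchar(forward) > 0L, nchar(backward) > 0L)
  if (min_overlap < 5L) stop("min_overlap must be >= 5")
  structure(list(forward = toupper(forward), backward = toupper(backward),
                 min_overlap = as.integer(min_overlap)),
            class = "adapter_pair")
}

#' Trim library adapters from reads
#'
#' Removes the forward adapter (exact match anywhere, or a 3'-end partial match
#' of at least `min_overlap` bases at the read start) together with everything
#' 5' of it, and symmetrically removes the reverse complement of the backward
#' adapter (exact, or a 5'-end partial match of at least `min_overlap` bases at
#' the read end) together with everything 3' of it. Qualities are trimmed in
#' lockstep. Reads without an adapter hit are returned unchanged; reads that
#' become empty are dropped. The operation is idempotent on adapter-free
#' inserts.
#'
#' @param reads an `amplicon_reads` object (or a single sequence string).
#' @param adapters an [adapter_pair()].
#' @return trimmed `amplicon_reads` (or a string when `reads` is a string).
#' @export
trim_adapters <- function(reads, adapters = adapter_pair()) {
  stopifnot(inherits(adapters, "adapter_pair"))
  if (is.character(reads) && length(reads) == 1L) {
    r <- amplicon_reads("r", reads, strrep("I", nchar(reads)))
    return(trim_adapters(r, adapters)$seq)
  }
  stopifnot(inherits(reads, "amplicon_reads"))
  fwd <- adapters$forward
  bwd_rc <- revcomp(adapters$backward)
  mo <- adapters$min_overlap

  seqs <- reads$seq
  quals <- reads$qual

  # forward adapter: cut everything up to and including its match
  start <- rep(1L, length(seqs))
  hit <- regexpr(fwd, seqs, fixed = TRUE)
  full <- hit > 0L
  start[full] <- hit[full] + nchar(fwd)
  if (any(!full) && nchar(fwd) - 1L >= mo) {
    # partial: a >= mo suffix of fwd equals the read prefix
    for (k in seq(nchar(fwd) - 1L, mo)) {
      if (!any(!full)) break
      sfx <- substr(fwd, nchar(fwd) - k + 1L, nchar(fwd))
      m <- !full & startsWith(seqs, sfx)
      start[m] <- k + 1L
      full <- full | m
    }
  }

  end <- nchar(seqs)
  hit <- regexpr(bwd_rc, seqs, fixed = TRUE)
  fullb <- hit > 0L
  end[fullb] <- hit[fullb] - 1L
  if (any(!fullb) && nchar(bwd_rc) - 1L >= mo) {
    for (k in seq(nchar(bwd_rc) - 1L, mo)) {
      if (!any(!fullb)) break
      pfx <- substr(bwd_rc, 1L, k)
      m <- !fullb & endsWith(seqs, pfx)
      end[m] <- nchar(seqs[m]) - k
      fullb <- fullb | m
    }
  }

  seqs <- substr(seqs, start, end)
  quals <- substr(quals, start, end)
  keep <- nchar(seqs) > 0L
  amplicon_reads(reads$id[keep], seqs[keep], quals[keep])
}
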