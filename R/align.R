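#' Alignment scoring scheme
#'
#' Affine-gap scoring for semi-global read-to-amplicon alignment. A gap of
#' length k costs `gap_open + k * gap_extend` (`gap_open` is the opening
#' surcharge). Defaults favour mismatches over short gaps, which keeps point
#' conversions (the signal of interest) out of gap columns.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0); pairs involving N score as mismatches.
#' @param gap_open gap opening surcharge (< 0).
#' @param gap_extend per-base gap extension score (< 0).
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -6, gap_extend = -1) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Read quality-control parameters
#'
#' @param min_mean_quality minimum mean Phred score per read.
#' @param min_read_length minimum read length after trimming; `NA` means "the
#'   protospacer length of the site being quantified".
#' @param min_score_fraction minimum alignment score as a fraction of the
#'   maximum attainable score (`match * read length`); reads below it are
#'   classed unusable.
#' @return a `qc_params` object.
#' @export
qc_params <- function(min_mean_quality = 20, min_read_length = NA_integer_,
                      min_score_fraction = 0.6) {
  stopifnot(min_mean_quality >= 0, min_score_fraction >= 0)
  structure(list(min_mean_quality = min_mean_quality,
                 min_read_length = min_read_length,
                 min_score_fraction = min_score_fraction),
            class = "qc_params")
}

#' Align one read semi-globally to the amplicon reference
#'
#' Optimal affine-gap alignment in which the read is aligned end-to-end and the
#' amplicon contributes a contiguous window with unpenalized overhangs (Gotoh
#' algorithm, compiled). Traceback ties are broken deterministically:
#' match/mismatch preferred over deletion over insertion, with the leftmost
#' best-scoring end column.
#'
#' @param read a read sequence (string) or an `amplicon_reads` object of
#'   length 1.
#' @param site a `target_site` (alignment is to `site$amplicon`).
#' @param scoring a [scoring_scheme()].
#' @return an `alignment` object: `score`, `ref_start`/`ref_end` (0-based
#'   half-open amplicon span), `cigar` (M/I/D, read-global), `aligned_pos` /
#'   `aligned_base` (0-based amplicon offsets of match/mismatch columns and the
#'   read base observed there), `del_pos` (offsets of deleted reference bases),
#'   `ins_pos` (offsets before which insertions occur).
#' @export
align_read <- function(read, site, scoring = scoring_scheme()) {
  seq <- if (inherits(read, "amplicon_reads")) read$seq[1L] else read
  stopifnot(inherits(site, "target_site"), is.character(seq), nchar(seq) > 0L)
  al <- .align_semiglobal(seq, site$amplicon, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
  class(al) <- "alignment"
  al
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> score ", x$score, ", ref ", x$ref_start, "..", x$ref_end,
      " (0-based), cigar ", x$cigar, "\n", sep = "")
  invisible(x)
}

# Classify every read against a target site.
#
# Returns one row per input read:
#   id, status ("unusable" | "indel" | "ok"), score, window_seq (protospacer
#   positions 1..L in protospacer orientation; "-" marks deleted bases),
#   has_indel (indel overlapping the protospacer +/- `indel_pad` window).
# "ok" reads cover the whole protospacer with match/mismatch columns only.
.process_reads <- function(reads, site, qc = qc_params(),
                           scoring = scoring_scheme(), adapters = NULL,
                           indel_pad = 5L) {
  stopifnot(inherits(reads, "amplicon_reads"), inherits(site, "target_site"))
  if (!is.null(adapters)) reads <- trim_adapters(reads, adapters)
  n <- length(reads)
  min_len <- if (is.na(qc$min_read_length)) nchar(site$protospacer) else qc$min_read_length
  status <- character(n)
  window_seq <- rep(NA_character_, n)
  has_indel <- rep(FALSE, n)
  score <- rep(NA_real_, n)

  pos <- site$positions                       # 0-based amplicon offsets
  ws <- min(pos) - indel_pad                  # indel quantification window
  we <- max(pos) + indel_pad
  minus <- site$strand == "-"
  mq <- .mean_phred(reads$qual)

  for (i in seq_len(n)) {
    sq <- reads$seq[i]
    if (nchar(sq) < min_len || mq[i] < qc$min_mean_quality) {
      status[i] <- "unusable"
      next
    }
    al <- .align_semiglobal(sq, site$amplicon, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend)
    score[i] <- al$score
    if (al$score < qc$min_score_fraction * scoring$match * nchar(sq)) {
      status[i] <- "unusable"
      next
    }
    # must span the protospacer (reference overhang regions are uncovered)
    if (al$ref_start > min(pos) || al$ref_end <= max(pos)) {
      status[i] <- "unusable"
      next
    }
    # deletions overlap when the deleted base lies in the window; insertions
    # when their anchor touches it (inclusive of both edges)
    ind <- any(al$del_pos >= ws & al$del_pos <= we) ||
      any(al$ins_pos >= ws & al$ins_pos <= we + 1L)
    m <- match(pos, al$aligned_pos)
    bases <- al$aligned_base[m]
    bases[is.na(bases)] <- "-"               # deleted protospacer base
    if (minus) bases <- .complement(bases)
    window_seq[i] <- paste(bases, collapse = "")
    if (ind || any(bases == "-")) {
      status[i] <- "indel"
      has_indel[i] <- TRUE
    } else {
      status[i] <- "ok"
    }
  }
  data.frame(id = reads$id, status = status, score = score,
             window_seq = window_seq, has_indel = has_indel,
             stringsAsFactors = FALSE)
}

#' Align and classify amplicon reads against a target site
#'
#' Workhorse shared by [quantify()] and [allele_table()]: trims (optionally),
#' applies QC, aligns each read, and classifies it as `"unusable"` (failed QC,
#' low alignment score, or not spanning the protospacer), `"indel"` (an
#' insertion or deletion overlaps the protospacer `+/- indel_pad` window), or
#' `"ok"` (indel-free over the window). For `"indel"`/`"ok"` reads the
#' protospacer-window sequence is reported in protospacer orientation
#' (complemented for minus-strand sites), with `-` marking deleted bases.
#'
#' @inheritParams align_read
#' @param reads an `amplicon_reads` object.
#' @param qc a [qc_params()].
#' @param adapters optional [adapter_pair()] to trim first.
#' @param indel_pad half-width (nt) added on each side of the protospacer to
#'   form the indel quantification window.
#' @return data frame with columns `id`, `status`, `score`, `window_seq`,
#'   `has_indel`.
#' @export
process_reads <- function(reads, site, qc = qc_params(),
                          scoring = scoring_scheme(), adapters = NULL,
                          indel_pad = 5L) {
  .process_reads(reads, site, qc, scoring, adapters, indel_pad)
}
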