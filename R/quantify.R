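#' Tabulate per-protospacer-position base counts from amplicon reads
#'
#' Aligns every read to the amplicon and counts the base observed at each
#' protospacer position (protospacer orientation) among indel-free reads.
#' Reads with an insertion or deletion overlapping the protospacer
#' `+/- indel_pad` window are counted in `n_indel` and excluded from the base
#' counts, so gap columns never deflate conversion rates; reads failing QC,
#' scoring below the alignment threshold, or not spanning the protospacer are
#' counted as unusable.
#'
#' @inheritParams process_reads
#' @param reads an `amplicon_reads` object, or a data frame previously
#'   returned by [process_reads()] for this site.
#' @return an `editing_matrix`: `site`, `counts` (L x 6 matrix over
#'   A/C/G/T/N/del), `n_aligned` (= `n_indel_free + n_indel`), `n_indel_free`,
#'   `n_indel`, `n_unusable`.
#' @seealso [efficiency()], [indel_frequency()], [allele_table()]
#' @export
quantify <- function(reads, site, qc = qc_params(), scoring = scoring_scheme(),
                     adapters = NULL, indel_pad = 5L) {
  proc <- if (is.data.frame(reads)) reads
          else .process_reads(reads, site, qc, scoring, adapters, indel_pad)
  L <- nchar(site$protospacer)
  bases <- c("A", "C", "G", "T", "N", "del")
  counts <- matrix(0L, nrow = L, ncol = length(bases),
                   dimnames = list(position = seq_len(L), base = bases))
  ok <- proc$status == "ok"
  n_indel <- sum(proc$status == "indel")
  n_unusable <- sum(proc$status == "unusable")
  if (!any(ok) && n_indel == 0L) stop("no usable reads")
  if (any(ok)) {
    mat <- do.call(rbind, strsplit(proc$window_seq[ok], ""))
    for (j in seq_len(L)) {
      tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T", "N")))
      counts[j, 1:5] <- as.integer(tab)
    }
  }
  structure(list(site = site, counts = counts,
                 n_aligned = sum(ok) + n_indel,
                 n_indel_free = sum(ok),
                 n_indel = n_indel,
                 n_unusable = n_unusable),
            class = "editing_matrix")
}

#' Per-position conversion efficiency
#'
#' For each protospacer position whose reference base (protospacer
#' orientation) is `from`, the percentage of indel-free reads carrying `to`
#' there: `100 * counts[pos, to] / (n_indel_free - counts[pos, "N"])`. N calls
#' are excluded from both numerator and denominator; positions with a
#' different reference base are `NA`, never zero.
#'
#' @param matrix an `editing_matrix` from [quantify()].
#' @param from,to single reference/converted bases, e.g. `"A"`, `"G"`.
#' @return named numeric vector of length L (percentages, `NA` where the
#'   reference base is not `from`).
#' @export
efficiency <- function(matrix, from = "A", to = "G") {
  stopifnot(inherits(matrix, "editing_matrix"))
  if (matrix$n_indel_free == 0L) stop("no indel-free reads to compute efficiency from")
  ref <- proto_bases(matrix$site)
  out <- rep(NA_real_, length(ref))
  names(out) <- seq_along(ref)
  idx <- which(ref == from)
  denom <- matrix$n_indel_free - matrix$counts[idx, "N"]
  out[idx] <- ifelse(denom > 0, 100 * matrix$counts[idx, to] / denom, NA_real_)
  out
}

#' Indel frequency
#'
#' Percentage of aligned reads (indel-free plus indel-containing) carrying an
#' insertion or deletion overlapping the quantification window:
#' `100 * n_indel / n_aligned`.
#'
#' @param matrix an `editing_matrix`.
#' @return a percentage.
#' @export
indel_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "editing_matrix"))
  if (matrix$n_aligned == 0L) stop("no aligned reads")
  100 * matrix$n_indel / matrix$n_aligned
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat("<editing_matrix> ", x$site$name, ": ", x$n_aligned, " aligned (",
      x$n_indel_free, " indel-free, ", x$n_indel, " indel, ",
      x$n_unusable, " unusable)\n", sep = "")
  invisible(x)
}

#' @export
summary.editing_matrix <- function(object, conversions = list(c("A", "G"), c("C", "T")), ...) {
  ref <- proto_bases(object$site)
  df <- data.frame(position = seq_along(ref), ref_base = ref,
                   object$counts, check.names = FALSE)
  for (cv in conversions) {
    eff <- efficiency(object, cv[1], cv[2])
    df[[paste0(cv[1], "_to_", cv[2], "_pct")]] <- round(eff, 3)
  }
  df
}

#' @export
plot.editing_matrix <- function(x, from = "A", to = "G", ...) {
  eff <- efficiency(x, from, to)
  bp <- barplot(eff, names.arg = names(eff),
                xlab = "protospacer position (1 = PAM-distal)",
                ylab = sprintf("%s-to-%s efficiency (%%)", from, to),
                main = x$site$name, ylim = c(0, 100), ...)
  invisible(bp)
}

#' Write an editing matrix (and efficiencies) to TSV
#'
#' @param matrix an `editing_matrix`.
#' @param path output TSV path.
#' @param conversions list of `c(from, to)` base pairs to add as efficiency
#'   columns.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path,
                             conversions = list(c("A", "G"), c("C", "T"))) {
  df <- summary.editing_matrix(matrix, conversions)
  df$n_indel_free <- matrix$n_indel_free
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
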