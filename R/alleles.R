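#' Build an allele table from amplicon reads
#'
#' Tallies each aligned read's protospacer-window sequence (protospacer
#' orientation; `-` marks deleted bases) into distinct alleles. Entries are
#' sorted by descending count, then lexicographically. Unusable reads are
#' excluded; `n_total` counts all classified (indel-free plus indel) reads.
#'
#' @inheritParams quantify
#' @return an `allele_table`: `site`, `entries` (data frame `allele_seq`,
#'   `has_indel`, `count`, `frequency`), `n_total`.
#' @export
allele_table <- function(reads, site, qc = qc_params(), scoring = scoring_scheme(),
                         adapters = NULL, indel_pad = 5L) {
  proc <- if (is.data.frame(reads)) reads
          else .process_reads(reads, site, qc, scoring, adapters, indel_pad)
  keep <- proc$status %in% c("ok", "indel")
  proc <- proc[keep, , drop = FALSE]
  if (nrow(proc) == 0L) {
    entries <- data.frame(allele_seq = character(), has_indel = logical(),
                          count = integer(), frequency = numeric(),
                          stringsAsFactors = FALSE)
    return(structure(list(site = site, entries = entries, n_total = 0L),
                     class = "allele_table"))
  }
  key <- paste(proc$window_seq, proc$has_indel, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  entries <- data.frame(
    allele_seq = vapply(parts, `[`, "", 1L),
    has_indel = vapply(parts, `[`, "", 2L) == "TRUE",
    count = as.integer(tab),
    stringsAsFactors = FALSE)
  entries <- entries[order(-entries$count, entries$allele_seq), , drop = FALSE]
  rownames(entries) <- NULL
  entries$frequency <- entries$count / nrow(proc)
  structure(list(site = site, entries = entries, n_total = nrow(proc)),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, n = 10L, ...) {
  cat("<allele_table> ", x$site$name, ": ", nrow(x$entries),
      " distinct alleles over ", x$n_total, " reads\n", sep = "")
  if (nrow(x$entries)) print(utils::head(x$entries, n))
  invisible(x)
}

#' Number of mutant allele types
#'
#' Distinct non-reference alleles whose frequency reaches `min_freq` (default
#' 0.1% of classified reads, suppressing sequencing-error singletons).
#'
#' @param table an [allele_table()].
#' @param min_freq minimum allele frequency (fraction of `n_total`).
#' @return integer count of mutant allele types.
#' @export
n_allele_types <- function(table, min_freq = 0.001) {
  stopifnot(inherits(table, "allele_table"))
  if (table$n_total == 0L) return(0L)
  ref <- table$site$protospacer
  e <- table$entries
  sum(!(e$allele_seq == ref & !e$has_indel) & e$frequency >= min_freq)
}

#' Classify alleles into exclusive / combined edit classes
#'
#' Partitions every classified read into six mutually exclusive classes, the
#' dual-base-editor outcome breakdown: `indel` (indel overlapping the window),
#' `simultaneous` (at least one A-to-G at `a_positions` and at least one
#' C-to-T at `c_positions` on the same allele), `only_a2g`, `only_c2t`,
#' `unedited` (identical to reference), and `other_subst` (substitutions but
#' no qualifying conversion).
#'
#' @param table an [allele_table()].
#' @param a_positions protospacer positions with a reference A to score A-to-G
#'   at (default: all reference-A positions).
#' @param c_positions protospacer positions with a reference C to score C-to-T
#'   at (default: all reference-C positions).
#' @return an `edit_class_counts`: the six class counts plus `n_total`.
#' @export
classify_alleles <- function(table, a_positions = NULL, c_positions = NULL) {
  stopifnot(inherits(table, "allele_table"))
  ref <- proto_bases(table$site)
  L <- length(ref)
  if (is.null(a_positions)) a_positions <- which(ref == "A")
  if (is.null(c_positions)) c_positions <- which(ref == "C")
  if (length(a_positions) && (any(a_positions < 1L) || any(a_positions > L))) {
    stop("a_positions outside protospacer (1..", L, ")")
  }
  if (length(c_positions) && (any(c_positions < 1L) || any(c_positions > L))) {
    stop("c_positions outside protospacer (1..", L, ")")
  }
  if (any(ref[a_positions] != "A")) stop("a_positions must be reference-A positions")
  if (any(ref[c_positions] != "C")) stop("c_positions must be reference-C positions")

  cls <- c(only_a2g = 0L, only_c2t = 0L, simultaneous = 0L,
           unedited = 0L, other_subst = 0L, indel = 0L)
  e <- table$entries
  for (i in seq_len(nrow(e))) {
    k <- .classify_one(e$allele_seq[i], e$has_indel[i], ref,
                       a_positions, c_positions)
    cls[k] <- cls[k] + e$count[i]
  }
  structure(c(as.list(cls), list(n_total = table$n_total)),
            class = "edit_class_counts")
}

# classify a single allele window string; returns the class name
.classify_one <- function(seq, has_indel, ref, a_positions, c_positions) {
  if (has_indel) return("indel")
  obs <- strsplit(seq, "")[[1L]]
  a2g <- length(a_positions) > 0L && any(obs[a_positions] == "G")
  c2t <- length(c_positions) > 0L && any(obs[c_positions] == "T")
  if (a2g && c2t) return("simultaneous")
  if (a2g) return("only_a2g")
  if (c2t) return("only_c2t")
  if (all(obs == ref)) return("unedited")
  "other_subst"
}

#' @export
print.edit_class_counts <- function(x, ...) {
  cat("<edit_class_counts> n_total = ", x$n_total, "\n", sep = "")
  for (k in c("only_a2g", "only_c2t", "simultaneous", "unedited",
              "other_subst", "indel")) {
    cat(sprintf("  %-12s %7d (%5.1f%%)\n", k, x[[k]],
                if (x$n_total) 100 * x[[k]] / x$n_total else 0))
  }
  invisible(x)
}

#' Frequency of simultaneous A/C conversion
#'
#' Percentage of classified reads carrying both at least one A-to-G and at
#' least one C-to-T conversion on the same allele:
#' `100 * simultaneous / n_total`. The headline statistic for dual base
#' editors.
#'
#' @param counts an `edit_class_counts` from [classify_alleles()].
#' @return a percentage.
#' @export
simultaneous_fraction <- function(counts) {
  stopifnot(inherits(counts, "edit_class_counts"))
  if (counts$n_total == 0L) stop("n_total is zero")
  100 * counts$simultaneous / counts$n_total
}

#' Most efficiently edited position
#'
#' @param matrix an `editing_matrix`.
#' @param from,to the conversion (default A-to-G).
#' @return list with `position` and `efficiency` (%); ties are broken toward
#'   the PAM-distal (smaller) position.
#' @export
max_position_efficiency <- function(matrix, from = "A", to = "G") {
  eff <- efficiency(matrix, from, to)
  if (all(is.na(eff))) stop("no editable (reference ", from, ") position in protospacer")
  pos <- which.max(eff)  # first maximum = PAM-distal tie-break
  list(position = as.integer(names(eff)[pos]), efficiency = unname(eff[pos]))
}
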