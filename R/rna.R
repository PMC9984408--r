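#' RNA off-target filter thresholds
#'
#' Thresholds for the RNA variant filtering chain: a candidate locus in a base
#' editor overexpression sample is kept only if the matched control covers it
#' deeper than the `coverage_percentile`-th percentile of coverages across all
#' overexpression variants and the control shows at least
#' `control_ref_consensus` of reads carrying the reference allele; background
#' RNA-editing loci from a GFP control are those with at least `min_reads_gfp`
#' reads and more than 0% alternate-allele reads.
#'
#' @param coverage_percentile percentile (0-100) of overexpression variant
#'   coverages that the control depth must exceed.
#' @param control_ref_consensus minimum control reference-allele fraction.
#' @param min_reads_gfp minimum GFP-control depth for a background locus.
#' @param min_alt_fraction retained loci must exceed this alternate-allele
#'   fraction (0 means "more than 0%", i.e. at least one alt read).
#' @return an `rna_filter_params` object.
#' @export
rna_filter_params <- function(coverage_percentile = 90,
                              control_ref_consensus = 0.99,
                              min_reads_gfp = 10L,
                              min_alt_fraction = 0) {
  stopifnot(coverage_percentile >= 0, coverage_percentile <= 100,
            control_ref_consensus > 0, control_ref_consensus <= 1,
            min_reads_gfp >= 1L, min_alt_fraction >= 0)
  structure(list(coverage_percentile = coverage_percentile,
                 control_ref_consensus = control_ref_consensus,
                 min_reads_gfp = as.integer(min_reads_gfp),
                 min_alt_fraction = min_alt_fraction),
            class = "rna_filter_params")
}

#' Linear-interpolation percentile
#'
#' The type-7 (linear interpolation, inclusive endpoints) sample percentile:
#' `percentile(1:100, 90)` is 90.1 and `percentile(x, 100)` is `max(x)`.
#'
#' @param values non-empty numeric vector.
#' @param q percentile in 0-100.
#' @return the percentile value.
#' @export
percentile <- function(values, q) {
  stopifnot(length(values) > 0L, q >= 0, q <= 100)
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

# canonical columns of a variant table
.variant_cols <- c("contig", "position", "ref", "alt", "depth", "alt_depth",
                   "gene_strand")

.check_variants <- function(df, need_strand = FALSE) {
  need <- setdiff(.variant_cols, if (need_strand) character() else "gene_strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (!"gene_strand" %in% names(df)) df$gene_strand <- "unknown"
  if (any(df$alt_depth > df$depth)) stop("alt_depth exceeds depth")
  if (any(df$ref == df$alt)) stop("ref equals alt at some loci")
  df
}

#' Read a per-sample variant table (TSV or VCF)
#'
#' TSV input must carry columns `contig`, `position`, `ref`, `alt`, `depth`,
#' `alt_depth` and optionally `gene_strand` (`+`, `-` or `unknown`). VCF input
#' (requires the vcfR package) uses CHROM/POS/REF/ALT with per-sample `DP` and
#' `AD` fields; the gene strand then comes from `strand_bed`, a BED file of
#' stranded gene intervals.
#'
#' @param path variant table path (`.tsv`/`.txt` or `.vcf`/`.vcf.gz`).
#' @param strand_bed optional BED file (chrom, start, end, name, score,
#'   strand) used to assign `gene_strand` to VCF records.
#' @return data frame of variant records.
#' @export
read_variants <- function(path, strand_bed = NULL) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package; supply a TSV instead")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1L]))
    ad <- vcfR::extract.gt(v, "AD")[, 1L]
    alt_depth <- suppressWarnings(as.integer(vapply(
      strsplit(ad, ","), function(p) if (length(p) >= 2L) p[2L] else NA_character_,
      character(1))))
    df <- data.frame(contig = fix$CHROM, position = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, depth = dp,
                     alt_depth = alt_depth, gene_strand = "unknown",
                     stringsAsFactors = FALSE)
    if (!is.null(strand_bed)) {
      bed <- read.delim(strand_bed, header = FALSE, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(df))) {
        hit <- which(bed[[1L]] == df$contig[i] & bed[[2L]] < df$position[i] &
                       bed[[3L]] >= df$position[i])
        if (length(hit)) df$gene_strand[i] <- bed[[6L]][hit[1L]]
      }
    }
    .check_variants(df)
  } else {
    .check_variants(read.delim(path, stringsAsFactors = FALSE))
  }
}

#' Control-confidence filter for overexpression variants
#'
#' Retains an overexpression variant locus only when the control sample gives
#' a high-confidence reference genotype there: (a) the control covers the
#' locus with depth strictly greater than the `coverage_percentile`-th
#' percentile of coverages across all overexpression variants, and (b) the
#' control reference-allele fraction at the locus is at least
#' `control_ref_consensus`. Loci absent from the control table are excluded.
#'
#' @param oe_variants overexpression variant table (data frame).
#' @param control_variants control coverage table: same columns; `alt_depth`
#'   is the count of non-reference reads at the locus (0 for a clean control).
#' @param params an [rna_filter_params()].
#' @return retained rows of `oe_variants`, with an attribute `filter_counts`
#'   (named integer vector: input, no_control, low_depth, low_consensus,
#'   retained).
#' @export
control_confidence_filter <- function(oe_variants, control_variants,
                                      params = rna_filter_params()) {
  oe <- .check_variants(oe_variants)
  ctl <- .check_variants(control_variants)
  if (nrow(oe) == 0L) {
    out <- oe
    attr(out, "filter_counts") <- c(input = 0L, no_control = 0L, low_depth = 0L,
                                    low_consensus = 0L, retained = 0L)
    return(out)
  }
  thr <- percentile(oe$depth, params$coverage_percentile)
  key <- function(d) paste(d$contig, d$position, sep = ":")
  m <- match(key(oe), key(ctl))
  no_control <- is.na(m)
  ctl_depth <- ctl$depth[m]
  ctl_ref_frac <- (ctl$depth[m] - ctl$alt_depth[m]) / ctl$depth[m]
  deep <- !no_control & ctl_depth > thr
  consensus <- deep & ctl_ref_frac >= params$control_ref_consensus
  out <- oe[which(consensus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    input = nrow(oe),
    no_control = sum(no_control),
    low_depth = sum(!no_control & !deep),
    low_consensus = sum(deep & !consensus),
    retained = nrow(out))
  out
}

#' Background RNA-editing loci in a GFP control
#'
#' Keeps GFP-control loci with at least `min_reads_gfp` reads and more than 0%
#' of reads carrying the alternate allele; these form the background set
#' subtracted from the overexpression variants.
#'
#' @param variants GFP-control variant table.
#' @param params an [rna_filter_params()].
#' @return retained rows of `variants`.
#' @export
gfp_background_filter <- function(variants, params = rna_filter_params()) {
  v <- .check_variants(variants)
  out <- v[v$depth >= params$min_reads_gfp & v$alt_depth >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-aware edit-type labels
#'
#' A-to-I RNA editing reads as A-to-G on the transcribed plus strand or T-to-C
#' on the minus strand; C-to-U as C-to-T on the plus strand or G-to-A on the
#' minus strand. Everything else (including loci on genes of unknown strand)
#' is `other`.
#'
#' @param ref,alt reference/alternate bases (vectors recycled to a common
#'   length).
#' @param gene_strand `"+"`, `"-"` or `"unknown"`.
#' @return character vector over `"A-to-I"`, `"C-to-U"`, `"other"`.
#' @export
#' @examples
#' label_edit_type(c("A", "T", "A"), c("G", "C", "G"), c("+", "-", "-"))
label_edit_type <- function(ref, alt, gene_strand) {
  n <- max(length(ref), length(alt), length(gene_strand))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  gene_strand <- rep_len(gene_strand, n)
  out <- rep("other", n)
  out[(ref == "A" & alt == "G" & gene_strand == "+") |
        (ref == "T" & alt == "C" & gene_strand == "-")] <- "A-to-I"
  out[(ref == "C" & alt == "T" & gene_strand == "+") |
        (ref == "G" & alt == "A" & gene_strand == "-")] <- "C-to-U"
  out
}

#' RNA off-target variant filtering pipeline
#'
#' Applies, in order: the control-confidence filter
#' ([control_confidence_filter()]); subtraction of background RNA-editing loci
#' retained from the GFP control ([gfp_background_filter()]), matched by
#' (contig, position, ref, alt); removal of loci without alternate reads; and
#' strand-aware edit-type labeling ([label_edit_type()]).
#'
#' @param oe_table overexpression variant table.
#' @param control_table control variant/coverage table.
#' @param gfp_table GFP-control variant table.
#' @param params an [rna_filter_params()].
#' @return an `rna_edit_summary`: `n_sites`, `editing_fractions`
#'   (`alt_depth/depth` per retained site), `mean_efficiency`, `by_type`
#'   (A-to-I / C-to-U / other counts), `sites` (the retained table with an
#'   `edit_type` column), `filter_log` (row counts after each step).
#' @export
rna_pipeline <- function(oe_table, control_table, gfp_table,
                         params = rna_filter_params()) {
  retained <- control_confidence_filter(oe_table, control_table, params)
  log <- c(input = nrow(.check_variants(oe_table)),
           control_confident = nrow(retained))
  bg <- gfp_background_filter(gfp_table, params)
  key <- function(d) paste(d$contig, d$position, d$ref, d$alt, sep = ":")
  retained <- retained[!(key(retained) %in% key(bg)), , drop = FALSE]
  log <- c(log, background_subtracted = nrow(retained))
  frac <- retained$alt_depth / retained$depth
  keep <- retained$alt_depth >= 1L & frac > params$min_alt_fraction
  retained <- retained[keep, , drop = FALSE]
  rownames(retained) <- NULL
  log <- c(log, with_alt_reads = nrow(retained))
  retained$edit_type <- if (nrow(retained)) {
    label_edit_type(retained$ref, retained$alt, retained$gene_strand)
  } else character()
  fractions <- retained$alt_depth / retained$depth
  by_type <- c("A-to-I" = sum(retained$edit_type == "A-to-I"),
               "C-to-U" = sum(retained$edit_type == "C-to-U"),
               other = sum(retained$edit_type == "other"))
  structure(list(n_sites = nrow(retained),
                 editing_fractions = fractions,
                 mean_efficiency = if (nrow(retained)) mean(fractions) else NA_real_,
                 by_type = by_type,
                 sites = retained,
                 filter_log = log),
            class = "rna_edit_summary")
}

#' @export
print.rna_edit_summary <- function(x, ...) {
  cat("<rna_edit_summary> ", x$n_sites, " retained edit sites", sep = "")
  if (x$n_sites) {
    cat(sprintf(" (mean editing fraction %.4f)", x$mean_efficiency))
  }
  cat("\n  by type: ", paste(names(x$by_type), x$by_type, sep = "=",
                             collapse = ", "), "\n", sep = "")
  cat("  filter steps: ", paste(names(x$filter_log), x$filter_log, sep = "=",
                                collapse = " -> "), "\n", sep = "")
  invisible(x)
}
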