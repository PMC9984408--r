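#' Generative model for an edited amplicon read population
#'
#' Parameterizes a population of cells exposed to a (single or dual) base
#' editor: per-position conversion probabilities, a co-editing coupling, an
#' indel rate, and a uniform sequencing-error overlay. Coupling is a
#' two-component mixture: with probability `rho` all editable positions of a
#' read are driven by one shared uniform draw (position i edited iff
#' U < p_i), with probability `1 - rho` positions edit independently. Either
#' way the marginal conversion probability at position i is exactly `p_i`;
#' the co-edit probability of two positions interpolates from the product of
#' marginals (rho = 0) to the minimum of marginals (rho = 1).
#'
#' @param site a `target_site`.
#' @param p_edit named numeric vector: protospacer position -> conversion
#'   probability for that position's designated conversion (A-to-G at
#'   reference-A positions, C-to-T at reference-C positions; other reference
#'   bases are an error).
#' @param rho co-editing coupling in `[0, 1]`.
#' @param indel_rate per-read probability of one indel, placed uniformly
#'   within the protospacer `+/- 5` nt window.
#' @param indel_sizes,indel_size_probs indel size distribution; negative sizes
#'   are deletions, positive are insertions.
#' @param error_rate per-base uniform substitution error probability.
#' @param n_reads number of reads to simulate.
#' @param seed RNG seed (the simulation is fully deterministic given the seed).
#' @param phred constant Phred score assigned to every base.
#' @param adapters optional [adapter_pair()]; when given, reads are emitted as
#'   forward adapter + amplicon + revcomp(backward adapter), as in the
#'   sequencing libraries.
#' @return an `editing_model` object.
#' @export
editing_model <- function(site, p_edit, rho = 0, indel_rate = 0,
                          indel_sizes = c(-2L, -1L, 1L, 2L),
                          indel_size_probs = c(0.15, 0.55, 0.2, 0.1),
                          error_rate = 0, n_reads = 1000L, seed = 1L,
                          phred = 37L, adapters = NULL) {
  stopifnot(inherits(site, "target_site"),
            all(p_edit >= 0), all(p_edit <= 1),
            rho >= 0, rho <= 1, indel_rate >= 0, indel_rate <= 1,
            error_rate >= 0, error_rate <= 1, n_reads > 0)
  pos <- as.integer(names(p_edit))
  if (length(p_edit) && (is.null(names(p_edit)) || any(is.na(pos)))) {
    stop("p_edit must be named by protospacer position")
  }
  ref <- proto_bases(site)
  bad <- pos[!(ref[pos] %in% c("A", "C"))]
  if (length(bad)) {
    stop("p_edit references non-editable reference base at position(s) ",
         paste(bad, collapse = ", "), " (must be A or C)")
  }
  structure(list(site = site, p_edit = p_edit, rho = rho,
                 indel_rate = indel_rate, indel_sizes = as.integer(indel_sizes),
                 indel_size_probs = indel_size_probs / sum(indel_size_probs),
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), phred = as.integer(phred),
                 adapters = adapters),
            class = "editing_model")
}

# conversion target of an edited base, in protospacer orientation
.converted_base <- c(A = "G", C = "T")

#' Simulate an edited amplicon read population
#'
#' Draws reads from an [editing_model()]: per-read conversions (with the
#' rho-coupling described there), at most one indel per read placed uniformly
#' in the protospacer `+/- 5` window, then a uniform substitution error
#' overlay, constant-Phred qualities, and optional adapter attachment. Fixed
#' seeds give byte-identical output.
#'
#' @param model an [editing_model()].
#' @param fastq optional path; when given the reads are also written as FASTQ
#'   (Phred+33).
#' @param truth_tsv optional path for the per-read truth table.
#' @return list with `reads` (an `amplicon_reads`) and `truth` (data frame:
#'   `id`, one logical `edited_<pos>` column per modelled position,
#'   `has_indel`, `indel_size`).
#' @export
simulate_reads <- function(model, fastq = NULL, truth_tsv = NULL) {
  stopifnot(inherits(model, "editing_model"))
  site <- model$site
  ref_chars <- strsplit(site$amplicon, "")[[1L]]
  proto_ref <- proto_bases(site)
  pos <- as.integer(names(model$p_edit))
  p <- as.numeric(model$p_edit)
  offsets <- site$positions[pos] + 1L  # 1-based amplicon offsets
  minus <- site$strand == "-"
  ws <- min(site$positions) - 5L + 1L
  we <- max(site$positions) + 5L + 1L
  ws <- max(ws, 1L)
  we <- min(we, length(ref_chars))
  alphabet <- c("A", "C", "G", "T")

  .with_seed(model$seed, {
    n <- model$n_reads
    ids <- sprintf("read_%06d", seq_len(n))
    edited <- matrix(FALSE, nrow = n, ncol = length(pos))
    if (length(pos)) {
      coupled <- runif(n) < model$rho
      u <- runif(n)
      for (k in seq_along(pos)) {
        ind <- runif(n) < p[k]
        edited[, k] <- ifelse(coupled, u < p[k], ind)
      }
    }
    has_indel <- runif(n) < model$indel_rate
    indel_size <- rep(0L, n)
    if (any(has_indel)) {
      indel_size[has_indel] <- sample(model$indel_sizes, sum(has_indel),
                                      replace = TRUE,
                                      prob = model$indel_size_probs)
    }
    seqs <- character(n)
    for (i in seq_len(n)) {
      chars <- ref_chars
      for (k in which(edited[i, ])) {
        # conversion is defined in protospacer orientation; on the minus
        # strand the amplicon carries the complement
        to <- .converted_base[[proto_ref[pos[k]]]]
        chars[offsets[k]] <- if (minus) .complement(to) else to
      }
      if (has_indel[i]) {
        sz <- indel_size[i]
        if (sz < 0L) {
          anchor <- sample(ws:max(ws, we + sz + 1L), 1L)
          chars <- chars[-(anchor:min(length(chars), anchor - sz - 1L))]
        } else {
          anchor <- sample(ws:we, 1L)
          ins <- sample(alphabet, sz, replace = TRUE)
          chars <- append(chars, ins, after = anchor - 1L)
        }
      }
      if (model$error_rate > 0) {
        err <- which(runif(length(chars)) < model$error_rate)
        for (e in err) {
          chars[e] <- sample(setdiff(alphabet, chars[e]), 1L)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    if (!is.null(model$adapters)) {
      seqs <- paste0(model$adapters$forward, seqs,
                     revcomp(model$adapters$backward))
    }
    quals <- strrep(intToUtf8(model$phred + 33L), nchar(seqs))
    reads <- amplicon_reads(ids, seqs, quals)
    truth <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (k in seq_along(pos)) {
      truth[[paste0("edited_", pos[k])]] <- edited[, k]
    }
    truth$has_indel <- has_indel
    truth$indel_size <- indel_size
    if (!is.null(fastq)) write_fastq(reads, fastq)
    if (!is.null(truth_tsv)) {
      write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(reads = reads, truth = truth)
  })
}

#' Parameters for simulated RNA variant tables
#'
#' Describes paired control / base-editor-overexpression / GFP-control RNA
#' variant tables with planted A-to-I edits: `n_true_edits` deaminase-driven
#' edit loci present only in the overexpression sample, `n_background_snps`
#' germline-like heterozygous loci shared with the control (removed by the
#' reference-consensus filter), and `n_gfp_shared` background RNA-editing loci
#' present in both the GFP control and the overexpression sample (removed by
#' background subtraction). Control depths are drawn well above overexpression
#' depths so a clean control passes the coverage-percentile gate.
#'
#' @param n_true_edits,n_background_snps,n_gfp_shared locus counts.
#' @param edit_fraction_range planted editing fractions are drawn uniformly
#'   from this interval.
#' @param oe_depth_mean,control_depth_mean,gfp_depth_mean Poisson means of the
#'   per-locus read depths.
#' @param contigs contig names loci are scattered over.
#' @param seed RNG seed.
#' @return an `rna_sim_params` object.
#' @export
rna_sim_params <- function(n_true_edits = 20L, n_background_snps = 30L,
                           n_gfp_shared = 5L,
                           edit_fraction_range = c(0.05, 0.6),
                           oe_depth_mean = 50, control_depth_mean = 300,
                           gfp_depth_mean = 100,
                           contigs = paste0("chr", 1:5), seed = 1L) {
  stopifnot(n_true_edits >= 0, n_background_snps >= 0, n_gfp_shared >= 0,
            length(edit_fraction_range) == 2L,
            edit_fraction_range[1] > 0, edit_fraction_range[2] <= 1)
  structure(list(n_true_edits = as.integer(n_true_edits),
                 n_background_snps = as.integer(n_background_snps),
                 n_gfp_shared = as.integer(n_gfp_shared),
                 edit_fraction_range = edit_fraction_range,
                 oe_depth_mean = oe_depth_mean,
                 control_depth_mean = control_depth_mean,
                 gfp_depth_mean = gfp_depth_mean,
                 contigs = contigs, seed = as.integer(seed)),
            class = "rna_sim_params")
}

#' Simulate paired RNA variant tables with planted edits
#'
#' @param params an [rna_sim_params()].
#' @return list of data frames `oe`, `control`, `gfp`, and `truth` (the
#'   planted edit loci, all of which a clean run of [rna_pipeline()] should
#'   retain and label `A-to-I`).
#' @export
simulate_rna_tables <- function(params = rna_sim_params()) {
  stopifnot(inherits(params, "rna_sim_params"))
  .with_seed(params$seed, {
    n_all <- params$n_true_edits + params$n_background_snps + params$n_gfp_shared
    contig <- sample(params$contigs, n_all, replace = TRUE)
    position <- sample.int(1e6L, n_all, replace = FALSE)
    strand <- sample(c("+", "-"), n_all, replace = TRUE)
    # A-to-I loci: A>G on +, T>C on -
    ref <- ifelse(strand == "+", "A", "T")
    alt <- ifelse(strand == "+", "G", "C")
    kind <- rep(c("true", "snp", "gfp"),
                c(params$n_true_edits, params$n_background_snps,
                  params$n_gfp_shared))
    # germline-like SNPs need not follow the editing rule
    ref[kind == "snp"] <- sample(c("C", "G"), sum(kind == "snp"), replace = TRUE)
    alt[kind == "snp"] <- ifelse(ref[kind == "snp"] == "C", "A", "T")

    frac <- runif(n_all, params$edit_fraction_range[1],
                  params$edit_fraction_range[2])
    frac[kind == "snp"] <- 0.5

    oe_depth <- rpois(n_all, params$oe_depth_mean) + 1L
    oe_alt <- rbinom(n_all, oe_depth, frac)
    oe_alt[kind == "true"] <- pmax(oe_alt[kind == "true"], 1L)
    oe <- data.frame(contig = contig, position = position, ref = ref,
                     alt = alt, depth = oe_depth, alt_depth = oe_alt,
                     gene_strand = strand, stringsAsFactors = FALSE)

    ctl_depth <- rpois(n_all, params$control_depth_mean) + 1L
    ctl_alt <- rep(0L, n_all)  # clean control at edit loci
    het <- kind == "snp"
    ctl_alt[het] <- rbinom(sum(het), ctl_depth[het], 0.5)
    control <- data.frame(contig = contig, position = position, ref = ref,
                          alt = alt, depth = ctl_depth, alt_depth = ctl_alt,
                          gene_strand = strand, stringsAsFactors = FALSE)

    g <- kind == "gfp"
    gfp <- data.frame(contig = contig[g], position = position[g],
                      ref = ref[g], alt = alt[g],
                      depth = rpois(sum(g), params$gfp_depth_mean) +
                        params$min_reads_gfp %||% 10L,
                      alt_depth = 0L, gene_strand = strand[g],
                      stringsAsFactors = FALSE)
    if (nrow(gfp)) gfp$alt_depth <- pmax(rbinom(nrow(gfp), gfp$depth, 0.1), 1L)

    truth <- oe[kind == "true", , drop = FALSE]
    rownames(truth) <- NULL
    list(oe = oe, control = control, gfp = gfp, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
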