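# Shared fixtures and independent oracles. Oracles are deliberately written
# as straight-line/brute-force code, separate from the package's code paths.

FIX_PROTO <- "GACCATAAAGCATAGACTGC"  # A at 2,5,7,8,9,12,14,16; C at 3,4,11,17,20

fix_amplicon <- function(proto = FIX_PROTO, pam = "AGG",
                         left = "ATGCTTGACT", right = "CGATCAGTTC") {
  paste0(left, proto, pam, right)
}

fix_site <- function(proto = FIX_PROTO, ...) {
  locate_protospacer(fix_amplicon(proto, ...), proto, "NGG", name = "fix")
}

reads_from_seqs <- function(seqs, phred_char = "I") {
  amplicon_reads(sprintf("r%03d", seq_along(seqs)), seqs,
                 strrep(phred_char, nchar(seqs)))
}

# substitute `base` at protospacer position `pos` of a plus-strand amplicon
mutate_at <- function(amplicon, site, pos, base) {
  off <- site$positions[[as.character(pos)]] + 1L
  paste0(substr(amplicon, 1L, off - 1L), base,
         substr(amplicon, off + 1L, nchar(amplicon)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Independent score-only semi-global affine DP (plain R, matrices)
oracle_score <- function(read, ref, match = 2, mismatch = -1,
                         gap_open = -6, gap_extend = -1) {
  r <- strsplit(read, "")[[1L]]
  s <- strsplit(ref, "")[[1L]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  H <- matrix(NEG, n + 1L, m + 1L)
  D <- matrix(NEG, n + 1L, m + 1L)  # gap in read (ref consumed)
  I <- matrix(NEG, n + 1L, m + 1L)  # gap in ref (read consumed)
  H[1L, ] <- 0
  for (i in 2L:(n + 1L)) {
    I[i, 1L] <- gap_open + (i - 1L) * gap_extend
    H[i, 1L] <- I[i, 1L]
  }
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      sub <- if (r[i - 1L] == "N" || s[j - 1L] == "N") mismatch
             else if (r[i - 1L] == s[j - 1L]) match else mismatch
      D[i, j] <- max(H[i, j - 1L] + gap_open + gap_extend, D[i, j - 1L] + gap_extend)
      I[i, j] <- max(H[i - 1L, j] + gap_open + gap_extend, I[i - 1L, j] + gap_extend)
      H[i, j] <- max(H[i - 1L, j - 1L] + sub, D[i, j], I[i, j])
    }
  }
  max(H[n + 1L, ])
}

# Brute-force per-allele edit classification
oracle_classify <- function(seq, has_indel, ref_chars, a_pos, c_pos) {
  if (has_indel) return("indel")
  obs <- strsplit(seq, "")[[1L]]
  a <- FALSE
  for (p in a_pos) if (obs[p] == "G") a <- TRUE
  c <- FALSE
  for (p in c_pos) if (obs[p] == "T") c <- TRUE
  if (a && c) "simultaneous"
  else if (a) "only_a2g"
  else if (c) "only_c2t"
  else if (identical(obs, ref_chars)) "unedited"
  else "other_subst"
}

# Straight-line reimplementation of the RNA filter chain
oracle_rna_filter <- function(oe, ctl, gfp, cov_pct = 90, consensus = 0.99,
                              min_gfp = 10L) {
  thr <- as.numeric(quantile(oe$depth, cov_pct / 100))
  keep <- logical(nrow(oe))
  for (i in seq_len(nrow(oe))) {
    j <- which(ctl$contig == oe$contig[i] & ctl$position == oe$position[i])
    if (length(j) == 0L) next
    j <- j[1L]
    if (!(ctl$depth[j] > thr)) next
    if ((ctl$depth[j] - ctl$alt_depth[j]) / ctl$depth[j] < consensus) next
    in_gfp <- any(gfp$depth >= min_gfp & gfp$alt_depth >= 1L &
                    gfp$contig == oe$contig[i] & gfp$position == oe$position[i] &
                    gfp$ref == oe$ref[i] & gfp$alt == oe$alt[i])
    if (in_gfp) next
    if (oe$alt_depth[i] < 1L) next
    keep[i] <- TRUE
  }
  out <- oe[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Full 2^n enumeration of the signed-rank null; same two-sided rule
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(grid, 1L, function(s) sum(r[as.logical(s)]))
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random variant table over a few contigs
rand_variant_table <- function(n, seed = NULL, contigs = c("chr1", "chr2")) {
  if (!is.null(seed)) set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  depth <- sample(5:120, n, TRUE)
  data.frame(contig = sample(contigs, n, TRUE),
             position = sample.int(5000L, n),
             ref = ref, alt = unname(alt), depth = depth,
             alt_depth = vapply(depth, function(d) sample(0:d, 1L), 0L),
             gene_strand = sample(c("+", "-", "unknown"), n, TRUE),
             stringsAsFactors = FALSE)
}
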