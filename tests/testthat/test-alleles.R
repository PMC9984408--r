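test_that("allele tables tally distinct window sequences with sorted counts", {
  site <- fix_site()
  amp <- site$amplicon
  a5g <- mutate_at(amp, site, 5, "G")
  a5g_c11t <- mutate_at(a5g, site, 11, "T")
  reads <- reads_from_seqs(c(rep(amp, 6), rep(a5g, 3), a5g_c11t))
  tab <- allele_table(reads, site)
  expect_equal(tab$n_total, 10L)
  expect_equal(tab$entries$count, c(6L, 3L, 1L))
  expect_equal(sum(tab$entries$count), tab$n_total)
  expect_equal(tab$entries$allele_seq[1], site$protospacer)
  # allele count bounds
  expect_true(nrow(tab$entries) >= 1 && nrow(tab$entries) <= tab$n_total)
})

test_that("reads with a deletion in the window become has_indel alleles", {
  site <- fix_site()
  amp <- site$amplicon
  off <- site$positions[["8"]] + 1L
  del_read <- paste0(substr(amp, 1, off - 1L), substr(amp, off + 1L, nchar(amp)))
  tab <- allele_table(reads_from_seqs(c(amp, del_read)), site)
  expect_true(any(tab$entries$has_indel))
  expect_equal(tab$n_total, 2L)
})

test_that("empty input gives an empty allele table", {
  site <- fix_site()
  proc <- data.frame(id = character(), status = character(), score = numeric(),
                     window_seq = character(), has_indel = logical())
  tab <- allele_table(proc, site)
  expect_equal(tab$n_total, 0L)
  expect_equal(nrow(tab$entries), 0L)
})

test_that("edit classes match definitions and partition all reads", {
  site <- fix_site()
  amp <- site$amplicon
  a5g <- mutate_at(amp, site, 5, "G")
  c11t <- mutate_at(amp, site, 11, "T")
  both <- mutate_at(a5g, site, 11, "T")
  other <- mutate_at(amp, site, 6, "C")  # T6 -> C, not a scored conversion
  off <- site$positions[["8"]] + 1L
  del_read <- paste0(substr(amp, 1, off - 1L), substr(amp, off + 1L, nchar(amp)))
  reads <- reads_from_seqs(c(rep(amp, 3), rep(a5g, 2), c11t, rep(both, 2),
                             other, del_read))
  tab <- allele_table(reads, site)
  cls <- classify_alleles(tab)
  expect_equal(cls$unedited, 3L)
  expect_equal(cls$only_a2g, 2L)
  expect_equal(cls$only_c2t, 1L)
  expect_equal(cls$simultaneous, 2L)
  expect_equal(cls$other_subst, 1L)
  expect_equal(cls$indel, 1L)
  expect_equal(cls$only_a2g + cls$only_c2t + cls$simultaneous + cls$unedited +
                 cls$other_subst + cls$indel, cls$n_total)
})

test_that("classification agrees with a brute-force per-allele oracle", {
  site <- fix_site()
  ref <- proto_bases(site)
  a_pos <- which(ref == "A")
  c_pos <- which(ref == "C")
  set.seed(33)
  model <- editing_model(site, c("5" = 0.5, "8" = 0.4, "11" = 0.45, "4" = 0.3),
                         rho = 0.3, indel_rate = 0.1, error_rate = 0.01,
                         n_reads = 300, seed = 33)
  tab <- allele_table(simulate_reads(model)$reads, site)
  cls <- classify_alleles(tab)
  want <- c(only_a2g = 0L, only_c2t = 0L, simultaneous = 0L, unedited = 0L,
            other_subst = 0L, indel = 0L)
  for (i in seq_len(nrow(tab$entries))) {
    k <- oracle_classify(tab$entries$allele_seq[i], tab$entries$has_indel[i],
                         ref, a_pos, c_pos)
    want[k] <- want[k] + tab$entries$count[i]
  }
  got <- unlist(cls[names(want)])
  expect_equal(got, want)
  # simultaneous cannot exceed either marginal
  any_a <- sum(tab$entries$count[!tab$entries$has_indel &
    vapply(strsplit(tab$entries$allele_seq, ""),
           function(o) any(o[a_pos] == "G"), TRUE)])
  any_c <- sum(tab$entries$count[!tab$entries$has_indel &
    vapply(strsplit(tab$entries$allele_seq, ""),
           function(o) any(o[c_pos] == "T"), TRUE)])
  expect_lte(cls$simultaneous, min(any_a, any_c))
})

test_that("position sets outside the protospacer or off-base are rejected", {
  site <- fix_site()
  tab <- allele_table(reads_from_seqs(rep(site$amplicon, 3)), site)
  expect_error(classify_alleles(tab, a_positions = c(2, 25)), "outside")
  expect_error(classify_alleles(tab, a_positions = 1), "reference-A")
})

test_that("simultaneous_fraction is the percentage of simultaneous reads", {
  cls <- structure(list(only_a2g = 10L, only_c2t = 5L, simultaneous = 33L,
                        unedited = 40L, other_subst = 2L, indel = 10L,
                        n_total = 100L), class = "edit_class_counts")
  expect_equal(simultaneous_fraction(cls), 33)
  cls$simultaneous <- 0L
  expect_equal(simultaneous_fraction(cls), 0)
})

test_that("most efficiently edited position matches an exhaustive scan", {
  site <- fix_site()
  amp <- site$amplicon
  reads <- reads_from_seqs(c(rep(amp, 4),
                             rep(mutate_at(amp, site, 5, "G"), 3),
                             rep(mutate_at(amp, site, 7, "G"), 5),
                             rep(mutate_at(amp, site, 7, "G"), 1)))
  mat <- quantify(reads, site)
  mp <- max_position_efficiency(mat, "A", "G")
  eff <- efficiency(mat, "A", "G")
  best <- which(eff == max(eff, na.rm = TRUE))[1]  # exhaustive argmax
  expect_equal(mp$position, as.integer(names(eff)[best]))
  expect_equal(mp$efficiency, unname(eff[best]))

  set.seed(44)
  for (k in 1:20) {
    counts <- matrix(0L, 20, 6, dimnames = list(1:20, c("A","C","G","T","N","del")))
    ref <- proto_bases(site)
    n <- 50L
    for (i in 1:20) {
      g <- sample(0:n, 1)
      if (ref[i] == "A") { counts[i, "G"] <- g; counts[i, "A"] <- n - g }
      else counts[i, ref[i]] <- n
    }
    m <- structure(list(site = site, counts = counts, n_aligned = n,
                        n_indel_free = n, n_indel = 0L, n_unusable = 0L),
                   class = "editing_matrix")
    eff <- 100 * counts[, "G"] / n
    eff[ref != "A"] <- NA
    want <- which(eff == max(eff, na.rm = TRUE))[1]
    expect_equal(max_position_efficiency(m)$position, as.integer(want))
  }
})

test_that("ties go to the PAM-distal position and no-A matrices error", {
  site <- fix_site(proto = "GACCATAAAGCATAGACTGC")
  n <- 10L
  counts <- matrix(0L, 20, 6, dimnames = list(1:20, c("A","C","G","T","N","del")))
  ref <- proto_bases(site)
  for (i in 1:20) counts[i, ref[i]] <- n
  counts[5, ] <- c(5L, 0L, 5L, 0L, 0L, 0L)   # A5: 50%
  counts[8, ] <- c(5L, 0L, 5L, 0L, 0L, 0L)   # A8: 50% tie
  m <- structure(list(site = site, counts = counts, n_aligned = n,
                      n_indel_free = n, n_indel = 0L, n_unusable = 0L),
                 class = "editing_matrix")
  expect_equal(max_position_efficiency(m)$position, 5L)
  expect_error(max_position_efficiency(m, from = "N", to = "G"), "no editable")
})

test_that("mutant allele types respect the frequency floor", {
  site <- fix_site()
  amp <- site$amplicon
  a5g <- mutate_at(amp, site, 5, "G")
  singleton <- mutate_at(amp, site, 2, "G")
  reads <- reads_from_seqs(c(rep(amp, 500), rep(a5g, 499), singleton))
  tab <- allele_table(reads, site)
  expect_equal(n_allele_types(tab, min_freq = 0.001), 2L)  # both mutants pass
  expect_equal(n_allele_types(tab, min_freq = 0.002), 1L)  # singleton floored out
  expect_equal(n_allele_types(tab, min_freq = 0), 2L)
})
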