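test_that("the simulator is byte-identical under a fixed seed", {
  site <- fix_site()
  model <- editing_model(site, c("5" = 0.4, "11" = 0.3), rho = 0.5,
                         indel_rate = 0.05, error_rate = 0.01,
                         n_reads = 200, seed = 42, adapters = adapter_pair())
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  s1 <- simulate_reads(model, fastq = f1)
  s2 <- simulate_reads(model, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the draw
  model2 <- editing_model(site, c("5" = 0.4, "11" = 0.3), rho = 0.5,
                          indel_rate = 0.05, error_rate = 0.01,
                          n_reads = 200, seed = 43, adapters = adapter_pair())
  expect_false(identical(simulate_reads(model2)$reads$seq, s1$reads$seq))
})

test_that("degenerate models produce exactly what they promise", {
  site <- fix_site()
  clean <- editing_model(site, c("5" = 0), n_reads = 50, seed = 1)
  expect_true(all(simulate_reads(clean)$reads$seq == site$amplicon))

  always <- editing_model(site, c("5" = 1), n_reads = 50, seed = 1)
  sim <- simulate_reads(always)
  expect_true(all(sim$truth$edited_5))
  expect_true(all(substr(sim$reads$seq, site$positions[["5"]] + 1L,
                         site$positions[["5"]] + 1L) == "G"))
  # only position 5 differs from reference
  expect_true(all(vapply(sim$reads$seq, function(s) {
    d <- which(strsplit(s, "")[[1]] != strsplit(site$amplicon, "")[[1]])
    identical(d, as.integer(site$positions[["5"]] + 1L))
  }, TRUE)))
})

test_that("p_edit on a non-editable reference base is rejected", {
  site <- fix_site()  # position 1 is G, position 6 is T
  expect_error(editing_model(site, c("1" = 0.5)), "non-editable")
  expect_error(editing_model(site, c("6" = 0.5)), "non-editable")
})

test_that("re-quantifying error-free simulated reads reproduces the truth table", {
  site <- fix_site()
  model <- editing_model(site, c("5" = 0.35, "8" = 0.6, "11" = 0.25),
                         rho = 0.4, indel_rate = 0.1, error_rate = 0,
                         n_reads = 400, seed = 7)
  sim <- simulate_reads(model)
  mat <- quantify(sim$reads, site)
  indel_free <- !sim$truth$has_indel
  expect_equal(mat$n_indel, sum(sim$truth$has_indel))
  expect_equal(mat$n_indel_free, sum(indel_free))
  for (p in c(5, 8, 11)) {
    want <- sum(sim$truth[[paste0("edited_", p)]][indel_free])
    to <- if (proto_bases(site)[p] == "A") "G" else "T"
    expect_equal(unname(mat$counts[p, to]), want)
  }
  # allele-level truth: simultaneous = any A edit & any C edit per read
  tab <- allele_table(sim$reads, site)
  cls <- classify_alleles(tab)
  tt <- sim$truth[indel_free, ]
  a_edit <- tt$edited_5 | tt$edited_8
  c_edit <- tt$edited_11  # position 11 is a reference C
  expect_equal(cls$simultaneous, sum(a_edit & c_edit))
  expect_equal(cls$only_a2g, sum(a_edit & !c_edit))
  expect_equal(cls$only_c2t, sum(!a_edit & c_edit))
})

test_that("marginal edit frequencies respect the binomial bound", {
  site <- fix_site()
  n <- 3000
  p <- c("5" = 0.1, "8" = 0.5, "11" = 0.85)
  model <- editing_model(site, p, n_reads = n, seed = 13)
  sim <- simulate_reads(model)
  for (k in names(p)) {
    phat <- mean(sim$truth[[paste0("edited_", k)]])
    expect_lt(abs(phat - p[[k]]), 3 * sqrt(p[[k]] * (1 - p[[k]]) / n))
  }
})

test_that("rho interpolates co-editing from independence to full coupling", {
  site <- fix_site()
  n <- 4000
  pA <- 0.5; pC <- 0.3
  ind <- simulate_reads(editing_model(site, c("5" = pA, "11" = pC),
                                      rho = 0, n_reads = n, seed = 17))$truth
  co <- mean(ind$edited_5 & ind$edited_11)
  sd0 <- sqrt(pA * pC * (1 - pA * pC) / n)
  expect_lt(abs(co - pA * pC), 3 * sd0)

  cpl <- simulate_reads(editing_model(site, c("5" = pA, "11" = pC),
                                      rho = 1, n_reads = n, seed = 18))$truth
  co1 <- mean(cpl$edited_5 & cpl$edited_11)
  pmin_ <- min(pA, pC)
  sd1 <- sqrt(pmin_ * (1 - pmin_) / n)
  expect_lt(abs(co1 - pmin_), 3 * sd1)
})

test_that("simulated RNA tables respect their planted structure", {
  sim <- simulate_rna_tables(rna_sim_params(n_true_edits = 0, seed = 3))
  res <- rna_pipeline(sim$oe, sim$control, sim$gfp)
  expect_equal(res$n_sites, 0L)

  sim <- simulate_rna_tables(rna_sim_params(seed = 4))
  expect_equal(nrow(sim$truth), 20L)
  expect_true(all(label_edit_type(sim$truth$ref, sim$truth$alt,
                                  sim$truth$gene_strand) == "A-to-I"))

  # a control locus built to sit just under the consensus threshold is excluded
  oe <- sim$oe[1, , drop = FALSE]
  ctl <- oe
  ctl$depth <- 1000L
  ctl$alt_depth <- 20L  # ref fraction 0.98
  out <- control_confidence_filter(oe, ctl)
  expect_equal(nrow(out), 0L)
})
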