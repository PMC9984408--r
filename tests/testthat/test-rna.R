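test_that("percentile is linear-interpolation with inclusive endpoints", {
  expect_equal(percentile(1:100, 90), 90.1)
  expect_equal(percentile(7, 35), 7)
  expect_equal(percentile(c(4, 9, 2), 100), 9)
  expect_equal(percentile(c(4, 9, 2), 0), 2)
  # matches a sort-and-interpolate computation
  set.seed(1)
  v <- rnorm(37)
  s <- sort(v)
  h <- (length(v) - 1) * 0.9 + 1
  expect_equal(percentile(v, 90), s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)]))
})

test_that("control consensus boundary excludes 0.98 and keeps 1.00", {
  oe <- data.frame(contig = "chr1", position = c(100L, 200L), ref = "A",
                   alt = "G", depth = c(50L, 50L), alt_depth = c(5L, 5L),
                   gene_strand = "+", stringsAsFactors = FALSE)
  ctl <- data.frame(contig = "chr1", position = c(100L, 200L), ref = "A",
                    alt = "G", depth = c(100L, 100L), alt_depth = c(0L, 2L),
                    gene_strand = "+", stringsAsFactors = FALSE)
  out <- control_confidence_filter(oe, ctl)
  expect_equal(out$position, 100L)           # 0.98 < 0.99 consensus: dropped
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["low_consensus"]), 1L)
  # exactly 0.99 is kept ("at least 99%")
  ctl$alt_depth <- c(0L, 1L)
  expect_equal(nrow(control_confidence_filter(oe, ctl)), 2L)
})

test_that("control depth must exceed the coverage percentile of the OE table", {
  oe <- data.frame(contig = "chr1", position = 1:10 * 10L, ref = "A", alt = "G",
                   depth = c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L),
                   alt_depth = 1L, gene_strand = "+", stringsAsFactors = FALSE)
  thr <- percentile(oe$depth, 90)  # 91
  ctl <- oe
  ctl$alt_depth <- 0L
  ctl$depth <- rep(c(91L, 92L), 5)  # at vs above the threshold
  out <- control_confidence_filter(oe, ctl)
  expect_equal(out$position, oe$position[ctl$depth > thr])
})

test_that("loci absent from the control are excluded and counted", {
  oe <- data.frame(contig = "chr1", position = c(1L, 2L), ref = "A", alt = "G",
                   depth = 10L, alt_depth = 1L, gene_strand = "+",
                   stringsAsFactors = FALSE)
  ctl <- oe[1, ]
  ctl$alt_depth <- 0L
  ctl$depth <- 500L
  out <- control_confidence_filter(oe, ctl)
  expect_equal(out$position, 1L)
  expect_equal(unname(attr(out, "filter_counts")["no_control"]), 1L)
})

test_that("GFP background keeps loci with >= 10 reads and any alt reads", {
  v <- data.frame(contig = "chr1", position = 1:4, ref = "A", alt = "G",
                  depth = c(9L, 10L, 10L, 200L), alt_depth = c(5L, 1L, 0L, 1L),
                  gene_strand = "+", stringsAsFactors = FALSE)
  out <- gfp_background_filter(v)
  expect_equal(out$position, c(2L, 4L))  # depth 9 out; alt 0 out
})

test_that("edit-type labels follow the strand-aware rules", {
  expect_equal(label_edit_type("A", "G", "+"), "A-to-I")
  expect_equal(label_edit_type("T", "C", "-"), "A-to-I")
  expect_equal(label_edit_type("C", "T", "+"), "C-to-U")
  expect_equal(label_edit_type("G", "A", "-"), "C-to-U")
  expect_equal(label_edit_type("A", "G", "-"), "other")
  expect_equal(label_edit_type("T", "C", "+"), "other")
  expect_equal(label_edit_type("A", "G", "unknown"), "other")
  expect_equal(label_edit_type("A", "C", "+"), "other")
})

test_that("the filter chain equals a straight-line oracle on random tables", {
  for (seed in 1:5) {
    oe <- rand_variant_table(100, seed = seed)
    ctl <- oe
    set.seed(seed + 1000)
    ctl$depth <- sample(5:500, 100, TRUE)
    ctl$alt_depth <- vapply(ctl$depth, function(d) sample(0:min(d, 5), 1L), 0L)
    ctl <- ctl[sample(1:100, 85), ]  # some loci missing from the control
    gfp <- rand_variant_table(40, seed = seed + 2000)
    gfp$contig <- oe$contig[1:40]; gfp$position <- oe$position[1:40]
    gfp$ref <- oe$ref[1:40]; gfp$alt <- oe$alt[1:40]
    got <- rna_pipeline(oe, ctl, gfp)
    want <- oracle_rna_filter(oe, ctl, gfp)
    expect_equal(got$sites[names(oe)], want, info = paste("seed", seed))
    expect_equal(got$n_sites, nrow(want))
    if (got$n_sites > 0) {
      expect_equal(got$mean_efficiency, mean(want$alt_depth / want$depth))
    }
  }
})

test_that("the pipeline is invariant to input row order", {
  oe <- rand_variant_table(60, seed = 9)
  ctl <- oe
  ctl$depth <- oe$depth * 10L
  ctl$alt_depth <- 0L
  gfp <- oe[1:10, ]
  gfp$depth <- 50L
  gfp$alt_depth <- 2L
  a <- rna_pipeline(oe, ctl, gfp)
  set.seed(10)
  perm <- sample(nrow(oe))
  b <- rna_pipeline(oe[perm, ], ctl[sample(nrow(ctl)), ], gfp[sample(nrow(gfp)), ])
  keyfun <- function(d) paste(d$contig, d$position, d$ref, d$alt)
  expect_setequal(keyfun(a$sites), keyfun(b$sites))
  expect_equal(a$n_sites, b$n_sites)
})

test_that("tightening thresholds never enlarges the retained set", {
  oe <- rand_variant_table(80, seed = 21)
  ctl <- oe
  set.seed(22)
  ctl$depth <- sample(50:400, 80, TRUE)
  ctl$alt_depth <- vapply(ctl$depth, function(d) sample(0:3, 1L), 0L)
  gfp <- rand_variant_table(20, seed = 23)
  base <- rna_pipeline(oe, ctl, gfp)
  keyfun <- function(d) paste(d$contig, d$position, d$ref, d$alt)
  for (p in list(rna_filter_params(coverage_percentile = 95),
                 rna_filter_params(control_ref_consensus = 0.999),
                 rna_filter_params(min_reads_gfp = 5L))) {
    tight <- rna_pipeline(oe, ctl, gfp, p)
    expect_true(all(keyfun(tight$sites) %in% keyfun(base$sites)) ||
                  p$min_reads_gfp < 10L)
    if (p$min_reads_gfp < 10L) {
      # a looser GFP gate subtracts more background: retained set cannot grow
      expect_lte(tight$n_sites, base$n_sites)
    }
  }
})

test_that("planted edits are fully recovered with clean controls", {
  sim <- simulate_rna_tables(rna_sim_params(n_true_edits = 20, seed = 5))
  res <- rna_pipeline(sim$oe, sim$control, sim$gfp)
  keyfun <- function(d) paste(d$contig, d$position, d$ref, d$alt)
  expect_setequal(keyfun(res$sites), keyfun(sim$truth))  # recall 1, FP 0
  expect_true(all(res$sites$edit_type == "A-to-I"))
  expect_equal(res$n_sites, 20L)
})

test_that("OE loci that all sit in the GFP background give zero sites", {
  oe <- data.frame(contig = "chr1", position = 1:5, ref = "A", alt = "G",
                   depth = 50L, alt_depth = 5L, gene_strand = "+",
                   stringsAsFactors = FALSE)
  ctl <- oe; ctl$depth <- 1000L; ctl$alt_depth <- 0L
  gfp <- oe; gfp$depth <- 100L; gfp$alt_depth <- 3L
  res <- rna_pipeline(oe, ctl, gfp)
  expect_equal(res$n_sites, 0L)
})

test_that("variant TSV round-trips through read_variants with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  v <- rand_variant_table(10, seed = 31)
  write.table(v, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_variants(f)
  expect_equal(got, v)
  v$alt_depth[1] <- v$depth[1] + 5L
  write.table(v, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variants(f), "alt_depth")
})
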