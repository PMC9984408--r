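#' Run the amplicon quantification pipeline end to end
#'
#' Orchestrates simulate (optional) -> trim/QC/align -> per-position
#' quantification -> allele classification -> report for one target site, and
#' optionally the RNA off-target filtering stage. All outputs (TSV/JSON, a
#' parameter/count log, and a Markdown report) are written under
#' `config$out_dir`; none of them embeds a timestamp, so a rerun with the same
#' configuration and seed is file-identical. On a stage failure the partial
#' outputs are kept and `MANIFEST.txt` records the failure point.
#'
#' @param config a list (or path to a JSON file) with components:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{integer seed forwarded to the simulator.}
#'     \item{target}{list `name`, `amplicon`, `protospacer`, `pam`.}
#'     \item{simulate}{optional list of [editing_model()] arguments
#'       (`p_edit`, `rho`, `indel_rate`, `error_rate`, `n_reads`); when absent,
#'       `fastq` must point to an existing FASTQ file.}
#'     \item{fastq}{optional path to input reads (ignored when simulating).}
#'     \item{trim}{logical; trim the default library adapters (default TRUE
#'       when simulating — simulated reads carry them — else FALSE).}
#'     \item{conversions}{character vector like `c("A:G", "C:T")`.}
#'     \item{windows}{optional character vector like `c("2-9", "10-15")`.}
#'     \item{rna}{optional list of paths `oe`, `control`, `gfp` (TSV/VCF).}
#'   }
#' @return (invisibly) a list with the `editing_matrix`, `allele_table`,
#'   `edit_class_counts`, optional `rna_edit_summary`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "MANIFEST.txt")
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- "configure"

  result <- tryCatch({
    jsonlite::write_json(.config_for_echo(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    tg <- config$target
    site <- locate_protospacer(tg$amplicon, tg$protospacer,
                               tg$pam %||% "NGG", name = tg$name %||% "site")
    note("target: ", site$name, " strand ", site$strand,
         " protospacer length ", nchar(site$protospacer))

    stage <- "reads"
    trim <- config$trim
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      p_edit <- unlist(sim$p_edit)
      model <- editing_model(site, p_edit,
                             rho = sim$rho %||% 0,
                             indel_rate = sim$indel_rate %||% 0,
                             error_rate = sim$error_rate %||% 0,
                             n_reads = sim$n_reads %||% 1000L,
                             seed = config$seed %||% 1L,
                             adapters = adapter_pair())
      simres <- simulate_reads(model,
                               fastq = file.path(out_dir, "simulated.fastq"),
                               truth_tsv = file.path(out_dir, "truth.tsv"))
      reads <- simres$reads
      if (is.null(trim)) trim <- TRUE
      note("simulated ", length(reads), " reads (seed ", model$seed, ")")
    } else {
      if (is.null(config$fastq)) stop("config needs either $simulate or $fastq")
      reads <- read_fastq(config$fastq)
      if (is.null(trim)) trim <- FALSE
      note("read ", length(reads), " reads from ", config$fastq)
    }
    if (length(reads) == 0L) stop("no usable reads")

    stage <- "quantify"
    adapters <- if (isTRUE(trim)) adapter_pair() else NULL
    proc <- process_reads(reads, site, adapters = adapters)
    mat <- quantify(proc, site)
    note("aligned: ", mat$n_aligned, " (indel-free ", mat$n_indel_free,
         ", indel ", mat$n_indel, ", unusable ", mat$n_unusable, ")")
    conversions <- lapply(config$conversions %||% c("A:G"),
                          function(s) strsplit(s, ":")[[1L]])
    write_matrix_tsv(mat, file.path(out_dir, "editing_matrix.tsv"), conversions)

    stage <- "alleles"
    tab <- allele_table(proc, site)
    cls <- classify_alleles(tab)
    ent <- tab$entries
    ent$class <- vapply(seq_len(nrow(ent)), function(i) {
      .classify_one(ent$allele_seq[i], ent$has_indel[i], proto_bases(site),
                    which(proto_bases(site) == "A"),
                    which(proto_bases(site) == "C"))
    }, character(1))
    write.table(ent, file.path(out_dir, "alleles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(cls), file.path(out_dir, "classes.json"),
                         auto_unbox = TRUE, digits = NA)
    note("alleles: ", nrow(ent), " distinct; simultaneous fraction ",
         sprintf("%.4f%%", simultaneous_fraction(cls)))

    stage <- "rna"
    rna <- NULL
    if (!is.null(config$rna)) {
      rna <- rna_pipeline(read_variants(config$rna$oe),
                          read_variants(config$rna$control),
                          read_variants(config$rna$gfp))
      jsonlite::write_json(list(n_sites = rna$n_sites,
                                mean_efficiency = rna$mean_efficiency,
                                by_type = as.list(rna$by_type),
                                filter_log = as.list(rna$filter_log)),
                           file.path(out_dir, "rna_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      note("rna filter: ", paste(names(rna$filter_log), rna$filter_log,
                                 sep = "=", collapse = " -> "))
    }

    stage <- "report"
    windows <- lapply(config$windows %||% character(), function(s) {
      r <- as.integer(strsplit(s, "-")[[1L]])
      window_spec(s, seq(r[1L], r[2L]))
    })
    .write_report(file.path(out_dir, "report.md"), site, mat, cls, tab,
                  conversions, windows, rna)
    writeLines(log_lines, log_path)
    writeLines(c("status: ok", paste0("stage: ", stage),
                 paste0("files: ", paste(sort(setdiff(list.files(out_dir),
                                                      "MANIFEST.txt")),
                                         collapse = ", "))),
               manifest)
    invisible(list(matrix = mat, alleles = tab, classes = cls, rna = rna,
                   out_dir = out_dir))
  }, error = function(e) {
    writeLines(log_lines, log_path)
    writeLines(c("status: failed", paste0("stage: ", stage),
                 paste0("error: ", conditionMessage(e))), manifest)
    stop(e)
  })
  result
}

# drop non-serializable entries, keep a stable echo of the configuration
.config_for_echo <- function(config) {
  config[order(names(config))]
}

.write_report <- function(path, site, mat, cls, tab, conversions, windows, rna) {
  ln <- c(
    paste0("# Base-editing outcome report: ", site$name), "",
    paste0("Protospacer `", site$protospacer, "` (", site$strand,
           " strand, PAM ", site$pam, "); positions numbered 1 (PAM-distal) to ",
           nchar(site$protospacer), " (PAM-proximal)."), "",
    "## Read accounting", "",
    paste0("- aligned: ", mat$n_aligned),
    paste0("- indel-free: ", mat$n_indel_free),
    paste0("- with indel in window: ", mat$n_indel,
           sprintf(" (indel frequency %.3f%%)", indel_frequency(mat))),
    paste0("- unusable: ", mat$n_unusable), "",
    "## Per-position efficiency", "")
  for (cv in conversions) {
    eff <- efficiency(mat, cv[1L], cv[2L])
    ed <- which(!is.na(eff))
    ln <- c(ln, paste0("### ", cv[1L], "-to-", cv[2L]), "",
            "| position | efficiency (%) |", "|---:|---:|",
            sprintf("| %s%d | %.3f |", cv[1L], ed, eff[ed]), "")
    if (length(ed)) {
      mp <- max_position_efficiency(mat, cv[1L], cv[2L])
      ln <- c(ln, sprintf("Most efficiently edited position: %s%d (%.3f%%).",
                          cv[1L], mp$position, mp$efficiency), "")
    }
  }
  if (length(windows)) {
    ln <- c(ln, "## Window summaries", "")
    for (w in windows) {
      for (cv in conversions) {
        eff <- list(efficiency(mat, cv[1L], cv[2L]))
        names(eff) <- site$name
        ws <- window_summary(eff, w)
        val <- if (length(ws$per_site)) sprintf("%.3f", ws$per_site[[1L]]) else "no editable position"
        ln <- c(ln, paste0("- ", cv[1L], "-to-", cv[2L], " positions ",
                           w$label, ": ", val))
      }
    }
    ln <- c(ln, "")
  }
  ln <- c(ln, "## Allele composition", "",
          sprintf("- only A-to-G: %d (%.3f%%)", cls$only_a2g,
                  100 * cls$only_a2g / cls$n_total),
          sprintf("- only C-to-T: %d (%.3f%%)", cls$only_c2t,
                  100 * cls$only_c2t / cls$n_total),
          sprintf("- simultaneous A-to-G and C-to-T: %d (%.3f%%)",
                  cls$simultaneous, simultaneous_fraction(cls)),
          sprintf("- unedited: %d; other substitutions: %d; indel: %d",
                  cls$unedited, cls$other_subst, cls$indel),
          sprintf("- mutant allele types (>= 0.1%% frequency): %d",
                  n_allele_types(tab)), "")
  if (!is.null(rna)) {
    ln <- c(ln, "## RNA off-target filtering", "",
            sprintf("- retained edit sites: %d", rna$n_sites),
            sprintf("- mean editing fraction: %s",
                    ifelse(is.na(rna$mean_efficiency), "NA",
                           sprintf("%.4f", rna$mean_efficiency))),
            paste0("- by type: ", paste(names(rna$by_type), rna$by_type,
                                        sep = "=", collapse = ", ")),
            paste0("- filter steps: ", paste(names(rna$filter_log),
                                             rna$filter_log, sep = "=",
                                             collapse = " -> ")), "")
  }
  ln <- c(ln,
          "Statistics reported here are limited to those of the study design ",
          "(means and medians over sites, t tests, signed-rank tests); no ",
          "multiple-testing correction is applied.")
  writeLines(ln, path)
}
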