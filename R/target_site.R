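#' Locate a protospacer (and its PAM) inside an amplicon reference
#'
#' Searches both strands of the amplicon for the protospacer and verifies that
#' the PAM (IUPAC-aware, e.g. `NGG`) lies immediately 3' of it on the matched
#' strand. Protospacer positions are numbered 1 (PAM-distal) to
#' `nchar(protospacer)` (PAM-proximal) regardless of strand, so downstream
#' per-position counts are strand-invariant.
#'
#' @param amplicon amplicon reference sequence (one string, A/C/G/T/N).
#' @param protospacer protospacer sequence, 5'->3' (typically 20 nt).
#' @param pam PAM motif immediately 3' of the protospacer (IUPAC codes allowed).
#' @param name optional site label.
#' @return a `target_site` object with components `name`, `amplicon`,
#'   `protospacer`, `pam`, `strand` (`"+"` or `"-"`), `proto_start` (0-based
#'   half-open start of the protospacer match in amplicon coordinates), and
#'   `positions` (integer vector: protospacer position i -> 0-based amplicon
#'   offset of the base carrying that position).
#' @export
#' @examples
#' amp <- paste0("TTTTTTTTTT", "GAACACAAAGCATAGACTGC", "AGGTTTTTTTTTT")
#' locate_protospacer(amp, "GAACACAAAGCATAGACTGC", "NGG")
locate_protospacer <- function(amplicon, protospacer, pam = "NGG", name = "site") {
  amplicon <- toupper(amplicon)
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  L <- nchar(protospacer)
  npam <- nchar(pam)
  amp <- Biostrings::DNAString(amplicon)

  pam_ok <- function(seen) {
    if (nchar(seen) != npam) return(FALSE)
    length(Biostrings::matchPattern(Biostrings::DNAString(pam),
                                    Biostrings::DNAString(seen),
                                    fixed = FALSE)) > 0L
  }

  hits <- list()
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(protospacer), amp)
  for (s in BiocGenerics::start(fwd)) {        # 1-based
    pam_seen <- substr(amplicon, s + L, s + L + npam - 1L)
    if (pam_ok(pam_seen)) hits[[length(hits) + 1L]] <- list(strand = "+", start = s - 1L)
  }
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(protospacer)), amp)
  for (s in BiocGenerics::start(rev)) {
    # PAM sits 3' of the protospacer on the minus strand: amplicon bases just
    # 5' of the hit, read as revcomp
    if (s - npam < 1L) next
    pam_seen <- revcomp(substr(amplicon, s - npam, s - 1L))
    if (pam_ok(pam_seen)) hits[[length(hits) + 1L]] <- list(strand = "-", start = s - 1L)
  }

  if (length(hits) == 0L) stop("protospacer not found in amplicon (either strand, with PAM '", pam, "')")
  if (length(hits) > 1L) stop("ambiguous target: protospacer+PAM occurs ", length(hits), " times")

  h <- hits[[1L]]
  positions <- if (h$strand == "+") {
    h$start + seq_len(L) - 1L
  } else {
    h$start + L - seq_len(L)
  }
  names(positions) <- seq_len(L)
  structure(list(name = name, amplicon = amplicon, protospacer = protospacer,
                 pam = pam, strand = h$strand, proto_start = h$start,
                 positions = positions),
            class = "target_site")
}

#' Reference base at each protospacer position (protospacer orientation)
#'
#' @param site a `target_site`.
#' @return character vector of length `nchar(protospacer)`.
#' @export
proto_bases <- function(site) {
  stopifnot(inherits(site, "target_site"))
  strsplit(site$protospacer, "")[[1L]]
}

#' @export
print.target_site <- function(x, ...) {
  cat("<target_site> ", x$name, "\n", sep = "")
  cat("  amplicon:    ", nchar(x$amplicon), " nt\n", sep = "")
  cat("  protospacer: ", x$protospacer, " (", x$strand, " strand, PAM ",
      x$pam, ")\n", sep = "")
  cat("  amplicon offsets ", min(x$positions), "..", max(x$positions),
      " (0-based)\n", sep = "")
  invisible(x)
}

#' Read a target configuration file
#'
#' Accepts a TSV (columns `name`, `amplicon`, `protospacer`, `pam`) or a JSON
#' array of objects with those fields, and resolves each row with
#' [locate_protospacer()].
#'
#' @param path configuration file path (`.tsv`/`.txt` or `.json`).
#' @return named list of `target_site` objects.
#' @export
read_target_config <- function(path) {
  if (!file.exists(path)) stop("target config not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "amplicon", "protospacer", "pam")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("target config missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sites <- lapply(seq_len(nrow(df)), function(i) {
    locate_protospacer(df$amplicon[i], df$protospacer[i], df$pam[i], name = df$name[i])
  })
  names(sites) <- df$name
  sites
}
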