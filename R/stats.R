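#' Editing-window specification
#'
#' A labelled set of protospacer positions, e.g. the canonical window
#' (positions 2-9) or the PAM-proximal window (10-15).
#'
#' @param label window label, e.g. `"A2-A9"`.
#' @param positions integer vector of protospacer positions.
#' @return a `window_spec`.
#' @export
window_spec <- function(label, positions) {
  positions <- as.integer(positions)
  stopifnot(length(positions) > 0L, all(positions >= 1L))
  structure(list(label = label, positions = sort(unique(positions))),
            class = "window_spec")
}

#' Per-site window means and a cross-site summary
#'
#' Each site contributes the mean efficiency over its editable positions
#' (non-`NA` entries of its efficiency vector) inside the window; sites with no
#' editable position in the window are skipped and reported. The cross-site
#' summary is the median, minimum and maximum of the per-site values.
#'
#' @param per_site_efficiencies named list: site -> per-position efficiency
#'   vector as returned by [efficiency()] (NA at non-editable positions).
#' @param window a [window_spec()].
#' @return list with `window`, `per_site` (named numeric), `skipped` (names of
#'   sites with no editable position in the window), `median`, `min`, `max`.
#' @export
window_summary <- function(per_site_efficiencies, window) {
  stopifnot(inherits(window, "window_spec"))
  vals <- vapply(per_site_efficiencies, function(eff) {
    w <- window$positions[window$positions <= length(eff)]
    v <- eff[w]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  skipped <- names(vals)[is.na(vals)]
  vals <- vals[!is.na(vals)]
  list(window = window$label, per_site = vals, skipped = skipped,
       median = if (length(vals)) stats::median(vals) else NA_real_,
       min = if (length(vals)) min(vals) else NA_real_,
       max = if (length(vals)) max(vals) else NA_real_)
}

#' Exact / approximate Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired values. Zero differences are dropped
#' (if all differences are zero the test is degenerate and p = 1). For `n <=
#' exact_limit` remaining pairs the null distribution of the signed-rank
#' statistic W (sum of ranks of positive differences, average ranks for ties)
#' is computed exactly by convolution over all 2^n sign assignments; beyond
#' that a normal approximation with continuity and tie correction is used.
#'
#' @param x,y paired numeric vectors (`y` omitted: `x` are the differences).
#' @param exact_limit largest n for which the exact null is enumerated.
#' @return list with `statistic` (W), `n` (non-zero pairs), `p.value`,
#'   `method` ("exact" or "normal").
#' @export
#' @examples
#' signed_rank_test(c(2, 3, 1, 4, 2.5, 5), rep(0, 6))$p.value  # 2/2^6
signed_rank_test <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else x - y
  stopifnot(is.numeric(d))
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n = 0L, p.value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of sum(S_i * r_i), S_i iid Bernoulli(1/2); ranks doubled so
    # tied (half-integer) ranks convolve on an integer lattice
    r2 <- as.integer(round(2 * r))
    f <- numeric(sum(r2) + 1L)
    f[1L] <- 1
    for (ri in r2) {
      g <- f
      f[(ri + 1L):length(f)] <- f[(ri + 1L):length(f)] + g[seq_len(length(f) - ri)]
    }
    probs <- f / 2^n
    w2 <- round(2 * W)
    support <- seq_along(probs) - 1L
    p_le <- sum(probs[support <= w2])
    p_ge <- sum(probs[support >= w2])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = W, n = n, p.value = p, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  list(statistic = W, n = n, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Compare two editors position-by-position and window-by-window
#'
#' Inputs are per-site efficiency matrices for two editors over the same sites
#' and positions: for each editor a named list mapping site -> (L positions x
#' n replicates) matrix of per-position efficiencies (`NA` at non-editable
#' positions). Per position, the comparison reports each editor's cross-site
#' mean (of per-site replicate means), the fold change `mean(Y)/mean(X)` (`NA`
#' where `mean(X)` is 0), and a two-tailed two-sample t-test on the per-site
#' replicate means. Per window, per-site window means are compared with the
#' two-sided paired Wilcoxon signed-rank test ([signed_rank_test()]).
#'
#' @param summaries_x,summaries_y named lists of per-site efficiency matrices
#'   (same site names; rows = protospacer positions, columns = replicates).
#'   Plain vectors are accepted as single-replicate matrices.
#' @param windows list of [window_spec()]s for the window-level comparison.
#' @param paired_by_site logical; pair sites across editors for the window
#'   test (the default and the only supported design; kept as an argument to
#'   make the pairing explicit).
#' @return an `editor_comparison`: `per_position` data frame (`position`,
#'   `mean_x`, `mean_y`, `fold`, `t_p`), `per_window` data frame (`window`,
#'   `n_sites`, `median_x`, `median_y`, `wilcoxon_p`).
#' @export
compare_editors <- function(summaries_x, summaries_y, windows = list(),
                            paired_by_site = TRUE) {
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 1L)
  summaries_x <- lapply(summaries_x, as_mat)
  summaries_y <- lapply(summaries_y, as_mat)
  sites <- names(summaries_x)
  if (!setequal(sites, names(summaries_y))) {
    stop("the two editors must cover the same sites")
  }
  summaries_y <- summaries_y[sites]
  L <- nrow(summaries_x[[1L]])

  # per-site replicate means: sites x positions
  site_means <- function(s) t(vapply(s, function(m) rowMeans(m, na.rm = TRUE),
                                     numeric(L)))
  mx <- site_means(summaries_x)
  my <- site_means(summaries_y)

  per_position <- data.frame(position = seq_len(L), mean_x = NA_real_,
                             mean_y = NA_real_, fold = NA_real_, t_p = NA_real_)
  for (p in seq_len(L)) {
    xv <- mx[, p][!is.nan(mx[, p]) & !is.na(mx[, p])]
    yv <- my[, p][!is.nan(my[, p]) & !is.na(my[, p])]
    if (!length(xv) || !length(yv)) next
    per_position$mean_x[p] <- mean(xv)
    per_position$mean_y[p] <- mean(yv)
    if (per_position$mean_x[p] > 0) {
      per_position$fold[p] <- per_position$mean_y[p] / per_position$mean_x[p]
    }
    if (length(xv) > 1L && length(yv) > 1L &&
        (stats::var(xv) > 0 || stats::var(yv) > 0)) {
      per_position$t_p[p] <- stats::t.test(xv, yv)$p.value
    } else if (length(xv) > 1L && length(yv) > 1L) {
      per_position$t_p[p] <- 1  # identical constant groups
    }
  }

  per_window <- data.frame(window = character(), n_sites = integer(),
                           median_x = numeric(), median_y = numeric(),
                           wilcoxon_p = numeric(), stringsAsFactors = FALSE)
  for (w in windows) {
    effs_x <- lapply(sites, function(s) {
      v <- rowMeans(summaries_x[[s]], na.rm = TRUE); v[is.nan(v)] <- NA; v
    })
    effs_y <- lapply(sites, function(s) {
      v <- rowMeans(summaries_y[[s]], na.rm = TRUE); v[is.nan(v)] <- NA; v
    })
    names(effs_x) <- names(effs_y) <- sites
    wx <- window_summary(effs_x, w)
    wy <- window_summary(effs_y, w)
    common <- intersect(names(wx$per_site), names(wy$per_site))
    p <- if (length(common)) {
      signed_rank_test(wy$per_site[common], wx$per_site[common])$p.value
    } else NA_real_
    per_window <- rbind(per_window, data.frame(
      window = w$label, n_sites = length(common),
      median_x = wx$median, median_y = wy$median,
      wilcoxon_p = p, stringsAsFactors = FALSE))
  }
  structure(list(per_position = per_position, per_window = per_window,
                 sites = sites),
            class = "editor_comparison")
}

#' @export
print.editor_comparison <- function(x, ...) {
  cat("<editor_comparison> ", length(x$sites), " sites\n", sep = "")
  pp <- x$per_position[!is.na(x$per_position$mean_x), , drop = FALSE]
  pp[, -1] <- round(pp[, -1], 4)
  print(pp, row.names = FALSE)
  if (nrow(x$per_window)) {
    cat("windows:\n")
    print(x$per_window, row.names = FALSE)
  }
  invisible(x)
}
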