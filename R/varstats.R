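# Three-level variance profiling and the permutation D statistic.
#
# S1 pools lambda differences over all ordered pairs of individuals (G1),
# S2 over the tissue sections of one individual (G2), S3 over technical
# replicates of one section (G3).  Their spread decomposes the observed
# variation into individual, anatomic, and technical components.  The per
# gene D statistic aggregates squared lambda differences over the design's
# arrows; its null distribution under a chosen variance level is obtained
# by resampling that level's S-series.

#' Build a differential-expression series
#'
#' Pools `lambda[i] - lambda[j]` over every ordered pair `i != j` of the
#' group's samples, over every gene with complete values. Ordered pairs
#' include both signs, so the series is symmetric about zero by
#' construction.
#'
#' @param lambda_tab genes x sample-labels matrix, typically
#'   [composite_lambda()] output.
#' @param group character vector of at least two sample labels.
#' @param level optional label (`"individual"`, `"anatomic"`,
#'   `"technical"`) recorded on the result.
#' @return An object of class `diff_series`: `values`, `level`, `n_genes`,
#'   `n_samples`.
#' @export
build_series <- function(lambda_tab, group, level = NA_character_) {
  if (length(group) < 2L)
    stop("group must contain at least 2 samples, got ", length(group))
  missing <- setdiff(group, colnames(lambda_tab))
  if (length(missing))
    stop("unknown sample label(s): ", paste(missing, collapse = ", "))
  sub <- lambda_tab[, group, drop = FALSE]
  complete <- stats::complete.cases(sub)
  sub <- sub[complete, , drop = FALSE]
  k <- length(group)
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$i != pairs$j, ]
  values <- as.vector(sub[, pairs$i, drop = FALSE] -
                      sub[, pairs$j, drop = FALSE])
  structure(list(values = values, level = level, n_genes = nrow(sub),
                 n_samples = k),
            class = "diff_series")
}

#' @export
print.diff_series <- function(x, ...) {
  cat("Differential-expression series",
      if (!is.na(x$level)) paste0("(", x$level, ")"), "\n")
  cat(sprintf("  %d values: %d genes x %d ordered pairs of %d samples\n",
              length(x$values), x$n_genes,
              x$n_samples * (x$n_samples - 1L), x$n_samples))
  cat(sprintf("  SD %.4f, IQR %.4f\n", stats::sd(x$values),
              stats::IQR(x$values)))
  invisible(x)
}

#' Summarize a differential-expression series
#'
#' @param series a `diff_series`.
#' @param bins number of histogram bins, laid out symmetrically about zero.
#' @return list with `sd` (sample SD), `iqr`, and `histogram` (breaks,
#'   counts, density).
#' @export
series_summary <- function(series, bins = 50L) {
  v <- series$values
  if (!length(v)) stop("empty series")
  r <- max(abs(v))
  if (r == 0) r <- 1
  breaks <- seq(-r, r, length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(sd = stats::sd(v), iqr = stats::IQR(v),
       histogram = list(breaks = h$breaks, counts = h$counts,
                        density = h$density))
}

#' @export
plot.diff_series <- function(x, bins = 80L, ...) {
  s <- series_summary(x, bins = bins)
  graphics::plot(s$histogram$breaks,
                 c(s$histogram$density, 0), type = "s",
                 xlab = "log2 differential expression", ylab = "density",
                 main = if (!is.na(x$level))
                   paste("Series:", x$level) else "Series", ...)
  invisible(x)
}

#' Per-gene D statistic over the design's arrows
#'
#' `D = (1/n) * sum over arrows (lambda[i] - lambda[j])^2`, where `(i, j)`
#' are the tail/head samples of each dual-color array and `n` the number of
#' arrows. An absolute-difference variant (`(1/n) * sum |lambda_i -
#' lambda_j|`) is available for sensitivity analysis.
#'
#' @param lambda named numeric vector of one gene's sample values, or a
#'   genes x samples matrix for vectorized use.
#' @param arrows data frame with columns `tail`, `head` (sample labels), or
#'   a `loop_design` (its arrays are used).
#' @param method `"mean_square"` (default) or `"mean_abs"`.
#' @return A nonnegative D per gene (`NA` where any lambda is missing).
#' @export
d_statistic <- function(lambda, arrows, method = c("mean_square", "mean_abs")) {
  method <- match.arg(method)
  if (inherits(arrows, "loop_design")) arrows <- arrows$arrays
  if (!nrow(arrows)) stop("need at least one arrow")
  if (is.null(dim(lambda))) lambda <- matrix(lambda, 1L,
                                             dimnames = list(NULL,
                                                             names(lambda)))
  missing <- setdiff(unique(c(arrows$tail, arrows$head)), colnames(lambda))
  if (length(missing))
    stop("lambda missing for sample(s): ", paste(missing, collapse = ", "))
  d <- lambda[, arrows$tail, drop = FALSE] - lambda[, arrows$head, drop = FALSE]
  if (method == "mean_square") rowMeans(d^2) else rowMeans(abs(d))
}

#' Averaged fold change across individuals
#'
#' `AFC = 2^(mean over unordered sample pairs of |lambda_i - lambda_j|)`,
#' the fold-change indicator of individual variance; 1 when all samples
#' agree.
#'
#' @param lambda named vector for one gene, or genes x samples matrix
#'   (columns restricted to the individual-level group before calling).
#' @return AFC per gene, `>= 1`; `NA` where any sample value is missing.
#' @export
averaged_fold_change <- function(lambda) {
  if (is.null(dim(lambda))) lambda <- matrix(lambda, 1L)
  k <- ncol(lambda)
  if (k < 2L) stop("need at least 2 samples")
  pairs <- utils::combn(k, 2L)
  absd <- abs(lambda[, pairs[1L, ], drop = FALSE] -
              lambda[, pairs[2L, ], drop = FALSE])
  2^rowMeans(absd)
}

#' Permutation null distribution of the D statistic
#'
#' Each draw samples `n` values uniformly with replacement from the pooled
#' series and aggregates them exactly as [d_statistic()] does (mean of
#' squares by default). A Gaussian-kernel density with Silverman's
#' bandwidth is recorded for smoothed tail p-values.
#'
#' @param series a `diff_series` (e.g. S2 for the anatomic null, S3 for the
#'   technical null).
#' @param n number of differences per draw — the design's arrow count.
#' @param B number of permutation draws (>= 1000).
#' @param seed integer seed.
#' @param method aggregation, matching [d_statistic()].
#' @return An object of class `null_distribution`: `draws`, `B`, `n`,
#'   `bandwidth`, `level`, `seed`, `method`.
#' @export
permutation_null <- function(series, n, B = 1e5, seed = 1L,
                             method = c("mean_square", "mean_abs")) {
  method <- match.arg(method)
  if (!length(series$values)) stop("empty series")
  n <- as.integer(n); B <- as.integer(B)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (is.na(B) || B < 1000L) stop("B must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  x <- sample(series$values, n * B, replace = TRUE)
  agg <- if (method == "mean_square") x^2 else abs(x)
  draws <- colMeans(matrix(agg, n, B))
  structure(list(draws = draws, B = B, n = n,
                 bandwidth = stats::bw.nrd0(draws),
                 level = series$level, seed = seed, method = method),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Permutation null of D",
      if (!is.na(x$level)) paste0("(", x$level, " variance)"), "\n")
  cat(sprintf("  B = %d draws of n = %d, aggregation %s, seed %s\n",
              x$B, x$n, x$method, format(x$seed)))
  cat(sprintf("  mean %.5f, 95%% quantile %.5f, KDE bandwidth %.3g\n",
              mean(x$draws), stats::quantile(x$draws, 0.95), x$bandwidth))
  invisible(x)
}

#' @export
plot.null_distribution <- function(x, ...) {
  d <- stats::density(x$draws, bw = x$bandwidth)
  graphics::plot(d, xlab = "D", main = paste0(
    "Null density of D",
    if (!is.na(x$level)) paste0(" (", x$level, ")")), ...)
  invisible(x)
}

#' Tail p-value of an observed D under a permutation null
#'
#' `"empirical"` uses the add-one-corrected tail proportion
#' `(1 + #\{draws >= D\}) / (B + 1)`. `"density"` integrates the upper tail
#' of the recorded Gaussian-kernel smoothed density (computable in closed
#' form as a mean of normal tail probabilities), floored at `1/(B + 1)`;
#' it extends resolution beyond the largest draw.
#'
#' @param null a `null_distribution`.
#' @param d_obs observed D value(s), `>= 0`.
#' @param method `"empirical"` (default) or `"density"`.
#' @return p-value(s) in `(0, 1]`.
#' @export
p_value <- function(null, d_obs, method = c("empirical", "density")) {
  method <- match.arg(method)
  stopifnot(inherits(null, "null_distribution"))
  floor_p <- 1 / (null$B + 1)
  if (method == "empirical") {
    sorted <- sort(null$draws)
    # draws >= d via binary search on the sorted draws
    n_ge <- null$B - findInterval(d_obs, sorted, left.open = TRUE)
    p <- (1 + n_ge) / (null$B + 1)
  } else {
    p <- vapply(d_obs, function(d) {
      mean(stats::pnorm(d, mean = null$draws, sd = null$bandwidth,
                        lower.tail = FALSE))
    }, 0)
    p <- pmax(p, floor_p)
  }
  p[is.na(d_obs)] <- NA_real_
  p
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure on raw p-values; returns both the rejection flags at
#' level `alpha` and the monotone adjusted p-values.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param alpha target FDR.
#' @return list with `reject` (logical) and `p_adj`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) stop("empty p-value list")
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1)))
    stop("p-values must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p_adj <- stats::p.adjust(pvalues, method = "BH")
  list(reject = !is.na(p_adj) & p_adj <= alpha, p_adj = p_adj)
}

#' Per-gene D-statistic table with Pa, Pt and averaged fold change
#'
#' Assembles the quantities gene selection needs: the observed D over the
#' design's arrows, its p-value under the anatomic null (Pa) and under the
#' technical null (Pt), and the averaged fold change over the
#' individual-level (G1) samples.
#'
#' @param fit a `loop_fit`.
#' @param design the `loop_design` (its arrays give the arrow set).
#' @param hierarchy `sample_hierarchy` for composite resolution.
#' @param null_ana,null_tech `null_distribution`s built from the anatomic
#'   (S2) and technical (S3) series.
#' @param arrow_scope `"all"` uses every array of the design (default);
#'   `"inter_individual"` restricts to arrows whose endpoints belong to
#'   different individuals.
#' @param p_method p-value method, see [p_value()].
#' @param method D aggregation, see [d_statistic()].
#' @return data frame of class `dstat_table`: `gene_id`, `D`, `n_arrows_used`,
#'   `p_anatomic`, `p_technical`, `afc`. Singular genes carry `NA`.
#' @export
d_stat_table <- function(fit, design, hierarchy, null_ana, null_tech,
                         arrow_scope = c("all", "inter_individual"),
                         p_method = c("empirical", "density"),
                         method = c("mean_square", "mean_abs")) {
  arrow_scope <- match.arg(arrow_scope)
  p_method <- match.arg(p_method)
  method <- match.arg(method)
  stopifnot(inherits(fit, "loop_fit"))
  arrows <- design$arrays
  if (arrow_scope == "inter_individual") {
    ind <- setNames(design$units$individual, design$units$unit_id)
    arrows <- arrows[ind[arrows$tail] != ind[arrows$head], , drop = FALSE]
    if (!nrow(arrows)) stop("no inter-individual arrows in this design")
  }
  lam <- fit$lambda
  ok <- stats::complete.cases(lam[, unique(c(arrows$tail, arrows$head)),
                                  drop = FALSE])
  d <- rep(NA_real_, nrow(lam))
  d[ok] <- d_statistic(lam[ok, , drop = FALSE], arrows, method = method)

  comp <- composite_lambda(fit, hierarchy)
  g1 <- if ("G1" %in% names(design$groups)) design$groups$G1
        else unique(design$units$individual)
  afc <- rep(NA_real_, nrow(lam))
  cc <- stats::complete.cases(comp[, g1, drop = FALSE])
  afc[cc] <- averaged_fold_change(comp[cc, g1, drop = FALSE])

  out <- data.frame(gene_id = rownames(lam), D = d,
                    n_arrows_used = ifelse(is.na(d), NA_integer_, nrow(arrows)),
                    p_anatomic = p_value(null_ana, d, method = p_method),
                    p_technical = p_value(null_tech, d, method = p_method),
                    afc = afc, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "meta") <- list(arrow_scope = arrow_scope, p_method = p_method,
                            d_method = method,
                            B = c(anatomic = null_ana$B, technical = null_tech$B),
                            bandwidth = c(anatomic = null_ana$bandwidth,
                                          technical = null_tech$bandwidth))
  class(out) <- c("dstat_table", "data.frame")
  out
}

#' @export
plot.dstat_table <- function(x, which = c("anatomic", "technical"), ...) {
  which <- match.arg(which)
  p <- if (which == "anatomic") x$p_anatomic else x$p_technical
  graphics::plot(log2(x$afc), -log10(p),
                 xlab = "log2 averaged fold change",
                 ylab = expression(-log[10](p)),
                 main = paste0("AFC vs p (", which, " variance)"), ...)
  invisible(x)
}

#' Select inter-individual variable genes
#'
#' For each variance level (anatomic -> Pa, technical -> Pt): apply
#' Benjamini-Hochberg at `fdr_alpha`, then intersect with
#' `afc >= cutoff` for each cutoff. Selections are nested across cutoffs
#' by construction.
#'
#' @param dstats a `dstat_table`.
#' @param fdr_alpha target FDR for the per-level BH step.
#' @param afc_cutoffs averaged-fold-change cutoffs.
#' @return An object of class `gene_selection`: `flags` (logical matrix,
#'   one column per `level:cutoff` criterion), `counts`, `fdr_alpha`,
#'   `afc_cutoffs`, `gene_id`.
#' @export
select_genes <- function(dstats, fdr_alpha = 0.05,
                         afc_cutoffs = c(1.2, 1.3, 1.4, 1.5)) {
  stopifnot(inherits(dstats, "data.frame"))
  levels <- c(anatomic = "p_anatomic", technical = "p_technical")
  flags <- matrix(FALSE, nrow(dstats), length(levels) * length(afc_cutoffs))
  cn <- character(0)
  j <- 0L
  for (lv in names(levels)) {
    p <- dstats[[levels[[lv]]]]
    ok <- !is.na(p) & !is.na(dstats$afc)
    rej <- rep(FALSE, nrow(dstats))
    if (any(ok)) rej[ok] <- bh_fdr(p[ok], alpha = fdr_alpha)$reject
    for (cut in afc_cutoffs) {
      j <- j + 1L
      flags[, j] <- rej & !is.na(dstats$afc) & dstats$afc >= cut
      cn <- c(cn, sprintf("%s:%.1f", lv, cut))
    }
  }
  colnames(flags) <- cn
  rownames(flags) <- dstats$gene_id
  structure(list(flags = flags, counts = colSums(flags),
                 fdr_alpha = fdr_alpha, afc_cutoffs = afc_cutoffs,
                 gene_id = dstats$gene_id),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("Inter-individual variable gene selection (FDR", x$fdr_alpha, ")\n")
  print(x$counts)
  invisible(x)
}

#' Gene ids selected under one criterion
#'
#' @param selection a `gene_selection`.
#' @param criterion a column name of its flag matrix, e.g. `"technical:1.2"`.
#' @return character vector of gene ids.
#' @export
selected_genes <- function(selection, criterion) {
  stopifnot(inherits(selection, "gene_selection"))
  if (!criterion %in% colnames(selection$flags))
    stop("unknown criterion: ", criterion, " (have: ",
         paste(colnames(selection$flags), collapse = ", "), ")")
  selection$gene_id[selection$flags[, criterion]]
}
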