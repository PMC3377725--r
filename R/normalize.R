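# Intensity-dependent (LOWESS) normalization of spot-level log ratios and
# aggregation of replicate spots to one value per gene per array.

#' LOWESS-normalize the spots of one array
#'
#' Computes per spot `M = log2(f_num/f_den)` and `A = (log2 f_num +
#' log2 f_den)/2`, fits a robust locally weighted regression of M on A
#' (Cleveland's LOWESS: tricube weights with robustifying iterations) on
#' the unflagged spots, and returns the trend-corrected `M`. Flagged spots
#' are excluded from the fit and from the output.
#'
#' @param spots data frame with columns `gene_id`, `spot_rep`, `f_num`,
#'   `f_den`, `flag` (one array's spots).
#' @param span smoother span (fraction of spots in each local window),
#'   in (0, 1].
#' @param iterations robustifying iterations of the LOWESS fit.
#' @return data frame `gene_id`, `spot_rep`, `M`, `A` over the unflagged
#'   spots, in input order.
#' @export
lowess_normalize <- function(spots, span = 0.3, iterations = 3L) {
  if (!all(c("gene_id", "f_num", "f_den", "flag") %in% names(spots)))
    stop("spots needs columns gene_id, f_num, f_den, flag")
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  keep <- !spots$flag
  if (sum(keep) < 10L)
    stop("insufficient data: ", sum(keep),
         " unflagged spots (need at least 10)")
  bad <- which(keep & (spots$f_num <= 0 | spots$f_den <= 0))
  if (length(bad))
    stop("nonpositive intensity at spot row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  sp <- spots[keep, , drop = FALSE]
  m_raw <- log2(sp$f_num / sp$f_den)
  a <- (log2(sp$f_num) + log2(sp$f_den)) / 2
  fit <- stats::lowess(a, m_raw, f = span, iter = iterations)
  trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
  data.frame(gene_id = sp$gene_id,
             spot_rep = if (!is.null(sp$spot_rep)) sp$spot_rep else seq_len(nrow(sp)),
             M = m_raw - trend, A = a,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate replicate spots to one value per gene
#'
#' @param corrected output of [lowess_normalize()] for one array.
#' @param method `"median"` (default) or `"mean"` over the unflagged
#'   corrected spots of each gene.
#' @param min_valid minimum number of valid spots for a gene to receive a
#'   value; below it `M` is missing (missingness is data, not an error).
#' @param genes optional full gene universe; genes absent from `corrected`
#'   (e.g. all spots flagged) are reported with `n_valid_spots = 0`.
#' @return data frame `gene_id`, `M`, `A` (mean intensity of the valid
#'   spots), `n_valid_spots`.
#' @export
aggregate_replicates <- function(corrected, method = c("median", "mean"),
                                 min_valid = 2L, genes = NULL) {
  method <- match.arg(method)
  if (min_valid < 1L) stop("min_valid must be >= 1")
  if (is.null(genes)) genes <- unique(corrected$gene_id)
  f <- if (method == "median") stats::median else mean
  idx <- split(seq_len(nrow(corrected)),
               factor(corrected$gene_id, levels = genes))
  n_valid <- vapply(idx, length, 0L)
  m <- vapply(idx, function(i) if (length(i)) f(corrected$M[i]) else NA_real_,
              0)
  a <- vapply(idx, function(i) if (length(i)) mean(corrected$A[i]) else NA_real_,
              0)
  m[n_valid < min_valid] <- NA_real_
  data.frame(gene_id = genes, M = unname(m), A = unname(a),
             n_valid_spots = unname(n_valid),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize and aggregate all arrays of an experiment
#'
#' Applies [lowess_normalize()] then [aggregate_replicates()] per array and
#' stacks the results into the long gene-level table the model fit consumes.
#'
#' @param spots a `spot_tables` list (one spot data frame per array).
#' @inheritParams lowess_normalize
#' @inheritParams aggregate_replicates
#' @return data frame of class `normalized_ratios` with columns `array_id`,
#'   `gene_id`, `M`, `A`, `n_valid_spots`.
#' @export
normalize_arrays <- function(spots, span = 0.3, iterations = 3L,
                             method = c("median", "mean"), min_valid = 2L) {
  method <- match.arg(method)
  genes <- unique(unlist(lapply(spots, function(s) unique(s$gene_id)),
                         use.names = FALSE))
  out <- lapply(names(spots), function(aid) {
    corr <- lowess_normalize(spots[[aid]], span = span,
                             iterations = iterations)
    agg <- aggregate_replicates(corr, method = method, min_valid = min_valid,
                                genes = genes)
    cbind(array_id = aid, agg, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("normalized_ratios", "data.frame")
  res
}
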