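# Per-gene log-linear model over a loop design.
#
# For one gene, each array a contributes one observation
#     M_a = gamma + lambda[tail(a)] - lambda[head(a)] + eps_a,
# eps ~ N(0, sigma^2), with the identifiability constraint that lambda sums
# to zero over the units present in the observed arrays.  gamma is the
# gene's dye effect (relative labeling efficiency), lambda[i] the log2
# expression of unit i relative to the mean over units, and sigma the
# gene's residual SD.  Estimation is ordinary least squares; the constraint
# is imposed by a drop-one reparameterization and the dropped coefficient
# recovered afterwards, so the reported lambda sum to zero exactly.

# Constrained least squares for one missingness pattern.
# tails/heads: observed arrays; rhs: n_obs x n_genes matrix of M values.
# Returns NULL when the constrained design is rank-deficient (singular).
.solve_pattern <- function(tails, heads, rhs) {
  n_obs <- length(tails)
  if (n_obs == 0L) return(NULL)
  units <- unique(c(tails, heads))
  m <- length(units)
  # gamma column + (m-1) free lambda columns; lambda[m] = -sum(others)
  x <- matrix(0, n_obs, m)
  x[, 1L] <- 1
  last_t <- tails == units[m]
  last_h <- heads == units[m]
  if (m > 1L) for (k in seq_len(m - 1L)) {
    x[, k + 1L] <- (tails == units[k]) - (heads == units[k]) -
      (last_t - last_h)
  }
  qx <- qr(x)
  if (qx$rank < m) return(NULL)
  coef <- qr.coef(qx, rhs)                       # m x n_genes
  fitted <- x %*% coef
  rss <- colSums((rhs - fitted)^2)
  lambda <- rbind(coef[-1L, , drop = FALSE],
                  -colSums(coef[-1L, , drop = FALSE]))
  rownames(lambda) <- units
  list(gamma = coef[1L, ], lambda = lambda, rss = pmax(rss, 0),
       df = n_obs - m, n_obs = n_obs, units = units)
}

#' Fit the log-linear loop model for a single gene
#'
#' Least-squares fit of `M_a = gamma + lambda[tail] - lambda[head] + eps`
#' over the arrays with a non-missing M value, with `sum(lambda) = 0` over
#' the units those arrays touch. A gene is singular when the constrained
#' design matrix is rank-deficient — e.g. the observed-array subgraph is
#' disconnected, or acyclic so that gamma and lambda are confounded — in
#' which case only the flag is returned.
#'
#' @param m_values numeric vector of normalized log ratios named by
#'   `array_id`; `NA` entries (flagged/missing genes) drop the array.
#' @param design a `loop_design`.
#' @return An object of class `gene_fit`: `gamma_hat`, `lambda_hat` (named,
#'   summing to zero), `sigma_hat` (`NA` when `df = 0`), `df`, `n_obs`,
#'   `rss`, `singular`.
#' @examples
#' fx <- fig1_design()
#' m <- setNames(rnorm(fx$design$n_arrows), fx$design$arrays$array_id)
#' fit_gene(m, fx$design)
#' @export
fit_gene <- function(m_values, design) {
  stopifnot(inherits(design, "loop_design"))
  if (is.null(names(m_values)))
    stop("m_values must be named by array_id")
  unknown <- setdiff(names(m_values), design$arrays$array_id)
  if (length(unknown))
    stop("m_values names not in design: ", paste(unknown, collapse = ", "))
  m <- m_values[match(design$arrays$array_id, names(m_values))]
  obs <- which(!is.na(m))
  sol <- .solve_pattern(design$arrays$tail[obs], design$arrays$head[obs],
                        matrix(m[obs], ncol = 1L))
  if (is.null(sol)) {
    return(structure(list(gamma_hat = NA_real_, lambda_hat = NULL,
                          sigma_hat = NA_real_, df = NA_integer_,
                          n_obs = length(obs), rss = NA_real_,
                          singular = TRUE),
                     class = "gene_fit"))
  }
  sigma <- if (sol$df >= 1L) sqrt(sol$rss[1L] / sol$df) else NA_real_
  structure(list(gamma_hat = unname(sol$gamma[1L]),
                 lambda_hat = setNames(sol$lambda[, 1L], sol$units),
                 sigma_hat = sigma, df = sol$df, n_obs = sol$n_obs,
                 rss = sol$rss[1L], singular = FALSE),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  if (x$singular) {
    cat("Gene fit: singular (", x$n_obs, "observations )\n")
  } else {
    cat(sprintf("Gene fit: gamma_hat %.4f, sigma_hat %s, df %d (%d obs)\n",
                x$gamma_hat,
                if (is.na(x$sigma_hat)) "NA" else sprintf("%.4f", x$sigma_hat),
                x$df, x$n_obs))
    print(round(x$lambda_hat, 4))
  }
  invisible(x)
}

#' Fit the loop model gene-by-gene
#'
#' Applies the constrained least-squares fit of [fit_gene()] to every gene
#' of a normalized experiment. Genes sharing a missingness pattern share
#' one matrix factorization, so thousands of genes fit in well under a
#' second on the reference design.
#'
#' @param normalized a `normalized_ratios` data frame
#'   (`array_id`, `gene_id`, `M`) from [normalize_arrays()], or a genes x
#'   arrays numeric matrix with dimnames.
#' @param design a `loop_design`.
#' @return An object of class `loop_fit` with per-gene `gamma` and `sigma`
#'   vectors, a genes x units `lambda` matrix (rows sum to zero; `NA` for
#'   singular genes or units absent from a gene's observed arrays), `df`,
#'   `n_obs`, `rss`, logical `singular`, and `n_fit` — the number of genes
#'   estimable without singularity.
#' @seealso [fit_gene()], [composite_lambda()]
#' @export
loop_fit <- function(normalized, design) {
  stopifnot(inherits(design, "loop_design"))
  arrays <- design$arrays
  if (is.matrix(normalized)) {
    mmat <- normalized
    missing_arr <- setdiff(arrays$array_id, colnames(mmat))
    if (length(missing_arr)) {
      pad <- matrix(NA_real_, nrow(mmat), length(missing_arr),
                    dimnames = list(rownames(mmat), missing_arr))
      mmat <- cbind(mmat, pad)
    }
    mmat <- mmat[, arrays$array_id, drop = FALSE]
  } else {
    if (!all(c("array_id", "gene_id", "M") %in% names(normalized)))
      stop("normalized needs columns array_id, gene_id, M")
    genes <- unique(normalized$gene_id)
    mmat <- matrix(NA_real_, length(genes), nrow(arrays),
                   dimnames = list(genes, arrays$array_id))
    keep <- normalized$array_id %in% arrays$array_id
    mmat[cbind(match(normalized$gene_id[keep], genes),
               match(normalized$array_id[keep], arrays$array_id))] <-
      normalized$M[keep]
  }
  genes <- rownames(mmat)
  ng <- length(genes)
  unit_ids <- design$units$unit_id

  gamma <- setNames(rep(NA_real_, ng), genes)
  sigma <- gamma
  rss <- gamma
  df <- setNames(rep(NA_integer_, ng), genes)
  n_obs <- setNames(as.integer(rowSums(!is.na(mmat))), genes)
  singular <- setNames(rep(TRUE, ng), genes)
  lambda <- matrix(NA_real_, ng, length(unit_ids),
                   dimnames = list(genes, unit_ids))

  pattern <- apply(!is.na(mmat), 1L,
                   function(r) paste(as.integer(r), collapse = ""))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    obs <- which(strsplit(pat, "", fixed = TRUE)[[1L]] == "1")
    sol <- .solve_pattern(arrays$tail[obs], arrays$head[obs],
                          t(mmat[rows, obs, drop = FALSE]))
    if (is.null(sol)) next
    gamma[rows] <- sol$gamma
    rss[rows] <- sol$rss
    df[rows] <- sol$df
    singular[rows] <- FALSE
    sigma[rows] <- if (sol$df >= 1L) sqrt(sol$rss / sol$df) else NA_real_
    lambda[rows, sol$units] <- t(sol$lambda)
  }

  structure(list(gamma = gamma, lambda = lambda, sigma = sigma, rss = rss,
                 df = df, n_obs = n_obs, singular = singular,
                 n_fit = sum(!singular), m = mmat, design = design,
                 call = match.call()),
            class = "loop_fit")
}

#' @export
print.loop_fit <- function(x, ...) {
  cat("Loop-design log-linear fit\n")
  cat("  genes: ", length(x$gamma), " (", x$n_fit,
      " estimable without singularity)\n", sep = "")
  cat("  arrays:", ncol(x$m), " units:", ncol(x$lambda), "\n")
  invisible(x)
}

#' @export
summary.loop_fit <- function(object, ...) {
  ok <- !object$singular
  s <- list(
    n_genes = length(object$gamma),
    n_fit = object$n_fit,
    gamma_summary = summary(object$gamma[ok]),
    sigma_summary = summary(object$sigma[ok & !is.na(object$sigma)]),
    lambda_sd = apply(object$lambda, 2, stats::sd, na.rm = TRUE),
    df_table = table(object$df[ok])
  )
  class(s) <- "summary.loop_fit"
  s
}

#' @export
print.summary.loop_fit <- function(x, ...) {
  cat("Loop-design log-linear fit:", x$n_genes, "genes,", x$n_fit,
      "non-singular\n\nDye effect gamma_hat:\n")
  print(x$gamma_summary)
  cat("\nResidual SD sigma_hat:\n")
  print(x$sigma_summary)
  cat("\nPer-unit SD of lambda_hat over genes:\n")
  print(round(x$lambda_sd, 4))
  invisible(x)
}

#' @export
coef.loop_fit <- function(object, ...) {
  cbind(gamma = object$gamma, object$lambda)
}

#' @export
fitted.loop_fit <- function(object, ...) {
  arr <- object$design$arrays
  t_idx <- match(arr$tail, colnames(object$lambda))
  h_idx <- match(arr$head, colnames(object$lambda))
  out <- object$gamma +
    object$lambda[, t_idx, drop = FALSE] -
    object$lambda[, h_idx, drop = FALSE]
  colnames(out) <- arr$array_id
  out[is.na(object$m)] <- NA_real_
  out
}

#' @export
residuals.loop_fit <- function(object, ...) {
  object$m - fitted(object)
}

#' Predicted log ratios for arbitrary sample pairs
#'
#' @param object a `loop_fit`.
#' @param arrows data frame with columns `tail`, `head` (unit ids); default
#'   the fitted design's arrays.
#' @param ... unused.
#' @return genes x arrows matrix of `gamma_hat + lambda[tail] - lambda[head]`.
#' @export
predict.loop_fit <- function(object, arrows = NULL, ...) {
  if (is.null(arrows)) return(fitted(object))
  t_idx <- match(arrows$tail, colnames(object$lambda))
  h_idx <- match(arrows$head, colnames(object$lambda))
  if (anyNA(t_idx) || anyNA(h_idx)) stop("arrows reference unknown units")
  out <- object$gamma +
    object$lambda[, t_idx, drop = FALSE] -
    object$lambda[, h_idx, drop = FALSE]
  colnames(out) <- paste(arrows$tail, arrows$head, sep = "->")
  out
}

#' @export
simulate.loop_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    noise <- matrix(stats::rnorm(length(mu), 0,
                                 rep(ifelse(is.na(object$sigma), 0, object$sigma),
                                     ncol(mu))),
                    nrow(mu), ncol(mu))
    mu + noise
  })
}

#' Resolve composite-sample expression values from a fit
#'
#' Composite samples (a section from its technical replicates, an
#' individual from its sections) take the unweighted mean of their
#' children's lambda values, computed bottom-up through the hierarchy.
#' A gene missing any child value (e.g. a singular gene) gets a missing
#' composite.
#'
#' @param fit a `loop_fit`, or a genes x units lambda matrix.
#' @param hierarchy a `sample_hierarchy`.
#' @return genes x labels matrix covering the fitted units plus every
#'   composite label.
#' @export
composite_lambda <- function(fit, hierarchy) {
  stopifnot(inherits(hierarchy, "sample_hierarchy"))
  lambda <- if (inherits(fit, "loop_fit")) fit$lambda else as.matrix(fit)
  .composite_matrix(lambda, hierarchy)
}
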