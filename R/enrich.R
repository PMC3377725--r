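# Local functional-enrichment scoring: Fisher exact over-representation and
# its conservative EASE variant, on a user-supplied gene -> term annotation.

#' One-sided Fisher exact over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, list_size)`: the probability
#' of seeing at least `k` annotated genes in a list of `list_size` drawn
#' from a background of `N` genes of which `K` carry the term.
#'
#' @param k annotated genes in the list.
#' @param list_size size of the gene list.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return p-value in (0, 1]. Vectorized over all arguments.
#' @export
fisher_exact_enrichment <- function(k, list_size, K, N) {
  args <- cbind(k = k, list_size = list_size, K = K, N = N)
  if (any(args < 0) || any(args[, "K"] > args[, "N"]) ||
      any(args[, "list_size"] > args[, "N"]) ||
      any(args[, "k"] > pmin(args[, "list_size"], args[, "K"])))
    stop("need 0 <= k <= min(list_size, K), K <= N, list_size <= N")
  stats::phyper(k - 1, K, N - K, list_size, lower.tail = FALSE)
}

#' EASE score: the jackknifed Fisher exact p-value
#'
#' The Fisher tail recomputed after removing one list hit from the term
#' (`k - 1`, floored at 0), penalizing categories supported by few genes;
#' by construction `p_ease >= p_fisher`.
#'
#' @inheritParams fisher_exact_enrichment
#' @return p-value in (0, 1].
#' @export
ease_score <- function(k, list_size, K, N) {
  fisher_exact_enrichment(pmax(k - 1, 0), list_size, K, N)
}

#' Read a gene -> term annotation table
#'
#' @param path long-format TSV with columns `term_id`, `gene_id`.
#' @param background character vector of background gene ids; defaults to
#'   all annotated genes. Annotated genes outside the background are
#'   dropped with a warning.
#' @return An object of class `annotation_table`: `terms` (named list of
#'   gene-id vectors) and `background`.
#' @export
read_annotation <- function(path, background = NULL) {
  df <- .read_tsv_strict(path)
  if (!all(c("term_id", "gene_id") %in% names(df)))
    stop("annotation file needs columns term_id, gene_id")
  annotation_table(split(df$gene_id, df$term_id), background = background)
}

#' @rdname read_annotation
#' @param terms named list: term id -> character vector of gene ids.
#' @export
annotation_table <- function(terms, background = NULL) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(background)) {
    background <- unique(unlist(terms, use.names = FALSE))
  } else {
    background <- unique(as.character(background))
    out <- setdiff(unlist(terms, use.names = FALSE), background)
    if (length(out)) {
      warning(length(out), " annotated gene(s) outside the background dropped")
      terms <- lapply(terms, intersect, background)
    }
  }
  structure(list(terms = terms, background = background),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation:", length(x$terms), "terms over",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Term enrichment of a gene list
#'
#' Scores every annotation term against the list with the Fisher exact and
#' EASE p-values, keeping terms with `p_ease < ease_cutoff` and at least
#' `min_genes` list genes, sorted by significance score
#' (`-log10 p_ease`) descending.
#'
#' @param gene_list character vector of gene ids (deduplicated; genes
#'   outside the background are dropped with a warning).
#' @param annotation an `annotation_table`.
#' @param ease_cutoff retain terms with EASE score strictly below this.
#' @param min_genes minimum list genes in a term.
#' @return data frame of class `enrichment_result`: `term_id`, `k`,
#'   `list_size`, `K`, `N`, `p_fisher`, `p_ease`, `significance_score`.
#' @export
enrich_terms <- function(gene_list, annotation, ease_cutoff = 0.1,
                         min_genes = 2L) {
  stopifnot(inherits(annotation, "annotation_table"))
  gene_list <- unique(as.character(gene_list))
  out_bg <- setdiff(gene_list, annotation$background)
  if (length(out_bg)) {
    warning(length(out_bg), " listed gene(s) not in background dropped")
    gene_list <- setdiff(gene_list, out_bg)
  }
  n <- length(annotation$background)
  ls <- length(gene_list)
  empty <- data.frame(term_id = character(0), k = integer(0),
                      list_size = integer(0), K = integer(0), N = integer(0),
                      p_fisher = numeric(0), p_ease = numeric(0),
                      significance_score = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (!ls || !length(annotation$terms)) return(empty)
  k <- vapply(annotation$terms, function(g) length(intersect(g, gene_list)), 0L)
  K <- vapply(annotation$terms, length, 0L)
  p_f <- fisher_exact_enrichment(k, ls, K, n)
  p_e <- ease_score(k, ls, K, n)
  res <- data.frame(term_id = names(annotation$terms), k = k, list_size = ls,
                    K = K, N = n, p_fisher = p_f, p_ease = p_e,
                    significance_score = -log10(p_e),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[res$p_ease < ease_cutoff & res$k >= min_genes, , drop = FALSE]
  res <- res[order(-res$significance_score, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Terms common to every selection criterion
#'
#' Intersects the retained terms of several enrichment results and lays
#' out their per-criterion significance scores side by side — the shape of
#' a cross-criterion comparison table.
#'
#' @param results named list (criterion -> `enrichment_result`), length >= 2.
#' @return data frame: `term_id` plus one significance-score column per
#'   criterion, sorted by mean score descending; zero rows when the
#'   retained sets are disjoint.
#' @export
common_terms <- function(results) {
  if (length(results) < 2L) stop("need at least 2 criteria")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be a named list")
  shared <- Reduce(intersect, lapply(results, function(r) r$term_id))
  scores <- vapply(results, function(r) {
    r$significance_score[match(shared, r$term_id)]
  }, numeric(length(shared)))
  if (length(shared) == 1L) scores <- matrix(scores, 1L,
                                             dimnames = list(NULL,
                                                             names(results)))
  out <- data.frame(term_id = shared, scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1L)
    out <- out[order(-rowMeans(out[, -1L, drop = FALSE])), , drop = FALSE]
  rownames(out) <- NULL
  out
}
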