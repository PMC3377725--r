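# Synthetic spot-level generator for loop-design two-color experiments.
#
# Effects are additive on the log2 scale and nested: individual -> tissue
# section -> technical replicate, each level adding a fresh Gaussian
# perturbation.  This is the minimal generative structure under which the
# three variance series (individual / anatomic / technical) are all
# realized, with sigma_tech < sigma_ana < sigma_ind giving the expected
# progressive narrowing of their distributions.

#' Simulation configuration
#'
#' Parameters of the synthetic loop-design experiment. Scale is log2
#' throughout. Defaults describe a realistic placental-tissue-style study:
#' individual variation dominating anatomic, which dominates technical
#' (`0.3 > 0.1 > 0.05` log2 SD), a per-gene dye effect centred near 0.4,
#' quadruplicate spotting, a mild quadratic intensity-dependent dye bias,
#' and a 2\% spot flagging rate.
#'
#' @param n_genes number of genes (cDNA clones).
#' @param sigma_tech,sigma_ana,sigma_ind SDs of the technical-replicate,
#'   section (anatomic), and individual effects.
#' @param sigma_resid SD of the array-level residual error of the log ratio.
#' @param gamma_mean,gamma_sd mean and SD of the per-gene dye effect gamma
#'   (relative labeling efficiency between the two dyes).
#' @param n_spot_reps replicate spots per gene per array.
#' @param sigma_spot spot-level measurement SD added to each replicate spot.
#' @param dye_bias_coeffs polynomial coefficients (ascending powers) of the
#'   intensity-dependent dye bias in mean log intensity A; the default
#'   `c(0, 0, 0.01)` adds `0.01 * A^2` to every spot's log ratio, the kind
#'   of smooth trend LOWESS normalization removes.
#' @param flag_prob probability that a spot is flagged (excluded as invalid).
#' @param seed integer seed used by the simulation functions by default.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       sigma_tech = 0.05, sigma_ana = 0.1, sigma_ind = 0.3,
                       sigma_resid = 0.1,
                       gamma_mean = 0.4, gamma_sd = 0.2,
                       n_spot_reps = 4, sigma_spot = 0.1,
                       dye_bias_coeffs = c(0, 0, 0.01),
                       flag_prob = 0.02, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              sigma_tech = sigma_tech, sigma_ana = sigma_ana,
              sigma_ind = sigma_ind, sigma_resid = sigma_resid,
              gamma_mean = gamma_mean, gamma_sd = gamma_sd,
              n_spot_reps = as.integer(n_spot_reps),
              sigma_spot = sigma_spot,
              dye_bias_coeffs = as.numeric(dye_bias_coeffs),
              flag_prob = flag_prob, seed = as.integer(seed))
  sds <- c(cfg$sigma_tech, cfg$sigma_ana, cfg$sigma_ind, cfg$sigma_resid,
           cfg$sigma_spot)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all SDs must be finite and >= 0")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$n_spot_reps < 1L) stop("n_spot_reps must be >= 1")
  if (!is.finite(cfg$flag_prob) || cfg$flag_prob < 0 || cfg$flag_prob >= 1)
    stop("flag_prob must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_genes, "genes,", x$n_spot_reps,
      "spots/gene/array\n")
  cat(sprintf("  SD (log2): tech %.3g | ana %.3g | ind %.3g | resid %.3g | spot %.3g\n",
              x$sigma_tech, x$sigma_ana, x$sigma_ind, x$sigma_resid,
              x$sigma_spot))
  cat(sprintf("  gamma ~ N(%.3g, %.3g^2); flag_prob %.3g; seed %d\n",
              x$gamma_mean, x$gamma_sd, x$flag_prob, x$seed))
  invisible(x)
}

# evaluate sum coeffs[k] * a^(k-1)
.polyval <- function(coeffs, a) {
  out <- numeric(length(a))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * a^(k - 1)
  out
}

#' Simulate ground-truth gene effects over a loop design
#'
#' Draws, per gene, a dye effect `gamma_true ~ N(gamma_mean, gamma_sd^2)`
#' and nested sample effects: one individual effect per individual
#' (`N(0, sigma_ind^2)`), plus a section effect (`N(0, sigma_ana^2)`) for
#' units carrying a section label, plus a technical-replicate effect
#' (`N(0, sigma_tech^2)`) for units carrying a replicate label. The
#' per-unit `lambda_true` is the leaf value, re-centred per gene so the
#' mean over the individual-level (G1) samples — composites resolved
#' through the hierarchy — is zero.
#'
#' Note the centring gauge: the fitted model constrains the unit-level sum
#' of lambda to zero, so fitted and true lambda may differ by a per-gene
#' constant; all downstream quantities are pairwise differences and do not
#' depend on the gauge.
#'
#' @param config a [sim_config()].
#' @param design a `loop_design`.
#' @param hierarchy a `sample_hierarchy` used to resolve composite labels
#'   when centring.
#' @param seed seed for this draw; defaults to `config$seed`.
#' @return An object of class `truth_table`: `gamma` (named vector, one per
#'   gene) and `lambda` (genes x units matrix).
#' @export
simulate_truth <- function(config, design, hierarchy = sample_hierarchy(),
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "loop_design"))
  if (!is.null(seed)) set.seed(seed)
  units <- design$units
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))

  inds <- unique(units$individual)
  ind_eff <- matrix(stats::rnorm(ng * length(inds), 0, config$sigma_ind),
                    ng, length(inds), dimnames = list(genes, inds))
  sec_key <- ifelse(is.na(units$section), NA,
                    paste(units$individual, units$section, sep = "\r"))
  secs <- unique(sec_key[!is.na(sec_key)])
  sec_eff <- if (length(secs))
    matrix(stats::rnorm(ng * length(secs), 0, config$sigma_ana),
           ng, length(secs), dimnames = list(genes, secs))
  else matrix(0, ng, 0)
  tech_units <- units$unit_id[!is.na(units$tech_rep)]
  tech_eff <- if (length(tech_units))
    matrix(stats::rnorm(ng * length(tech_units), 0, config$sigma_tech),
           ng, length(tech_units), dimnames = list(genes, tech_units))
  else matrix(0, ng, 0)

  lambda <- matrix(0, ng, nrow(units), dimnames = list(genes, units$unit_id))
  for (i in seq_len(nrow(units))) {
    v <- ind_eff[, units$individual[i]]
    if (!is.na(sec_key[i])) v <- v + sec_eff[, sec_key[i]]
    if (!is.na(units$tech_rep[i])) v <- v + tech_eff[, units$unit_id[i]]
    lambda[, i] <- v
  }

  # centre per gene over the individual-level samples (G1 when declared)
  labels <- if ("G1" %in% names(design$groups)) design$groups$G1 else inds
  resolved <- .resolve_labels(lambda, hierarchy, labels)
  lambda <- lambda - rowMeans(resolved)

  gamma <- stats::rnorm(ng, config$gamma_mean, config$gamma_sd)
  names(gamma) <- genes
  structure(list(gamma = gamma, lambda = lambda), class = "truth_table")
}

# genes x labels matrix of lambda values, composites resolved bottom-up
# through the hierarchy as unweighted means of children
.resolve_labels <- function(lambda, hierarchy, labels) {
  full <- .composite_matrix(lambda, hierarchy)
  missing <- setdiff(labels, colnames(full))
  if (length(missing))
    stop("unresolvable sample label(s): ", paste(missing, collapse = ", "))
  full[, labels, drop = FALSE]
}

.composite_matrix <- function(lambda, hierarchy) {
  out <- lambda
  pending <- names(hierarchy$composite_map)
  while (length(pending)) {
    ready <- pending[vapply(pending, function(cmp) {
      all(hierarchy$composite_map[[cmp]] %in% colnames(out))
    }, logical(1))]
    if (!length(ready))
      stop("hierarchy references unknown label(s): ",
           paste(setdiff(unique(unlist(hierarchy$composite_map[pending])),
                         colnames(out)), collapse = ", "))
    for (cmp in ready) {
      kids <- hierarchy$composite_map[[cmp]]
      out <- cbind(out, rowMeans(out[, kids, drop = FALSE]))
      colnames(out)[ncol(out)] <- cmp
    }
    pending <- setdiff(pending, ready)
  }
  out
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Truth table:", length(x$gamma), "genes x", ncol(x$lambda), "units\n")
  cat(sprintf("  gamma: mean %.3f, sd %.3f\n", mean(x$gamma),
              stats::sd(x$gamma)))
  cat(sprintf("  lambda SD over genes (first units): %s\n",
              paste(sprintf("%.3f", apply(x$lambda[, seq_len(min(4, ncol(x$lambda))), drop = FALSE], 2, stats::sd)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate spot-level two-channel arrays from a truth table
#'
#' For each array `tail -> head` and gene, the true log ratio is
#' `M = gamma_true + lambda_true[tail] - lambda_true[head] + N(0, sigma_resid^2)`.
#' Each of `n_spot_reps` replicate spots draws a mean log intensity
#' `A ~ Uniform(6, 16)` and observes
#' `M_spot = M + polynomial(dye_bias_coeffs, A) + N(0, sigma_spot^2)`;
#' channel intensities are reconstructed as `2^(A + M_spot/2)` and
#' `2^(A - M_spot/2)`. Spots are flagged independently with `flag_prob`.
#'
#' @param truth a `truth_table` from [simulate_truth()] over the same design.
#' @param design the `loop_design`.
#' @param config the [sim_config()] used for the truth draw.
#' @param seed seed for the measurement-level noise; defaults to
#'   `config$seed + 1` so truth and spots use distinct streams.
#' @return A named list (one element per array) of spot data frames with
#'   columns `array_id`, `gene_id`, `spot_rep`, `f_num`, `f_den`, `flag`,
#'   of class `spot_tables`.
#' @export
simulate_spots <- function(truth, design, config,
                           seed = if (is.null(config$seed)) NULL else config$seed + 1L) {
  stopifnot(inherits(truth, "truth_table"), inherits(design, "loop_design"),
            inherits(config, "sim_config"))
  if (length(truth$gamma) != config$n_genes)
    stop("truth has ", length(truth$gamma), " genes but config declares ",
         config$n_genes)
  if (!all(c(design$arrays$tail, design$arrays$head) %in% colnames(truth$lambda)))
    stop("truth table does not cover the design's units")
  if (!is.null(seed)) set.seed(seed)
  genes <- names(truth$gamma)
  ng <- length(genes)
  reps <- config$n_spot_reps
  out <- vector("list", nrow(design$arrays))
  names(out) <- design$arrays$array_id
  for (a in seq_len(nrow(design$arrays))) {
    tl <- design$arrays$tail[a]; hd <- design$arrays$head[a]
    m_true <- truth$gamma + truth$lambda[, tl] - truth$lambda[, hd] +
      stats::rnorm(ng, 0, config$sigma_resid)
    n_spots <- ng * reps
    A <- stats::runif(n_spots, 6, 16)
    m_spot <- rep(m_true, each = reps) + .polyval(config$dye_bias_coeffs, A) +
      stats::rnorm(n_spots, 0, config$sigma_spot)
    out[[a]] <- data.frame(
      array_id = design$arrays$array_id[a],
      gene_id = rep(genes, each = reps),
      spot_rep = rep(seq_len(reps), ng),
      f_num = 2^(A + m_spot / 2),
      f_den = 2^(A - m_spot / 2),
      flag = stats::runif(n_spots) < config$flag_prob,
      stringsAsFactors = FALSE
    )
  }
  structure(out, class = "spot_tables")
}

#' @export
print.spot_tables <- function(x, ...) {
  n_spots <- sum(vapply(x, nrow, 0L))
  cat("Spot tables:", length(x), "arrays,", n_spots, "spots",
      sprintf("(%.1f%% flagged)\n",
              100 * sum(vapply(x, function(s) sum(s$flag), 0L)) / n_spots))
  invisible(x)
}

#' Write / read spot tables as one TSV per array
#'
#' @param spots a `spot_tables` list.
#' @param dir output directory.
#' @return Invisibly (write) the paths; (read) a `spot_tables` list.
#' @export
write_spot_tables <- function(spots, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(spots), function(aid) {
    p <- file.path(dir, paste0(aid, ".tsv"))
    utils::write.table(spots[[aid]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' @rdname write_spot_tables
#' @param paths TSV files, one per array.
#' @export
read_spot_tables <- function(paths) {
  out <- lapply(paths, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("array_id", "gene_id", "spot_rep", "f_num", "f_den", "flag")
    if (!all(need %in% names(df)))
      stop("spot table ", basename(p), " needs columns: ",
           paste(need, collapse = ", "))
    df$flag <- as.logical(df$flag)
    df
  })
  names(out) <- vapply(out, function(df) df$array_id[1L], "")
  structure(out, class = "spot_tables")
}
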