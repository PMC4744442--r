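#' Test a gene set against a phenotype by SDR permutation
#'
#' The main fitting/testing function. Standardizes the expression block once
#' (the transform depends on X only, never on the phenotype), slices the
#' samples by phenotype, computes the chosen sliced-average-variance statistic,
#' and assesses significance by permuting phenotype labels: permuting labels
#' preserves slice sizes, so only slice memberships change across replicates.
#' The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{b : stat_b \ge stat_{obs}\}) / (B + 1)}, with ties
#' counting toward the numerator, so `p >= 1/(B+1)` always.
#'
#' For the statistics with a per-gene decomposition (`T`, `Tstar`), each
#' observed per-gene contribution is compared with its own permutation
#' distribution from the same replicates, giving self-contained (unadjusted)
#' per-gene p-values.
#'
#' @param x Expression matrix, samples in rows, genes in columns.
#' @param y Phenotype vector, one value per sample (binary, categorical or
#'   continuous).
#' @param statistic `"T"` (coexpression-sensitive SAVE statistic), `"V"`
#'   (mean-augmented), `"Tstar"`/`"Vstar"` (unstandardized variants), or
#'   `"auto"`: `T` for categorical phenotypes, `V` for continuous ones.
#' @param slices Slice specification for continuous phenotypes: integer count,
#'   `"auto"` for `max(2, round(0.1 n))`, or `NULL` for the default of 2.
#'   Categorical phenotypes always use their natural slicing.
#' @param n_perm Number of label permutations `B` (default 1000; at least 99
#'   recommended for reportable p-values).
#' @param seed Integer seed making the permutation stream reproducible. If
#'   `NULL`, one is drawn from the session RNG and stored in the result.
#' @param standardize `"auto"`, `"exact"`, `"shrinkage"` or `"none"`; `"auto"`
#'   uses exact whitening when the pooled covariance is nonsingular, shrinkage
#'   otherwise, and centering only for the starred statistics.
#' @param divisor Covariance divisor convention, `"n"` (default) or `"n-1"`.
#' @param gene_level Compute per-gene permutation p-values (only meaningful
#'   for `T`/`Tstar`; default `TRUE` for those, ignored otherwise).
#' @param phenotype_type Force `"categorical"` or `"continuous"`; `NULL`
#'   infers (with a message).
#' @param quiet Suppress inference/fallback messages.
#' @return An object of class `"sdr_test"` with components `statistic_name`,
#'   `statistic`, `p_value`, `gene_contributions`, `gene_fractions`,
#'   `gene_p_values` (or `NULL`), `perm_stats`, `n_perm`, `seed`, `H`,
#'   `slice_sizes`, `standardize_mode`, `n`, `p`, `gene_ids`, `call`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 6), 40, 6)
#' y <- rep(c("ctrl", "case"), each = 20)
#' fit <- sdr_test(x, y, n_perm = 199, seed = 7, quiet = TRUE)
#' fit
#' @export
sdr_test <- function(x, y,
                     statistic = c("auto", "T", "V", "Tstar", "Vstar"),
                     slices = NULL, n_perm = 1000L, seed = NULL,
                     standardize = c("auto", "exact", "shrinkage", "none"),
                     divisor = c("n", "n-1"), gene_level = NULL,
                     phenotype_type = NULL, quiet = FALSE) {
  statistic <- match.arg(statistic)
  standardize <- match.arg(standardize)
  divisor <- match.arg(divisor)
  cl <- match.call()
  x <- .check_expression(x)
  if (length(y) != nrow(x)) {
    stop("phenotype length does not match the number of samples",
         call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (n_perm < 99L) {
    warning("fewer than 99 permutations; p-values are coarse",
            call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)

  ptype <- if (is.null(phenotype_type)) {
    t <- .infer_phenotype_type(y)
    if (!quiet) message("phenotype treated as ", t)
    t
  } else match.arg(phenotype_type, c("categorical", "continuous"))
  part <- make_slices(y, slices = slices, type = ptype, quiet = TRUE)

  if (statistic == "auto") {
    statistic <- if (ptype == "categorical") "T" else "V"
    if (!quiet) message("statistic 'auto' resolved to ", statistic)
  }
  starred <- statistic %in% c("Tstar", "Vstar")
  if (standardize == "auto") standardize <- if (starred) "none" else "auto"
  if (starred && !standardize %in% "none") {
    stop("statistics T*/V* are defined on centered, unstandardized data; ",
         "use standardize = \"none\"", call. = FALSE)
  }
  if (!starred && standardize == "none") {
    stop("statistics T/V require standardized data; ",
         "choose exact/shrinkage standardization or the starred variants",
         call. = FALSE)
  }
  std <- standardize_expression(x, mode = standardize, divisor = divisor,
                                quiet = quiet)

  if (is.null(gene_level)) gene_level <- statistic %in% c("T", "Tstar")
  gene_level <- gene_level && statistic %in% c("T", "Tstar")

  eng <- .perm_engine(std, part, stats = statistic, n_perm = n_perm,
                      seed = seed, gene_level = gene_level)
  obs <- eng$observed[[statistic]]
  perm <- eng$perm[, statistic]
  p_value <- (1 + sum(perm >= obs)) / (n_perm + 1)

  gene_contrib <- gene_frac <- gene_p <- NULL
  if (!is.null(eng$gene_obs)) {
    gene_contrib <- eng$gene_obs
    tot <- sum(gene_contrib)
    gene_frac <- if (tot > 0) gene_contrib / tot
                 else rep(1 / length(gene_contrib), length(gene_contrib))
    if (gene_level) {
      ge <- sweep(eng$gene_perm, 2L, gene_contrib, `>=`)
      gene_p <- (1 + colSums(ge)) / (n_perm + 1)
    }
    nm <- colnames(x)
    names(gene_contrib) <- names(gene_frac) <- nm
    if (!is.null(gene_p)) names(gene_p) <- nm
  }

  structure(
    list(statistic_name = statistic, statistic = obs, p_value = p_value,
         gene_contributions = gene_contrib, gene_fractions = gene_frac,
         gene_p_values = gene_p, perm_stats = perm, n_perm = n_perm,
         seed = seed, H = part$H, slice_sizes = part$sizes,
         phenotype_type = ptype, standardize_mode = std$mode,
         shrinkage_lambda = std$lambda, divisor = divisor,
         n = nrow(x), p = ncol(x), gene_ids = colnames(x), call = cl),
    class = "sdr_test"
  )
}

# Shared permutation engine. `stats` may name several statistics; all are
# evaluated on the same permutation stream (one observed pass + n_perm
# permuted passes). Standardization is computed by the caller, once.
.perm_engine <- function(std, part, stats, n_perm, seed,
                         gene_level = FALSE) {
  zm <- std$values
  n <- nrow(zm)
  identity_pooled <- std$mode %in% c("exact", "shrinkage")
  pooled <- if (identity_pooled) NULL else std$pooled_cov
  pooled_sqrt <- if (!identity_pooled && any(stats == "Vstar")) {
    sym_matrix_power(std$pooled_cov, 1 / 2)
  } else NULL
  gene_level <- gene_level && any(stats %in% c("T", "Tstar"))

  obs <- .stats_for_labels(zm, part$labels, part$H, part$proportions, stats,
                           pooled, pooled_sqrt, std$divisor, gene_level)
  perm <- matrix(NA_real_, n_perm, length(stats),
                 dimnames = list(NULL, stats))
  gene_perm <- if (gene_level) matrix(NA_real_, n_perm, ncol(zm)) else NULL
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    lab <- part$labels[sample.int(n)]
    r <- .stats_for_labels(zm, lab, part$H, part$proportions, stats,
                           pooled, pooled_sqrt, std$divisor, gene_level)
    perm[b, ] <- r$values
    if (gene_level) gene_perm[b, ] <- r$gene
  }
  list(observed = as.list(obs$values), perm = perm,
       gene_obs = obs$gene, gene_perm = gene_perm)
}

#' @export
print.sdr_test <- function(x, ...) {
  cat("SDR gene set association test\n")
  cat(sprintf("  statistic: SDR_%s = %.6g\n", x$statistic_name, x$statistic))
  cat(sprintf("  permutation p-value: %.4g  (B = %d, seed = %d)\n",
              x$p_value, x$n_perm, x$seed))
  cat(sprintf("  n = %d samples, p = %d genes, H = %d slices (%s)\n",
              x$n, x$p, x$H, paste(x$slice_sizes, collapse = "+")))
  cat(sprintf("  standardization: %s%s\n", x$standardize_mode,
              if (!is.na(x$shrinkage_lambda))
                sprintf(" (lambda = %.3f)", x$shrinkage_lambda) else ""))
  invisible(x)
}

#' Summarize an SDR gene set test
#'
#' @param object An `"sdr_test"` object.
#' @param p_adjust `"none"` (default; the test itself reports raw per-gene
#'   p-values) or `"BH"` to append a Benjamini-Hochberg adjusted column as an
#'   extension.
#' @param top Number of top genes (by contribution fraction) to keep in the
#'   gene table; `Inf` for all.
#' @param ... Unused.
#' @return An `"summary.sdr_test"` list with the set-level results and a
#'   `genes` data frame (contribution, fraction, permutation p-value) when the
#'   statistic decomposes by gene.
#' @export
summary.sdr_test <- function(object, p_adjust = c("none", "BH"), top = 10L,
                             ...) {
  p_adjust <- match.arg(p_adjust)
  genes <- NULL
  if (!is.null(object$gene_contributions)) {
    genes <- data.frame(
      gene = names(object$gene_contributions) %||%
        paste0("g", seq_along(object$gene_contributions)),
      contribution = unname(object$gene_contributions),
      fraction = unname(object$gene_fractions),
      stringsAsFactors = FALSE
    )
    if (!is.null(object$gene_p_values)) {
      genes$p_value <- unname(object$gene_p_values)
      if (p_adjust == "BH") {
        genes$p_BH <- stats::p.adjust(genes$p_value, method = "BH")
      }
    }
    genes <- genes[order(-genes$fraction), , drop = FALSE]
    if (is.finite(top)) genes <- utils::head(genes, top)
    rownames(genes) <- NULL
  }
  structure(list(test = object, genes = genes, p_adjust = p_adjust),
            class = "summary.sdr_test")
}

#' @export
print.summary.sdr_test <- function(x, ...) {
  print(x$test)
  if (!is.null(x$genes)) {
    cat("\nTop gene contributions:\n")
    print(x$genes, digits = 4)
  }
  invisible(x)
}

#' Per-gene contributions of a fitted SDR test
#'
#' For the decomposable statistics, `coef()` returns the per-gene
#' contributions `T_i` (summing to the set-level statistic).
#'
#' @param object An `"sdr_test"` object.
#' @param ... Unused.
#' @export
coef.sdr_test <- function(object, ...) object$gene_contributions

#' Plot the permutation null of an SDR test
#'
#' Histogram of the permuted statistic values with the observed value marked;
#' optionally a bar plot of per-gene contribution fractions.
#'
#' @param x An `"sdr_test"` object.
#' @param which `"null"` (default) and/or `"genes"`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.sdr_test <- function(x, which = "null", ...) {
  if ("null" %in% which) {
    graphics::hist(x$perm_stats,
                   main = sprintf("Permutation null of SDR_%s",
                                  x$statistic_name),
                   xlab = "statistic",
                   xlim = range(c(x$perm_stats, x$statistic)), ...)
    graphics::abline(v = x$statistic, col = 2, lwd = 2)
  }
  if ("genes" %in% which && !is.null(x$gene_fractions)) {
    graphics::barplot(sort(x$gene_fractions, decreasing = TRUE),
                      las = 2, ylab = "fraction of statistic")
  }
  invisible(x)
}
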