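#' Read a delimited expression matrix
#'
#' Reads a tab- or comma-delimited text file with a header row of sample ids
#' and a first column of gene ids (the microarray convention, genes in rows).
#' Use `samples_in_rows = TRUE` for the transposed layout. Missing or
#' non-numeric cells are an error (they must be handled upstream, never
#' silently dropped), as are duplicate gene ids unless
#' `duplicates = "first"`.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param samples_in_rows Orientation flag; default genes-in-rows.
#' @param sep Field delimiter override.
#' @param duplicates `"error"` (default) or `"first"` (keep first occurrence
#'   of a duplicated gene id, with a warning).
#' @return Numeric matrix, samples in rows and genes in columns, with sample
#'   ids as row names and gene ids as column names.
#' @export
read_expression <- function(path, samples_in_rows = FALSE, sep = NULL,
                            duplicates = c("error", "first")) {
  duplicates <- match.arg(duplicates)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs an id column plus data",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric entry at row %d, column '%s': '%s'",
                     bad[1L], names(vals)[j], col[bad[1L]]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row id '%s', column '%s'",
                 ids[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  rownames(m) <- ids
  if (!samples_in_rows) m <- t(m)
  gid <- colnames(m)
  if (anyDuplicated(gid)) {
    if (duplicates == "error") {
      stop("duplicate gene ids: ",
           paste(unique(gid[duplicated(gid)]), collapse = ", "),
           "; rerun with duplicates = \"first\" to keep first occurrences",
           call. = FALSE)
    }
    warning("duplicate gene ids collapsed to first occurrence", call. = FALSE)
    m <- m[, !duplicated(gid), drop = FALSE]
  }
  .check_expression(m)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: writes genes in rows (default) with a
#' header of sample ids and a leading gene-id column.
#'
#' @param x Samples-by-genes numeric matrix with dimnames.
#' @param path Output path; `.csv` selects comma delimiting.
#' @param samples_in_rows Write the transposed layout instead.
#' @export
write_expression <- function(x, path, samples_in_rows = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- if (samples_in_rows) x else t(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column phenotype file
#'
#' Expects a delimited file with a header and two columns: sample id and
#' phenotype value. Values that parse as numbers become numeric.
#'
#' @param path File path (`.csv` comma, otherwise tab, unless `sep` given).
#' @param sep Field delimiter override.
#' @return Named vector (names are sample ids).
#' @export
read_phenotype <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs (sample_id, value) columns",
                          call. = FALSE)
  y <- df[[2L]]
  if (anyNA(y)) stop("missing phenotype values", call. = FALSE)
  names(y) <- as.character(df[[1L]])
  y
}

#' Read a GMT gene set collection
#'
#' Standard MSigDB format: one set per line, tab-delimited as
#' `name TAB description TAB gene1 TAB gene2 ...`. Duplicated gene ids within
#' a set are removed with a warning; a line with fewer than three fields is a
#' parse error naming the line.
#'
#' @param path GMT file path.
#' @return An object of class `"sdr_gene_sets"`: a named list of character
#'   vectors with a `"descriptions"` attribute, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicated gene id(s) removed from set '%s'", f[1L]),
              call. = FALSE)
      genes <- unique(genes)
    }
    if (f[1L] %in% names(sets)) {
      stop(sprintf("duplicate set name '%s'", f[1L]), call. = FALSE)
    }
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  structure(sets, descriptions = desc, class = "sdr_gene_sets")
}

#' Write a gene set collection in GMT format
#' @param sets Named list of character vectors (or `"sdr_gene_sets"`).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sdr_gene_sets <- function(x, ...) {
  cat(sprintf("Gene set collection: %d set(s)\n", length(x)))
  sz <- lengths(x)
  if (length(x)) {
    cat(sprintf("set sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' Filter a gene set collection against an expression matrix
#'
#' Intersects each set with the measured gene ids and keeps sets whose
#' surviving size lies in `[min_size, max_size]` (the 10..500 convention for
#' curated collections).
#'
#' @param sets `"sdr_gene_sets"` object or named list of gene id vectors.
#' @param gene_ids Character vector of measured gene ids, or a samples by
#'   genes matrix whose column names are used.
#' @param min_size,max_size Inclusive size bounds after intersection.
#' @return Filtered `"sdr_gene_sets"` collection (original order kept).
#' @export
filter_sets <- function(sets, gene_ids, min_size = 10L, max_size = 500L) {
  if (is.matrix(gene_ids)) gene_ids <- colnames(gene_ids)
  trimmed <- lapply(sets, function(g) g[g %in% gene_ids])
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  out <- trimmed[keep]
  attr(out, "descriptions") <- attr(sets, "descriptions")[names(out)]
  class(out) <- "sdr_gene_sets"
  out
}

#' Run SDR gene set analysis over a collection
#'
#' Orchestrates the full screen: aligns expression and phenotype by sample id
#' (order-insensitive), filters the collection by post-intersection size, and
#' runs [sdr_test()] on every surviving set with a per-set seed derived from
#' `seed` (so results do not depend on the order sets are processed).
#'
#' @param expr Samples-by-genes expression matrix with dimnames (see
#'   [read_expression()]).
#' @param pheno Named phenotype vector; names must match the expression
#'   sample ids (any order).
#' @param sets Gene set collection ([read_gmt()]) or a named list.
#' @param statistic,slices,n_perm,standardize,divisor,phenotype_type
#'   Passed to [sdr_test()].
#' @param seed Master seed (default 1).
#' @param min_size,max_size Size filter, see [filter_sets()].
#' @param gene_level Also return the per-gene contribution table.
#' @return An object of class `"sdr_gsa"`: list with `sets` (data frame:
#'   set_name, set_size, genes_found, statistic_name, statistic, p_value) and
#'   `genes` (data frame of per-gene rows, or `NULL`).
#' @export
sdr_gsa <- function(expr, pheno, sets,
                    statistic = "auto", slices = NULL, n_perm = 1000L,
                    seed = 1L, min_size = 10L, max_size = 500L,
                    standardize = "auto", divisor = "n",
                    gene_level = FALSE, phenotype_type = NULL) {
  expr <- .check_expression(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs sample ids",
                                    call. = FALSE)
  if (is.null(names(pheno))) stop("phenotype needs sample ids (names)",
                                  call. = FALSE)
  miss_e <- setdiff(rownames(expr), names(pheno))
  miss_p <- setdiff(names(pheno), rownames(expr))
  if (length(miss_e) || length(miss_p)) {
    stop("sample id mismatch between expression and phenotype; ",
         "unmatched: ",
         paste(utils::head(c(miss_e, miss_p), 10L), collapse = ", "),
         call. = FALSE)
  }
  pheno <- pheno[rownames(expr)]

  orig_sizes <- lengths(sets)
  fsets <- filter_sets(sets, colnames(expr), min_size, max_size)
  if (length(fsets) == 0L) {
    stop("no gene set survives the size filter against this matrix",
         call. = FALSE)
  }
  dropped <- setdiff(names(sets), names(fsets))
  if (length(dropped)) {
    message(length(dropped), " set(s) dropped by the size filter")
  }

  ptype <- if (is.null(phenotype_type)) .infer_phenotype_type(pheno)
           else phenotype_type
  message("phenotype treated as ", ptype)

  rows <- vector("list", length(fsets))
  gene_rows <- list()
  for (i in seq_along(fsets)) {
    nm <- names(fsets)[i]
    sub <- expr[, fsets[[i]], drop = FALSE]
    fit <- sdr_test(sub, pheno, statistic = statistic, slices = slices,
                    n_perm = n_perm,
                    seed = (seed + i) %% 2147483647L,
                    standardize = standardize, divisor = divisor,
                    gene_level = gene_level, phenotype_type = ptype,
                    quiet = TRUE)
    rows[[i]] <- data.frame(
      set_name = nm,
      set_size = unname(orig_sizes[nm]),
      genes_found = ncol(sub),
      statistic_name = fit$statistic_name,
      statistic = fit$statistic,
      p_value = fit$p_value,
      stringsAsFactors = FALSE
    )
    if (gene_level && !is.null(fit$gene_contributions)) {
      gene_rows[[nm]] <- data.frame(
        set_name = nm,
        gene = names(fit$gene_contributions),
        contribution = unname(fit$gene_contributions),
        fraction = unname(fit$gene_fractions),
        p_value = if (!is.null(fit$gene_p_values))
          unname(fit$gene_p_values) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(sets = do.call(rbind, rows),
         genes = if (length(gene_rows)) do.call(rbind, c(gene_rows,
                                                         make.row.names = FALSE))
                 else NULL,
         seed = seed, n_perm = n_perm),
    class = "sdr_gsa"
  )
}

#' @export
print.sdr_gsa <- function(x, ...) {
  cat(sprintf("SDR gene set analysis: %d set(s), B = %d permutations\n",
              nrow(x$sets), x$n_perm))
  print(utils::head(x$sets[order(x$sets$p_value), , drop = FALSE], 10L),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a GSA report as TSV
#'
#' @param result `"sdr_gsa"` object.
#' @param path Set-level output path.
#' @param gene_path Optional per-gene table path.
#' @export
write_gsa_report <- function(result, path, gene_path = NULL) {
  utils::write.table(result$sets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(gene_path) && !is.null(result$genes)) {
    utils::write.table(result$genes, gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a flat key=value scenario configuration
#'
#' Configuration files for the command-line `simulate` and `evaluate`
#' subcommands: one `key = value` pair per line, `#` comments allowed. The
#' `design` key selects `binary`, `threeclass` or `continuous`; remaining
#' keys are the matching constructor's arguments (see [sdr_scenarios]),
#' e.g. `n`, `p`, `variance`, `gamma`, `rho`, `null`, `p1`, `link`, `nu`.
#'
#' @param path Configuration file path.
#' @return A scenario object.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  cfg <- stats::setNames(as.list(vals), keys)
  design <- cfg$design %||% stop("scenario file must set 'design'",
                                 call. = FALSE)
  cfg$design <- NULL
  num <- suppressWarnings(lapply(cfg, function(v) {
    n <- as.numeric(v)
    if (!is.na(n)) n
    else if (v %in% c("true", "TRUE", "yes")) TRUE
    else if (v %in% c("false", "FALSE", "no")) FALSE
    else v
  }))
  ctor <- switch(design,
                 binary = binary_scenario,
                 threeclass = threeclass_scenario,
                 continuous = continuous_scenario,
                 stop("unknown design '", design, "'", call. = FALSE))
  do.call(ctor, num)
}
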