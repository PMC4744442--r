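#' Slice a categorical phenotype
#'
#' Categorical (binary, multi-class or discrete) phenotypes have a natural
#' slicing: one slice per distinct level, in sorted level order.
#'
#' @param y Vector of phenotype labels (factor, character, logical or a
#'   numeric vector of class codes).
#' @return An object of class `"sdr_slices"`: list with `labels` (integer
#'   vector in `1..H`), `H`, `sizes` and `proportions`.
#' @examples
#' slice_categorical(c("A", "A", "B", "B", "B"))
#' @export
slice_categorical <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  n <- length(y)
  lev <- sort(unique(y))
  if (length(lev) < 2L) {
    stop("categorical phenotype needs at least 2 distinct levels",
         call. = FALSE)
  }
  labels <- match(y, lev)
  sizes <- tabulate(labels, nbins = length(lev))
  if (any(sizes < 2L)) {
    stop(sprintf("phenotype level(s) with fewer than 2 samples: %s",
                 paste(lev[sizes < 2L], collapse = ", ")), call. = FALSE)
  }
  .new_slices(labels, length(lev), level_names = as.character(lev))
}

#' Slice a continuous phenotype into rank-based bins
#'
#' Monotonic discretization: samples are ordered by phenotype value and cut
#' into `H` contiguous slices of as-equal-as-possible size (sizes differ by at
#' most one; the first `n %% H` slices take the extra sample). Slice 1 holds
#' the smallest values. Ties are broken by original sample order, so the
#' partition is deterministic and invariant under any strictly increasing
#' transform of `y`.
#'
#' @param y Numeric phenotype vector.
#' @param H Number of slices, `2 <= H <= n/2` so every slice has at least two
#'   samples.
#' @return An `"sdr_slices"` object (see [slice_categorical()]).
#' @examples
#' slice_continuous(c(0.1, 0.9, 0.5, 0.3), H = 2)$labels  # 1 2 2 1
#' @export
slice_continuous <- function(y, H = 2L) {
  if (!is.numeric(y)) stop("continuous phenotype must be numeric", call. = FALSE)
  n <- length(y)
  H <- as.integer(H)
  if (H < 2L) stop("H must be at least 2", call. = FALSE)
  if (H > n %/% 2L) {
    stop(sprintf("too many slices: H = %d leaves slices of size < 2 (n = %d)",
                 H, n), call. = FALSE)
  }
  ord <- order(y)                      # stable (radix) for numeric input
  base <- n %/% H
  extra <- n %% H
  sizes <- rep.int(base, H) + rep.int(c(1L, 0L), c(extra, H - extra))
  labels <- integer(n)
  labels[ord] <- rep.int(seq_len(H), sizes)
  if (anyDuplicated(y)) {
    bnd <- cumsum(sizes[-H])
    ys <- y[ord]
    if (any(ys[bnd] == ys[bnd + 1L])) {
      message("tied phenotype values straddle a slice boundary; ",
              "split by original sample order")
    }
  }
  .new_slices(labels, H)
}

#' Build a slice partition from any phenotype
#'
#' Dispatches on the phenotype kind: categorical phenotypes get their natural
#' slicing, continuous ones a rank-based partition. The kind is inferred
#' unless given: non-numeric vectors are categorical; numeric vectors are
#' categorical when integer-valued with at most 10 distinct levels, else
#' continuous. Inference is always reported via `message()` so it is never
#' silent.
#'
#' @param y Phenotype vector.
#' @param slices For continuous phenotypes: an integer slice count, or
#'   `"auto"` for the `max(2, round(0.1 n))` rule of thumb. Default 2 slices.
#'   Ignored (with a message) for categorical phenotypes.
#' @param type `"categorical"`, `"continuous"` or `NULL` to infer.
#' @param quiet Suppress inference messages.
#' @return An `"sdr_slices"` object.
#' @export
make_slices <- function(y, slices = NULL, type = NULL, quiet = FALSE) {
  if (is.null(type)) {
    type <- .infer_phenotype_type(y)
    if (!quiet) message("phenotype treated as ", type)
  }
  type <- match.arg(type, c("categorical", "continuous"))
  if (type == "categorical") {
    if (!is.null(slices) && !identical(slices, "auto") && !quiet) {
      message("'slices' ignored for a categorical phenotype (natural slicing)")
    }
    slice_categorical(y)
  } else {
    n <- length(y)
    H <- if (is.null(slices)) 2L
         else if (identical(slices, "auto")) max(2L, as.integer(round(0.1 * n)))
         else as.integer(slices)
    slice_continuous(y, H)
  }
}

.infer_phenotype_type <- function(y) {
  if (is.factor(y) || is.character(y) || is.logical(y)) return("categorical")
  if (!is.numeric(y)) stop("unsupported phenotype type", call. = FALSE)
  u <- unique(y)
  if (length(u) <= 10L && all(y == round(y))) "categorical" else "continuous"
}

.new_slices <- function(labels, H, level_names = NULL) {
  sizes <- tabulate(labels, nbins = H)
  stopifnot(all(sizes >= 2L))
  structure(
    list(labels = labels, H = H, sizes = sizes,
         proportions = sizes / length(labels), level_names = level_names),
    class = "sdr_slices"
  )
}

#' @export
print.sdr_slices <- function(x, ...) {
  cat(sprintf("Slice partition: H = %d, n = %d\n", x$H, length(x$labels)))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}
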