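#' Normalize functional-category profiles
#'
#' Scales each sample's counts to relative abundances (row sums 1), matching
#' the percentage-of-annotated-reads convention used when comparing
#' metagenomes across ecosystems. With `mode = "relative_standardize"` the
#' category columns are additionally z-standardized (mean 0, sd 1);
#' zero-variance categories are dropped with a warning.
#'
#' @param profiles Tibble with `sample_id`, optional `ecosystem`, and
#'   non-negative numeric category columns.
#' @param mode `"relative"` or `"relative_standardize"`.
#' @return The normalized profile tibble.
#' @export
normalize_profiles <- function(profiles, mode = c("relative", "relative_standardize")) {
  mode <- match.arg(mode)
  meta_cols <- intersect(c("sample_id", "ecosystem"), names(profiles))
  m <- as.matrix(profiles[, setdiff(names(profiles), meta_cols)])
  if (any(m < 0)) abort("negative values in profile matrix")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    bad <- profiles$sample_id[tot == 0]
    abort(paste0("all-zero profile for sample(s): ", paste(bad, collapse = ", ")))
  }
  m <- m / tot
  if (mode == "relative_standardize") {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warn(paste0("dropping zero-variance categories: ",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
      m <- m[, sds > 0, drop = FALSE]
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  bind_cols(profiles[, meta_cols, drop = FALSE], as_tibble(m))
}

#' PCA ordination of functional profiles
#'
#' Centers the samples-by-categories matrix and decomposes it by singular
#' values (covariance PCA; set `scale = TRUE` for correlation PCA). Loading
#' signs follow the convention that each loading vector's largest-magnitude
#' entry is positive. Explained variance fractions are nonincreasing, and
#' retaining all components reconstructs the input exactly.
#'
#' @param profiles Normalized profile tibble (see [normalize_profiles()]).
#' @param n_components Components to retain (<= min(n samples - 1,
#'   n categories)).
#' @param scale Use correlation instead of covariance PCA.
#' @return A `profile_pca` object: `scores` tibble (sample metadata + PC
#'   columns), `loadings` matrix, `explained` fractions, `center`/`scale`
#'   vectors.
#' @export
profile_pca <- function(profiles, n_components = 2, scale = FALSE) {
  meta_cols <- intersect(c("sample_id", "ecosystem"), names(profiles))
  m <- as.matrix(profiles[, setdiff(names(profiles), meta_cols)])
  if (nrow(m) < 2 || ncol(m) < 2) abort("need >= 2 samples and >= 2 categories")
  max_comp <- min(nrow(m) - 1, ncol(m))
  if (n_components > max_comp) {
    abort(paste0("n_components must be <= ", max_comp))
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = scale)

  # sign convention: largest-magnitude loading entry positive
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  fit$rotation <- sweep(fit$rotation, 2, flip, `*`)
  fit$x <- sweep(fit$x, 2, flip, `*`)

  explained <- fit$sdev^2 / sum(fit$sdev^2)
  keep <- seq_len(n_components)
  scores <- bind_cols(profiles[, meta_cols, drop = FALSE],
                      as_tibble(fit$x[, keep, drop = FALSE]))
  structure(
    list(scores = scores,
         loadings = fit$rotation[, keep, drop = FALSE],
         explained = explained[keep],
         explained_all = explained,
         rotation_all = fit$rotation,
         scores_all = fit$x,
         center = fit$center,
         scale = if (scale) fit$scale else NULL,
         n_components = as.integer(n_components)),
    class = "profile_pca"
  )
}

#' @export
print.profile_pca <- function(x, ...) {
  cat("<profile_pca> ", nrow(x$scores), " samples, ", x$n_components,
      " components (", paste0(round(100 * x$explained, 1), "%", collapse = ", "),
      " of variance)\n", sep = "")
  invisible(x)
}

#' Tidiers for dwbiofilm result objects
#'
#' [generics::tidy()] and [generics::glance()] methods: `tidy()` returns the
#' per-sample scores (`matrix = "scores"`, default), per-category loadings
#' (`"loadings"`) or explained-variance fractions (`"eigenvalues"`) of a
#' `profile_pca`, and the member-contig table of a `genome_bin`; `glance()`
#' returns one-row summaries.
#'
#' @param x A `profile_pca` or `genome_bin` object.
#' @param matrix For `profile_pca`: which component of the fit to return.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_dwbiofilm
NULL

#' @rdname tidy_dwbiofilm
#' @export
tidy.profile_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores,
                                 cols = dplyr::starts_with("PC"),
                                 names_to = "component", values_to = "score"),
    loadings = as_tibble(x$loadings, rownames = "category") |>
      tidyr::pivot_longer(-"category", names_to = "component",
                          values_to = "loading"),
    eigenvalues = tibble(component = paste0("PC", seq_along(x$explained_all)),
                         explained_fraction = x$explained_all)
  )
}

#' @rdname tidy_dwbiofilm
#' @export
glance.profile_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_categories = nrow(x$rotation_all),
         n_components = x$n_components,
         explained_retained = sum(x$explained))
}

#' Plot a PCA ordination
#'
#' PC1 x PC2 scatter of the sample scores, coloured by ecosystem label when
#' present, with explained-variance percentages on the axes.
#'
#' @param object A `profile_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_pca <- function(object, ...) {
  sc <- object$scores
  if (!all(c("PC1", "PC2") %in% names(sc))) {
    abort("autoplot needs at least 2 retained components")
  }
  aes_args <- if ("ecosystem" %in% names(sc)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$ecosystem)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(sc, aes_args) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = "Ecosystem"
    ) +
    ggplot2::theme_minimal()
}

#' Reconstruct the centered data from a PCA fit
#'
#' With all components retained, `scores %*% t(loadings) + center`
#' reproduces the input matrix; useful as a numerical check.
#'
#' @param x A `profile_pca`.
#' @return Numeric matrix on the scale of the input profiles.
#' @export
pca_reconstruct <- function(x) {
  m <- x$scores_all %*% t(x$rotation_all)
  if (!is.null(x$scale)) m <- sweep(m, 2, x$scale, `*`)
  sweep(m, 2, x$center, `+`)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
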