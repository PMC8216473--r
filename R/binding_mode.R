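#' Per-miRNA binding-position frequency profile
#'
#' For each miRNA, counts across all its heteroduplexes how often each miRNA
#' position is paired to the target, and normalizes the row to `[0, 1]` —
#' by its maximum positional count (default, so the preferred positions read
#' 1) or by its total. Rows are padded with 0 to the longest miRNA. The
#' profile rows are the objects clustered to compare miRNA modes of binding
#' (seed-focused vs 3'-extended pairing).
#'
#' @param duplexes Heteroduplex tibble with `mirna`, `len_mirna` and the
#'   `pairing_mask` list-column (internal engine output only; imported
#'   predictions carry no mask).
#' @param mirnas Optional character vector of miRNA names fixing the row
#'   set; miRNAs with zero duplexes get a zero row and a warning.
#' @param normalize `"max"` (default) or `"sum"`.
#' @return An object of class `binding_profile`: list with `matrix`
#'   (miRNA x position, rows in `[0,1]`) and `n_sites` (named per-miRNA
#'   duplex counts).
#' @export
position_frequency_matrix <- function(duplexes, mirnas = NULL,
                                      normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  if (is.null(mirnas)) mirnas <- sort(unique(duplexes$mirna))
  width <- max(c(duplexes$len_mirna, 1L))
  mat <- matrix(0, nrow = length(mirnas), ncol = width,
                dimnames = list(mirnas, paste0("p", seq_len(width))))
  n_sites <- setNames(integer(length(mirnas)), mirnas)
  for (m in mirnas) {
    masks <- duplexes$pairing_mask[duplexes$mirna == m]
    n_sites[m] <- length(masks)
    if (length(masks) == 0) {
      warn(sprintf("miRNA %s has no binding sites; zero profile row", m))
      next
    }
    counts <- rep(0, width)
    for (mk in masks) counts[seq_along(mk)] <- counts[seq_along(mk)] + mk
    denom <- if (normalize == "max") max(counts) else sum(counts)
    if (denom > 0) mat[m, ] <- counts / denom
  }
  structure(list(matrix = mat, n_sites = n_sites),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("binding_profile:", nrow(x$matrix), "miRNAs x", ncol(x$matrix),
      "positions\n")
  invisible(x)
}

#' @rdname position_frequency_matrix
#' @param object A `binding_profile`.
#' @param ... Unused.
#' @method autoplot binding_profile
#' @export
autoplot.binding_profile <- function(object, ...) {
  df <- as_tibble(object$matrix, rownames = "mirna") |>
    tidyr::pivot_longer(-"mirna", names_to = "position",
                        values_to = "frequency") |>
    mutate(position = as.integer(sub("^p", "", .data$position)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mirna,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "miRNA position (5' to 3')", y = NULL,
                  fill = "paired\nfrequency") +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of binding profiles
#'
#' Agglomerative clustering of the profile rows with Euclidean distance and
#' complete linkage, cut into `n_groups` groups.
#'
#' @param profile A `binding_profile` (or a plain numeric matrix).
#' @param n_groups Number of groups to cut the tree into.
#' @return A list: `labels` (tibble `mirna`, `cluster`) and `tree` (the
#'   `hclust` object).
#' @export
hierarchical_clusters <- function(profile, n_groups) {
  mat <- if (inherits(profile, "binding_profile")) profile$matrix else profile
  if (n_groups > nrow(mat)) abort("n_groups exceeds the number of miRNAs")
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "complete")
  cl <- stats::cutree(tree, k = n_groups)
  list(labels = tibble(mirna = rownames(mat), cluster = unname(cl)),
       tree = tree)
}

#' K-means clustering of binding profiles
#'
#' Seeded `stats::kmeans` with `n_init` random restarts keeping the best
#' within-cluster sum of squares; deterministic given `seed`.
#'
#' @param profile A `binding_profile` (or a plain numeric matrix).
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param n_init Number of restarts.
#' @return Tibble `mirna`, `cluster`.
#' @export
kmeans_clusters <- function(profile, k, seed = 1, n_init = 10) {
  mat <- if (inherits(profile, "binding_profile")) profile$matrix else profile
  if (k > nrow(mat)) abort("k exceeds the number of miRNAs")
  km <- withr::with_seed(seed,
    stats::kmeans(mat, centers = k, nstart = n_init))
  tibble(mirna = rownames(mat), cluster = unname(km$cluster))
}
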