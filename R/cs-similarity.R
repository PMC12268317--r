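# Agreement of retention behaviour between systems: Pearson correlation of
# raw retention times and Spearman correlation of retention orders, plus
# average-linkage hierarchical clustering of the systems.

#' Correlation between two systems' retention times
#'
#' Pearson works on the raw retention times; Spearman is Pearson on
#' average-ranked values, i.e. tie-aware rank correlation of the retention
#' order. Pairs with fewer than 3 complete observations, or zero variance in
#' either vector, give `NA`.
#'
#' @param rts_a,rts_b paired retention times in minutes (`NA` = undetected).
#' @param method `"pearson"` or `"spearman"`.
#' @return A correlation coefficient, or `NA` if undefined.
#' @export
pairwise_correlation <- function(rts_a, rts_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(rts_a) & !is.na(rts_b)
  if (sum(ok) < 3) return(NA_real_)
  a <- rts_a[ok]; b <- rts_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  suppressWarnings(stats::cor(a, b, method = method))
}

#' Pairwise similarity matrix over all systems
#'
#' The per-pair coefficient is computed on all compounds (calibrants and
#' suspects) detected in both systems; the number of shared compounds is
#' recorded alongside.
#'
#' @param table a `retention_table` with at least 2 systems.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `similarity_matrix`: list with `cs_ids`, `method`, `values`
#'   (symmetric, unit diagonal) and `n_shared`.
#' @export
similarity_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- table_systems(table)
  if (length(ids) < 2) validation_error("need at least 2 systems")
  n <- length(ids)
  vals <- diag(1, n)
  nsh <- matrix(0L, n, n)
  dimnames(vals) <- dimnames(nsh) <- list(ids, ids)
  for (i in seq_len(n)) {
    ri <- table[[paste0("rt_", ids[i])]]
    nsh[i, i] <- sum(!is.na(ri))
    for (j in seq_len(n)[-seq_len(i)]) {
      rj <- table[[paste0("rt_", ids[j])]]
      nsh[i, j] <- nsh[j, i] <- sum(!is.na(ri) & !is.na(rj))
      vals[i, j] <- vals[j, i] <- pairwise_correlation(ri, rj, method)
    }
  }
  structure(list(cs_ids = ids, method = method, values = vals, n_shared = nsh),
            class = "similarity_matrix")
}

#' Order systems by agglomerative clustering of the similarity matrix
#'
#' Distance is `1 - coefficient`; linkage is average. Missing entries are
#' imputed with the column mean of the available distances (with a message).
#' Input rows are sorted lexically by cs_id first, so leaf order is
#' deterministic and lexical where distances tie.
#'
#' @param matrix a `similarity_matrix`.
#' @return List with `order` (cs_ids in leaf order) and `tree` (an `hclust`).
#' @export
cluster_order <- function(matrix) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  ids <- sort(matrix$cs_ids)
  d <- 1 - matrix$values[ids, ids, drop = FALSE]
  if (anyNA(d)) {
    message("cluster_order: imputing missing distances with column means")
    for (j in seq_along(ids)) {
      miss <- is.na(d[, j])
      if (any(miss)) d[miss, j] <- mean(d[!miss, j][ids[!miss] != ids[j]])
    }
    d <- (d + t(d)) / 2
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  dend <- stats::reorder(stats::as.dendrogram(tree), wts = seq_along(ids),
                         agglo.FUN = mean)
  list(order = labels(dend), tree = tree)
}
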