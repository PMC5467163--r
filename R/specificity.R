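# Multi-substrate specificity: cross-selection correlations, fitness
# landscape PCA, seven-bin Venn classification and specificity-determining
# calls.

#' Merge per-substrate fitness tables into a multi-substrate matrix
#'
#' Joins protein-level fitness tables on the variant identity, yielding one
#' zeta column per substrate plus the per-substrate detection limits.
#'
#' @param fits named list of `fitness_table`s (>= 2; names are the substrate
#'   labels).
#' @param complete_only keep only variants present in every table (default).
#' @return data.frame of class `substrate_matrix` with `variant`, `position`,
#'   `wt_aa`, `mut_aa`, `type` and one numeric column per substrate;
#'   attribute `zeta_lb` is the named vector of lower bounds.
#' @export
substrate_matrix <- function(fits, complete_only = TRUE) {
  if (length(fits) < 2L || is.null(names(fits)) || any(names(fits) == "")) {
    stop("at least two named fitness tables are required")
  }
  labels <- names(fits)
  base <- fits[[1L]][, intersect(c("variant", "position", "wt_aa", "mut_aa",
                                   "type"), names(fits[[1L]]))]
  base <- base[base$variant != "WT", , drop = FALSE]
  out <- base
  for (lab in labels) {
    f <- fits[[lab]]
    out[[lab]] <- f$zeta[match(out$variant, f$variant)]
  }
  if (complete_only) out <- out[complete.cases(out[, labels]), , drop = FALSE]
  rownames(out) <- NULL
  lbs <- vapply(fits, function(f) attr(f, "zeta_lb") %||% -Inf, 0)
  structure(out, labels = labels, zeta_lb = lbs,
            class = c("substrate_matrix", "data.frame"))
}

#' Pairwise cross-substrate correlations of fitness metrics
#'
#' Pearson correlation per substrate pair, restricted (by default) to
#' variants above both substrates' detection limits — point estimates below a
#' bound are categorical and would deflate the correlation.  Two-tailed
#' t-test P values.
#'
#' @param mat a [substrate_matrix()].
#' @param apply_lower_bounds restrict to variants above both bounds.
#' @return data.frame with `substrate_a`, `substrate_b`, `r`, `p`, `n`.
#' @export
pairwise_correlation <- function(mat, apply_lower_bounds = TRUE) {
  labels <- attr(mat, "labels")
  lbs <- attr(mat, "zeta_lb")
  pairs <- combn(labels, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- mat[[pr[1L]]]; b <- mat[[pr[2L]]]
    if (apply_lower_bounds) {
      keep <- a >= lbs[[pr[1L]]] & b >= lbs[[pr[2L]]]
      a <- a[keep]; b <- b[keep]
    }
    if (length(a) < 3L) {
      stop("insufficient data for pair ", pr[1L], " vs ", pr[2L],
           " (n = ", length(a), ")")
    }
    ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
    data.frame(substrate_a = pr[1L], substrate_b = pr[2L],
               r = unname(ct$estimate), p = ct$p.value, n = length(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PCA of the variants x substrates fitness matrix
#'
#' Columns are centered (all share zeta units; scaling to unit variance is
#' optional).  Reports both the global eigenvalue shares and, because
#' "variance of a data set explained by one component" can also mean the
#' per-column fit, the per-substrate R-squared of the rank-1 reconstruction.
#'
#' @param mat a [substrate_matrix()].
#' @param scale. scale columns to unit variance before PCA (default FALSE).
#' @return list of class `fitness_pca`: `sdev`, `rotation` (loadings),
#'   `eigenvalues`, `var_explained` (global cumulative shares),
#'   `pc1_column_r2` (per-substrate R2 of the rank-1 reconstruction), `n`.
#' @export
pca_fitness <- function(mat, scale. = FALSE) {
  labels <- attr(mat, "labels")
  X <- as.matrix(mat[, labels, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("at least 3 complete rows are required")
  vars <- apply(X, 2L, var)
  if (any(vars == 0)) {
    stop("degenerate variance: constant column(s) ",
         paste(labels[vars == 0], collapse = ", "))
  }
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  Xc <- scale(X, center = TRUE, scale = scale.)
  rank1 <- pc$x[, 1L, drop = FALSE] %*% t(pc$rotation[, 1L, drop = FALSE])
  r2 <- 1 - colSums((Xc - rank1)^2) / colSums(Xc^2)
  structure(list(sdev = pc$sdev, rotation = pc$rotation, eigenvalues = ev,
                 var_explained = cumsum(ev) / sum(ev),
                 pc1_column_r2 = r2, n = nrow(X)),
            class = "fitness_pca")
}

#' Seven-bin Venn classification of beneficial specificity
#'
#' Each variant is assigned to the subset of substrates on which it is
#' beneficial (`zeta > threshold`), yielding the seven possible non-empty
#' membership bins over three substrates (each single, each pair, all
#' three), or `"none"`.  Bins are written as the member labels joined by
#' `"+"` in matrix column order.
#'
#' @param mat a [substrate_matrix()].
#' @param threshold beneficial threshold (default 0.15).
#' @return character vector of bin labels, one per row of `mat`.
#' @export
classify_bins <- function(mat, threshold = 0.15) {
  labels <- attr(mat, "labels")
  Z <- as.matrix(mat[, labels, drop = FALSE])
  if (anyNA(Z)) stop("incomplete rows: every substrate needs a zeta value")
  member <- Z > threshold
  unname(apply(member, 1L, function(m) {
    if (!any(m)) "none" else paste(labels[m], collapse = "+")
  }))
}

#' Specificity-determining call
#'
#' A mutation is specificity-determining for a substrate when it is
#' beneficial there (`zeta > benef`) and deleterious (`zeta < 0`) on every
#' other substrate.
#'
#' @param mat a [substrate_matrix()].
#' @param benef beneficial threshold (default 0.15).
#' @return character vector: the determining substrate label or `"none"`.
#' @export
specificity_determining <- function(mat, benef = 0.15) {
  labels <- attr(mat, "labels")
  Z <- as.matrix(mat[, labels, drop = FALSE])
  if (anyNA(Z)) stop("incomplete rows: every substrate needs a zeta value")
  unname(apply(Z, 1L, function(z) {
    hit <- z > benef
    if (sum(hit) == 1L && all(z[!hit] < 0)) labels[hit] else "none"
  }))
}

#' Hotspot positions of specificity-determining mutations
#'
#' Positions carrying at least `min_count` specificity-determining mutations
#' for a given substrate.
#'
#' @param calls data.frame with `position` and `specificity_determining`
#'   columns (e.g. a [substrate_matrix()] with the call column added).
#' @param min_count minimum mutations per position (default 5).
#' @return data.frame with `substrate`, `position`, `n`, sorted by substrate
#'   then position.
#' @export
hotspot_positions <- function(calls, min_count = 5L) {
  sd_col <- calls$specificity_determining
  keep <- sd_col != "none" & !is.na(calls$position)
  if (!any(keep)) {
    return(data.frame(substrate = character(), position = integer(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  tab <- aggregate(list(n = rep(1L, sum(keep))),
                   by = list(substrate = sd_col[keep],
                             position = calls$position[keep]),
                   FUN = sum)
  tab <- tab[tab$n >= min_count, , drop = FALSE]
  tab <- tab[order(tab$substrate, tab$position), ]
  rownames(tab) <- NULL
  tab
}
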