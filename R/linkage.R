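#' Complete-linkage agglomerative clustering with deterministic tie-breaks
#'
#' Agglomerative hierarchical clustering under the complete (maximum)
#' linkage, equivalent to `hclust(dist(x), method = "complete")` except that
#' equal-distance merges are resolved deterministically: among all pairs at
#' the current minimum distance, the pair whose clusters have the smallest
#' (lexicographically ordered) minimum member labels is merged first. This
#' makes the merge sequence, and hence cluster labels, invariant to input
#' row order.
#'
#' @param d A `dist` object or symmetric distance matrix with labels.
#' @return An object of class `"hclust"` (works with [stats::cutree()],
#'   `as.dendrogram()`, `ape::as.phylo()`).
#' @export
complete_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) abort("need at least two observations to cluster")
  labels <- rownames(dm) %||% as.character(seq_len(n))
  if (!isTRUE(all.equal(dm, t(dm))) || any(!is.finite(dm[upper.tri(dm)]))) {
    abort("d must be a finite symmetric distance matrix")
  }
  diag(dm) <- Inf

  active <- rep(TRUE, n)
  key <- labels                    # min member label per active cluster
  code <- -seq_len(n)              # hclust merge coding: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- which(active)
    dsub <- dm[sub, sub, drop = FALSE]
    m <- min(dsub)
    hit <- which(dsub == m, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    i <- sub[hit[, 1]]
    j <- sub[hit[, 2]]
    k1 <- pmin(key[i], key[j])
    k2 <- pmax(key[i], key[j])
    pick <- order(k1, k2)[1]
    a <- i[pick]; b <- j[pick]

    merge[step, ] <- sort(c(code[a], code[b]))
    height[step] <- m
    # complete linkage: distance of the union is the max of the parts
    upd <- pmax(dm[a, ], dm[b, ])
    dm[a, ] <- upd
    dm[, a] <- upd
    dm[a, a] <- Inf
    active[b] <- FALSE
    key[a] <- min(key[a], key[b])
    code[a] <- step
  }

  # leaf order for plotting: concatenate subtrees recursively
  orders <- vector("list", n - 1L)
  expand <- function(x) if (x < 0) -x else orders[[x]]
  for (s in seq_len(n - 1L)) {
    orders[[s]] <- c(expand(merge[s, 1]), expand(merge[s, 2]))
  }

  structure(list(merge = merge, height = height,
                 order = orders[[n - 1L]], labels = labels,
                 method = "complete", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}
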