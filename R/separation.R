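#' Pairwise dissimilarity between two profiles
#'
#' `euclidean`: `sqrt(sum((u - v)^2))`. `bray_curtis`:
#' `sum(|u - v|) / sum(u + v)`, defined for non-negative profiles (rescale
#' signed component scores with [minmax_scale()] first); an all-zero
#' denominator yields 0 with a warning.
#'
#' @param u,v Numeric vectors of equal length.
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @export
pairwise_dissimilarity <- function(u, v, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  if (length(u) != length(v))
    stop("profiles differ in length: ", length(u), " vs ", length(v))
  if (metric == "euclidean") return(sqrt(sum((u - v)^2)))
  if (any(u < 0) || any(v < 0))
    stop("bray_curtis requires non-negative profiles; min-max rescale first")
  den <- sum(u + v)
  if (den == 0) {
    warning("all-zero profiles: Bray-Curtis defined as 0")
    return(0)
  }
  sum(abs(u - v)) / den
}

#' Min-max rescale each column to [0, 1]
#'
#' Columns are rescaled across the compared profiles jointly; a constant
#' column is set to 0 with a warning.
#'
#' @param m Numeric matrix (profiles in rows).
#' @export
minmax_scale <- function(m) {
  m <- as.matrix(m)
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0))
    warning("constant component(s) scaled to 0: ",
            paste(colnames(m)[span == 0], collapse = ", "))
  span[span == 0] <- 1
  sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
}

# full dissimilarity matrix for a profile matrix
dissimilarity_matrix <- function(profiles, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(profiles)
  if (metric == "euclidean") return(as.matrix(dist(m)))
  if (any(m < 0))
    stop("bray_curtis requires non-negative profiles; min-max rescale first")
  rs <- rowSums(m)
  den <- outer(rs, rs, "+")
  num <- matrix(0, nrow(m), nrow(m))
  for (i in seq_len(nrow(m) - 1)) {
    d <- colSums(abs(t(m[(i + 1):nrow(m), , drop = FALSE]) - m[i, ]))
    num[i, (i + 1):nrow(m)] <- d
    num[(i + 1):nrow(m), i] <- d
  }
  zero <- den == 0
  diag(zero) <- FALSE
  if (any(zero)) warning("all-zero profile pair(s): Bray-Curtis defined as 0")
  zero <- den == 0
  den[zero] <- 1
  num / den
}

# between/within mean dissimilarity ratio from a precomputed matrix
ratio_from_matrix <- function(dm, labels) {
  cls <- unique(labels)
  a <- labels == cls[1]
  na <- sum(a); nb <- sum(!a)
  sum_a <- sum(dm[a, a]) / 2
  sum_b <- sum(dm[!a, !a]) / 2
  between <- (sum(dm) / 2) - sum_a - sum_b
  n_within <- na * (na - 1) / 2 + nb * (nb - 1) / 2
  n_between <- na * nb
  within_mean <- (sum_a + sum_b) / n_within
  if (within_mean == 0) return(Inf)
  (between / n_between) / within_mean
}

#' Between/within separation statistic
#'
#' D = (mean dissimilarity over all between-class pairs) / (mean over all
#' within-class pairs). D near 1 means no separation; D above 1 means the
#' classes are farther apart than their internal spread. For
#' `metric = "bray_curtis"` the profiles are min-max rescaled per component
#' across both classes first.
#'
#' @param profiles Numeric matrix, profiles in rows.
#' @param labels Two-class label vector (>= 2 members per class).
#' @param metric Dissimilarity metric.
#' @export
separation_score <- function(profiles, labels,
                             metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly 2 label classes required")
  if (any(table(labels) < 2))
    stop("each class needs at least 2 members")
  m <- as.matrix(profiles)
  if (metric == "bray_curtis") m <- minmax_scale(m)
  dm <- dissimilarity_matrix(m, metric)
  D <- ratio_from_matrix(dm, labels)
  if (is.infinite(D)) warning("zero within-class dissimilarity; D is Inf")
  D
}

#' Permutation test of phenotypic separation
#'
#' Tests the observed between/within ratio D against the distribution under
#' uniformly permuted labels; add-one p-value
#' `(1 + #{permuted D >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams separation_score
#' @param n_perm Number of label permutations (>= 19).
#' @param seed RNG seed.
#' @return A `separation_result` list: `metric`, `D`, `p`, `n_perm`, `seed`,
#'   `group_sizes`, `perm_D` (the permuted statistics).
#' @export
permutation_test <- function(profiles, labels,
                             metric = c("bray_curtis", "euclidean"),
                             n_perm = 999, seed = 1) {
  metric <- match.arg(metric)
  if (n_perm < 19) stop("n_perm must be at least 19")
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly 2 label classes required")
  if (any(table(labels) < 2)) stop("each class needs at least 2 members")
  m <- as.matrix(profiles)
  if (metric == "bray_curtis") m <- minmax_scale(m)
  dm <- dissimilarity_matrix(m, metric)
  D <- ratio_from_matrix(dm, labels)
  perm_D <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    ratio_from_matrix(dm, sample(labels)), numeric(1)))
  p <- (1 + sum(perm_D >= D)) / (n_perm + 1)
  structure(list(metric = metric, D = D, p = p, n_perm = n_perm, seed = seed,
                 group_sizes = as.list(table(labels)), perm_D = perm_D),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("separation (%s): D = %.4f, permutation p = %.4g (%d permutations)\n",
              x$metric, x$D, x$p, x$n_perm))
  invisible(x)
}

#' Hierarchical-clustering view of component profiles
#'
#' Min-max scales each component to [0, 1], clusters profiles by Euclidean
#' distance with Ward linkage and returns the leaf order together with the
#' scaled matrix — the data behind the clustered-heatmap view of a screen.
#'
#' @param profiles Numeric matrix, profiles in rows.
#' @param linkage hclust agglomeration method (default `"ward.D2"`).
#' @return list with `order` (leaf order), `scaled` (min-max scaled matrix)
#'   and `hclust` (the tree).
#' @export
cluster_view <- function(profiles, linkage = "ward.D2") {
  m <- as.matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 profiles")
  sm <- minmax_scale(m)
  hc <- hclust(dist(sm), method = linkage)
  list(order = hc$order, scaled = sm, hclust = hc)
}
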