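# Two-sample t statistics from sufficient statistics (group sums and sums
# of squares). Both the scalar front door and the blockwise scan route
# through t_rows() so their floating-point arithmetic is identical.
t_rows <- function(Z, idx0, variant = "welch") {
  n0 <- sum(idx0)
  n1 <- sum(!idx0)
  Z0 <- Z[, idx0, drop = FALSE]
  Z1 <- Z[, !idx0, drop = FALSE]
  s0 <- rowSums(Z0); ss0 <- rowSums(Z0 * Z0)
  s1 <- rowSums(Z1); ss1 <- rowSums(Z1 * Z1)
  m0 <- s0 / n0
  m1 <- s1 / n1
  v0 <- pmax((ss0 - s0 * m0) / (n0 - 1), 0)
  v1 <- pmax((ss1 - s1 * m1) / (n1 - 1), 0)
  se2 <- if (variant == "welch") {
    v0 / n0 + v1 / n1
  } else {
    (((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)) * (1 / n0 + 1 / n1)
  }
  d <- m0 - m1
  t <- d / sqrt(se2)
  zero_se <- se2 <= 0
  if (any(zero_se)) {
    # degenerate: no within-class variance. Equal means -> 0; otherwise a
    # +/-Inf sentinel that sorts above every finite score.
    t[zero_se] <- ifelse(d[zero_se] == 0, 0, sign(d[zero_se]) * Inf)
  }
  t
}

#' Two-sample t-score of a feature against the class labels
#'
#' The score that ranks converted pair features and individual genes.
#' Sign convention: mean of class 0 minus mean of class 1, so a positive
#' score means the feature is higher in class 0. Ranking always uses the
#' absolute value. The default `"welch"` variant does not pool the class
#' variances; `"pooled"` gives the classical equal-variance Student t.
#'
#' If the feature is constant within both classes the statistic is 0 when
#' the class means agree and a signed infinity sentinel when they differ
#' (a perfectly separating feature, ranked above all finite scores).
#'
#' @param z Numeric vector, one value per sample.
#' @param labels Binary 0/1 vector, same length; both classes must have
#'   at least 2 samples.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A single numeric t statistic (possibly `Inf`/`-Inf`).
#' @examples
#' t_score(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
#' @export
t_score <- function(z, labels, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  labels <- as.integer(labels)
  if (length(z) != length(labels)) abort("`z` and `labels` lengths differ.")
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be binary 0/1.")
  if (sum(labels == 0L) < 2 || sum(labels == 1L) < 2) {
    abort("Both classes need at least 2 samples.")
  }
  unname(t_rows(matrix(z, nrow = 1), labels == 0L, variant))
}

new_screen_result <- function(df, method, top_n, gene_ids, t_variant,
                              n_scored) {
  structure(
    tibble::as_tibble(df),
    method = method,
    top_n = top_n,
    gene_ids = gene_ids,
    t_variant = t_variant,
    n_scored = n_scored,
    class = c("screen_result", class(tibble::tibble()))
  )
}

order_scores <- function(t, p, q) {
  # descending |t| (Inf first), ties broken by the lexicographically
  # smaller (p, q) pair so output is deterministic
  order(-abs(t), p, q)
}

#' Exhaustive pairwise scan under a conversion type
#'
#' Scores all m(m-1)/2 canonical gene pairs (p < q): each pair's rank rows
#' are collapsed by `conversion` into a feature Z and scored by
#' [t_score()] against the labels. Returns the `top_n` pairs by
#' descending |t|. The scan is blockwise — per reference gene, partner
#' genes are processed in chunks of `block_size` rows and scores are
#' formed from group sums and sums of squares — so memory stays
#' O(block_size x n) and no per-pair vector survives the scan.
#'
#' @param x A `rank_matrix` from [rank_transform()], or an `expr_dataset`
#'   (rank-transformed on the fly with average ties).
#' @param conversion One of `"sum"`, `"diff"`, `"mul"`, `"sign"`, `"abs"`.
#' @param top_n Number of pairs to keep. If it exceeds the number of
#'   pairs, all pairs are returned with a warning.
#' @param labels Optional 0/1 labels; defaults to the labels carried by
#'   `x`.
#' @param block_size Chunk width of the inner scan loop.
#' @param t_variant `"welch"` (default) or `"pooled"`; see [t_score()].
#' @return A `screen_result`: tibble with columns `rank`, `gene_p`,
#'   `gene_q`, `conversion`, `t_score`, ordered by descending |t|.
#' @examples
#' ds <- simulate_table4(k = 1, n = 50, seed = 1, n_noise = 4)
#' scan_pairs(ds, "abs", top_n = 3)
#' @export
scan_pairs <- function(x, conversion = "abs", top_n = 10, labels = NULL,
                       block_size = 512,
                       t_variant = c("welch", "pooled")) {
  t_variant <- match.arg(t_variant)
  if (inherits(x, "expr_dataset")) x <- rank_transform(x)
  stopifnot(inherits(x, "rank_matrix"))
  if (!conversion %in% conversion_types) {
    abort(sprintf("Unknown conversion type '%s'. Use one of: %s.",
                  conversion, paste(conversion_types, collapse = ", ")))
  }
  labels <- as.integer(labels %||% x$labels)
  R <- x$ranks
  m <- nrow(R)
  if (m < 2) abort("Need at least 2 genes to scan pairs.")
  n_pairs <- m * (m - 1) / 2
  top_n <- as.integer(top_n)
  if (top_n < 1) abort("`top_n` must be at least 1.")
  if (top_n > n_pairs) {
    warn(sprintf("top_n = %d exceeds the %d available pairs; returning all.",
                 top_n, n_pairs))
    top_n <- as.integer(n_pairs)
  }
  idx0 <- labels == 0L

  pool_t <- numeric(0); pool_p <- integer(0); pool_q <- integer(0)
  prune <- function() {
    o <- order_scores(pool_t, pool_p, pool_q)
    keep <- o[seq_len(min(top_n, length(o)))]
    pool_t <<- pool_t[keep]; pool_p <<- pool_p[keep]; pool_q <<- pool_q[keep]
  }
  pool_cap <- max(4L * top_n, 4096L)

  for (p in seq_len(m - 1)) {
    qs <- (p + 1):m
    for (start in seq(1, length(qs), by = block_size)) {
      chunk <- qs[start:min(start + block_size - 1, length(qs))]
      Z <- convert_rows(R[p, ], R[chunk, , drop = FALSE], conversion)
      t <- t_rows(Z, idx0, t_variant)
      pool_t <- c(pool_t, t)
      pool_p <- c(pool_p, rep.int(p, length(chunk)))
      pool_q <- c(pool_q, chunk)
      if (length(pool_t) > pool_cap) prune()
    }
  }
  prune()

  ids <- rownames(R)
  new_screen_result(
    tibble::tibble(
      rank = seq_along(pool_t),
      gene_p = ids[pool_p],
      gene_q = ids[pool_q],
      conversion = conversion,
      t_score = unname(pool_t)
    ),
    method = conversion, top_n = top_n, gene_ids = ids,
    t_variant = t_variant, n_scored = as.integer(n_pairs)
  )
}

#' Rank individual genes by t-score
#'
#' The marginal screen: each gene's raw expression values are scored by
#' [t_score()] against the labels and the `top_n` genes by |t| are
#' returned.
#'
#' @param data An `expr_dataset`.
#' @param top_n Number of genes to keep (capped at m with a warning).
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @return A `screen_result` with `gene_q = NA` and
#'   `conversion = "ind"`.
#' @export
rank_individual <- function(data, top_n = 10,
                            t_variant = c("welch", "pooled")) {
  t_variant <- match.arg(t_variant)
  stopifnot(inherits(data, "expr_dataset"))
  m <- nrow(data$values)
  top_n <- as.integer(top_n)
  if (top_n < 1) abort("`top_n` must be at least 1.")
  if (top_n > m) {
    warn(sprintf("top_n = %d exceeds the %d available genes; returning all.",
                 top_n, m))
    top_n <- m
  }
  t <- t_rows(data$values, data$labels == 0L, t_variant)
  o <- order_scores(t, seq_len(m), seq_len(m))[seq_len(top_n)]
  new_screen_result(
    tibble::tibble(
      rank = seq_len(top_n),
      gene_p = rownames(data$values)[o],
      gene_q = NA_character_,
      conversion = "ind",
      t_score = unname(t[o])
    ),
    method = "ind", top_n = top_n, gene_ids = rownames(data$values),
    t_variant = t_variant, n_scored = m
  )
}

#' Distinct genes in the top entries of a screen
#'
#' Collapses the top pairs (or genes) of a screen into the ordered list of
#' distinct gene ids, first appearance first — "removing repeated genes".
#' For a pair screen of N pairs the union holds at most 2N genes.
#'
#' @param result A `screen_result`.
#' @return Character vector of gene ids.
#' @export
gene_union <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  if (nrow(result) == 0) abort("Empty screen result.")
  g <- as.vector(t(cbind(result$gene_p, result$gene_q)))
  unique(g[!is.na(g)])
}

#' Overlap counts between gene unions of several screens
#'
#' For each pair of screen results, counts the genes shared by their
#' [gene_union()]s — the cross-method overlap table of informative genes.
#' Diagonal entries are the union sizes.
#'
#' @param results List of `screen_result` objects over the same gene
#'   universe (results whose universe was lost in serialization are
#'   accepted and skip the check).
#' @return Symmetric integer matrix with methods as dimnames.
#' @export
overlap_matrix <- function(results) {
  stopifnot(is.list(results), length(results) >= 2)
  universes <- lapply(results, attr, "gene_ids")
  known <- Filter(Negate(is.null), universes)
  if (length(known) >= 2) {
    ref <- known[[1]]
    for (u in known[-1]) {
      if (!setequal(ref, u)) abort("Screen results use different gene universes.")
    }
  }
  unions <- lapply(results, gene_union)
  nms <- names(results) %||% vapply(results, attr, "", "method")
  k <- length(unions)
  out <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- length(intersect(unions[[i]], unions[[j]]))
    }
  }
  out
}

#' @export
tidy.screen_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

unclass_result <- function(x) {
  attr(x, "method") <- NULL; attr(x, "top_n") <- NULL
  attr(x, "gene_ids") <- NULL; attr(x, "t_variant") <- NULL
  attr(x, "n_scored") <- NULL
  class(x) <- class(tibble::tibble())
  x
}

#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    top_n = attr(x, "top_n"),
    n_scored = attr(x, "n_scored"),
    n_genes_union = length(gene_union(x)),
    max_abs_t = max(abs(x$t_score)),
    t_variant = attr(x, "t_variant")
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> method = %s, top %d of %d scored (t: %s)\n",
              attr(x, "method"), attr(x, "top_n"), attr(x, "n_scored"),
              attr(x, "t_variant")))
  print(tidy(x), ...)
  invisible(x)
}
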