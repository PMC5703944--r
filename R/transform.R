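#' Rank-transform an expression dataset
#'
#' Replaces every gene's expression values by their within-gene sample
#' ranks (1 = smallest). Ranks are robust to background and quantization
#' differences between genes, and invariant under any strictly increasing
#' per-gene transformation. With the default `"average"` tie handling,
#' tied values receive the mean of the ranks they span, so each row still
#' sums to n(n+1)/2 exactly; `"competition"` assigns the minimum rank to
#' ties instead.
#'
#' @param data An [expression_dataset()].
#' @param ties `"average"` (default) or `"competition"`.
#' @return A `rank_matrix`: list with `ranks` (m x n matrix), `labels`,
#'   and `ties`.
#' @examples
#' ds <- simulate_table4(k = 1, n = 20, seed = 1)
#' rank_transform(ds)
#' @export
rank_transform <- function(data, ties = c("average", "competition")) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "expr_dataset"))
  method <- if (ties == "average") "average" else "min"
  ranks <- t(apply(data$values, 1, rank, ties.method = method))
  dimnames(ranks) <- dimnames(data$values)
  structure(
    list(ranks = ranks, labels = data$labels, ties = ties),
    class = "rank_matrix"
  )
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d genes x %d samples (ties: %s)\n",
              nrow(x$ranks), ncol(x$ranks), x$ties))
  invisible(x)
}

#' @export
dim.rank_matrix <- function(x) dim(x$ranks)

#' @export
tidy.rank_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$ranks), times = ncol(x$ranks)),
    sample_id = rep(colnames(x$ranks), each = nrow(x$ranks)),
    rank = as.vector(x$ranks),
    label = rep(unname(x$labels), each = nrow(x$ranks))
  )
}

conversion_types <- c("sum", "diff", "mul", "sign", "abs")

convert_rows <- function(rp, rq_mat, conversion) {
  switch(conversion,
    sum  = sweep(rq_mat, 2, rp, function(q, p) p + q),
    diff = sweep(rq_mat, 2, rp, function(q, p) p - q),
    mul  = sweep(rq_mat, 2, rp, function(q, p) p * q),
    sign = sweep(rq_mat, 2, rp, function(q, p) (p >= q) * 1),
    abs  = abs(sweep(rq_mat, 2, rp, function(q, p) p - q)),
    abort(sprintf("Unknown conversion type '%s'. Use one of: %s.",
                  conversion, paste(conversion_types, collapse = ", ")))
  )
}

#' Convert a gene pair into a single feature
#'
#' Collapses the rank rows of genes `p` and `q` into one vector Z, one
#' value per sample:
#' \describe{
#'   \item{sum}{`R_p + R_q`}
#'   \item{diff}{`R_p - R_q`}
#'   \item{mul}{`R_p * R_q`}
#'   \item{sign}{1 if `R_p >= R_q`, else 0 (ties count as 1)}
#'   \item{abs}{`|R_p - R_q|`, the synergy-oriented conversion}
#' }
#' `sum`, `mul` and `abs` are symmetric in (p, q); `diff` negates and
#' `sign` complements (on tie-free rows) when the pair is swapped.
#'
#' @param ranks A `rank_matrix` from [rank_transform()].
#' @param p,q Gene index or gene id; `p != q`.
#' @param conversion One of `"sum"`, `"diff"`, `"mul"`, `"sign"`, `"abs"`.
#' @return A `pair_feature`: list with `p`, `q` (ids), `conversion`, and
#'   the converted vector `z` (named by sample).
#' @export
convert_pair <- function(ranks, p, q, conversion) {
  stopifnot(inherits(ranks, "rank_matrix"))
  conversion <- as.character(conversion)
  if (!conversion %in% conversion_types) {
    abort(sprintf("Unknown conversion type '%s'. Use one of: %s.",
                  conversion, paste(conversion_types, collapse = ", ")))
  }
  pi <- resolve_gene(ranks, p)
  qi <- resolve_gene(ranks, q)
  if (pi == qi) abort("`p` and `q` must be different genes.")
  z <- drop(convert_rows(ranks$ranks[pi, ], ranks$ranks[qi, , drop = FALSE],
                         conversion))
  names(z) <- colnames(ranks$ranks)
  structure(
    list(p = rownames(ranks$ranks)[pi], q = rownames(ranks$ranks)[qi],
         conversion = conversion, z = z),
    class = "pair_feature"
  )
}

resolve_gene <- function(ranks, g) {
  if (is.character(g)) {
    i <- match(g, rownames(ranks$ranks))
    if (is.na(i)) abort(sprintf("Unknown gene id '%s'.", g))
    return(i)
  }
  g <- as.integer(g)
  if (g < 1 || g > nrow(ranks$ranks)) abort("Gene index out of range.")
  g
}

#' @export
print.pair_feature <- function(x, ...) {
  cat(sprintf("<pair_feature> %s(%s, %s), n = %d\n",
              x$conversion, x$p, x$q, length(x$z)))
  invisible(x)
}

#' @export
tidy.pair_feature <- function(x, ...) {
  tibble::tibble(sample_id = names(x$z), z = unname(x$z))
}

#' Converted feature matrix for a set of pairs
#'
#' Builds the n x k matrix whose columns are the converted features of the
#' given gene pairs — the input the classifier sees for a "Syn" feature
#' scheme.
#'
#' @param ranks A `rank_matrix`.
#' @param pairs A `screen_result` from [scan_pairs()], or a data frame
#'   with columns `gene_p` and `gene_q`.
#' @param conversion Conversion type; defaults to the one recorded in
#'   `pairs` (per row).
#' @return Numeric matrix, one row per sample, one column per pair,
#'   columns named `"p|q"`.
#' @export
pair_features <- function(ranks, pairs, conversion = NULL) {
  stopifnot(inherits(ranks, "rank_matrix"))
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) abort("`pairs` is empty.")
  conv <- conversion %||% pairs$conversion
  conv <- rep_len(as.character(conv), nrow(pairs))
  cols <- lapply(seq_len(nrow(pairs)), function(i) {
    convert_pair(ranks, pairs$gene_p[i], pairs$gene_q[i], conv[i])$z
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0(pairs$gene_p, "|", pairs$gene_q)
  out
}

#' Rescale matrix rows to [-1, 1]
#'
#' Heat-map preparation: each row is affinely rescaled so its minimum
#' maps to -1 and its maximum to +1; constant rows map to 0.
#'
#' @param x Numeric matrix (or anything coercible).
#' @return Matrix of the same shape with rows in \[-1, 1\].
#' @examples
#' heatmap_values(matrix(1:6, nrow = 2, byrow = TRUE))
#' @export
heatmap_values <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0) abort("`x` must be a nonempty matrix.")
  rmin <- apply(x, 1, min)
  rmax <- apply(x, 1, max)
  den <- rmax - rmin
  constant <- den == 0
  den[constant] <- 1
  out <- 2 * sweep(sweep(x, 1, rmin), 1, den, "/") - 1
  out[constant, ] <- 0
  out
}
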