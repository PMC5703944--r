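#' Equal-frequency discretization
#'
#' Cuts a continuous vector at its empirical quantiles into (up to)
#' `n_bins` bins. When the data have fewer distinct quantile breaks than
#' requested (heavily tied or discrete input), duplicate breaks are
#' collapsed and a warning reports the effective number of bins.
#'
#' @param x Numeric vector.
#' @param n_bins Requested number of bins (>= 2).
#' @return Factor of bin memberships.
#' @export
discretize_equal_freq <- function(x, n_bins = 4) {
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE))
  if (length(breaks) < 2) breaks <- c(breaks - 0.5, breaks + 0.5)
  if (length(breaks) - 1 < n_bins) {
    warn(sprintf("Only %d distinct bins possible (requested %d); bins collapsed.",
                 length(breaks) - 1, n_bins))
  }
  cut(x, breaks, include.lowest = TRUE)
}

# Plug-in (maximum-likelihood) mutual information in bits from two factors.
mi_bits <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
}

#' Interaction information of a gene pair with a binary phenotype
#'
#' Computes the plug-in estimate of
#' `I(X1; X2; Y) = I(X1, X2; Y) - I(X1; Y) - I(X2; Y)` in bits, after
#' equal-frequency discretization of `x1` and `x2`. Positive interaction
#' means the pair carries information about `y` beyond the sum of its
#' members (synergy); negative means the members are redundant. This is a
#' reference measure for small examples — the pairwise screen itself uses
#' [t_score()] on converted features, which needs no discretization.
#'
#' The estimator is plain maximum likelihood with no bias correction, so
#' at small n the interaction term inherits the usual positive bias of
#' plug-in mutual information.
#'
#' @param x1,x2 Numeric vectors (discretized internally). Already-discrete
#'   input is fine; bins then collapse to the distinct values (with a
#'   warning if fewer than `n_bins`).
#' @param y Binary phenotype vector (two distinct values).
#' @param n_bins Bins per variable for the discretization (default 4).
#' @return A `synergy_score`: list with `i_x1_y`, `i_x2_y`, `i_joint_y`,
#'   `interaction` (all in bits) and `bins`.
#' @examples
#' set.seed(1)
#' x1 <- rbinom(1000, 1, 0.5); x2 <- rbinom(1000, 1, 0.5)
#' interaction_information(x1, x2, xor(x1, x2), n_bins = 2)
#' @export
interaction_information <- function(x1, x2, y, n_bins = 4) {
  if (length(x1) != length(x2) || length(x1) != length(y)) {
    abort("`x1`, `x2` and `y` must have equal lengths.")
  }
  yl <- unique(y)
  if (length(yl) != 2) abort("`y` must be binary (exactly two distinct values).")
  d1 <- discretize_equal_freq(x1, n_bins)
  d2 <- discretize_equal_freq(x2, n_bins)
  yf <- factor(y)
  i1 <- mi_bits(d1, yf)
  i2 <- mi_bits(d2, yf)
  ij <- mi_bits(interaction(d1, d2, drop = TRUE), yf)
  structure(
    list(
      i_x1_y = i1, i_x2_y = i2, i_joint_y = ij,
      interaction = ij - i1 - i2,
      bins = list(requested = n_bins,
                  effective_x1 = nlevels(droplevels(d1)),
                  effective_x2 = nlevels(droplevels(d2)))
    ),
    class = "synergy_score"
  )
}

#' @export
print.synergy_score <- function(x, ...) {
  cat(sprintf(
    "<synergy_score> I(X1;Y) = %.4f, I(X2;Y) = %.4f, I(X1,X2;Y) = %.4f bits\n",
    x$i_x1_y, x$i_x2_y, x$i_joint_y))
  verdict <- if (x$interaction > 0) "synergy" else
    if (x$interaction < 0) "redundancy" else "additive"
  cat(sprintf("  interaction I(X1;X2;Y) = %+.4f bits (%s)\n",
              x$interaction, verdict))
  invisible(x)
}

#' @export
tidy.synergy_score <- function(x, ...) {
  tibble::tibble(
    term = c("I(X1;Y)", "I(X2;Y)", "I(X1,X2;Y)", "I(X1;X2;Y)"),
    bits = c(x$i_x1_y, x$i_x2_y, x$i_joint_y, x$interaction)
  )
}

#' @export
glance.synergy_score <- function(x, ...) {
  tibble::tibble(
    i_x1_y = x$i_x1_y, i_x2_y = x$i_x2_y, i_joint_y = x$i_joint_y,
    interaction = x$interaction,
    n_bins = x$bins$requested
  )
}
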