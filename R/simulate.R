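#' Simulate an additive absolute-difference architecture
#'
#' Generates the pure abs-pair family of simulation datasets: 2k causal
#' columns are drawn i.i.d. uniform on (0, 1), the continuous phenotype is
#' `y = |X1 - X2| + |X3 - X4| + ... + |X(2k-1) - X(2k)|`, and the binary
#' label is the median split of y (strictly above the midpoint median is
#' class 1), giving an exact 50/50 split for even n. Optional extra
#' uniform columns unrelated to y act as noise genes. Every marginal
#' column is uniform, so no single causal gene separates the classes —
#' the signal is purely synergic and is what the `abs` conversion is
#' built to detect.
#'
#' @param k Number of abs-pairs (1..10 covers the standard ladder).
#' @param n Number of samples; must be even so the median split balances.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param n_noise Number of extra noise columns (default 0).
#' @return A `sim_dataset` (also an `expr_dataset`): `values` is the
#'   (2k + n_noise) x n genes-by-samples matrix, plus `y_continuous`
#'   (length n), `z_true` (n x k matrix of the true converted features),
#'   `gene_roles` (tibble: gene_id, role, pair), `k`, and `seed`.
#' @examples
#' ds <- simulate_table4(k = 2, n = 100, seed = 7, n_noise = 5)
#' table(ds$labels)
#' @export
simulate_table4 <- function(k, n = 200, seed, n_noise = 0) {
  k <- as.integer(k)
  if (k < 1) abort("`k` must be at least 1.")
  simulate_abs_model(n_ind = 0, n_syn_pairs = k, n_noise = n_noise,
                     n = n, seed = seed)
}

#' Simulate a mixed individual + synergic architecture
#'
#' Generalizes [simulate_table4()] with marginal (individually
#' discriminant) genes: the continuous phenotype is
#' `y = X1 + ... + X(n_ind) + |Xa - Xb| + ...` over `n_syn_pairs`
#' abs-pairs, followed by the same median binarization. With
#' `n_ind = 2, n_syn_pairs = 2` this is the canonical
#' `Y = X1 + X2 + |X3 - X4| + |X5 - X6|` architecture whose optimal
#' feature subset mixes both kinds of signal.
#'
#' @param n_ind Number of additive individual genes.
#' @param n_syn_pairs Number of abs-pairs.
#' @param n_noise Number of noise genes unrelated to y.
#' @param n Number of samples (even).
#' @param seed Integer seed.
#' @return A `sim_dataset`; see [simulate_table4()]. `gene_roles$role`
#'   is one of `"individual"`, `"pair_member"`, `"noise"`.
#' @export
simulate_mixed <- function(n_ind, n_syn_pairs, n_noise = 0, n = 200, seed) {
  simulate_abs_model(n_ind = n_ind, n_syn_pairs = n_syn_pairs,
                     n_noise = n_noise, n = n, seed = seed)
}

simulate_abs_model <- function(n_ind, n_syn_pairs, n_noise, n, seed) {
  n <- as.integer(n)
  if (n %% 2 != 0) abort("`n` must be even so the median split balances classes.")
  if (n < 20) abort("`n` must be at least 20.")
  n_ind <- as.integer(n_ind); n_syn_pairs <- as.integer(n_syn_pairs)
  n_noise <- as.integer(n_noise)
  if (n_ind + n_syn_pairs < 1) abort("Need at least one causal term.")
  seed <- as.integer(seed)

  m_causal <- n_ind + 2L * n_syn_pairs
  withr::local_seed(seed)
  x <- matrix(runif(n * m_causal), nrow = n, ncol = m_causal)
  noise <- if (n_noise > 0) {
    matrix(runif(n * n_noise), nrow = n, ncol = n_noise)
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }

  ind_cols <- seq_len(n_ind)
  z_true <- matrix(numeric(0), nrow = n, ncol = 0)
  if (n_syn_pairs > 0) {
    z_true <- vapply(seq_len(n_syn_pairs), function(j) {
      a <- n_ind + 2 * j - 1
      abs(x[, a] - x[, a + 1])
    }, numeric(n))
    z_true <- matrix(z_true, nrow = n)
    colnames(z_true) <- paste0("Z", seq_len(n_syn_pairs))
  }
  y <- (if (n_ind > 0) rowSums(x[, ind_cols, drop = FALSE]) else 0) +
    (if (n_syn_pairs > 0) rowSums(z_true) else 0)
  labels <- as.integer(y > median(y))

  gene_names <- c(paste0("X", seq_len(m_causal)),
                  if (n_noise > 0) paste0("N", seq_len(n_noise)))
  values <- t(cbind(x, noise))
  rownames(values) <- gene_names
  colnames(values) <- paste0("S", seq_len(n))

  roles <- tibble::tibble(
    gene_id = gene_names,
    role = c(rep("individual", n_ind),
             rep("pair_member", 2 * n_syn_pairs),
             rep("noise", n_noise)),
    pair = c(rep(NA_integer_, n_ind),
             rep(seq_len(n_syn_pairs), each = 2),
             rep(NA_integer_, n_noise))
  )

  ds <- expression_dataset(values, labels)
  ds$y_continuous <- setNames(y, colnames(values))
  ds$z_true <- z_true
  ds$gene_roles <- roles
  ds$k <- n_syn_pairs
  ds$n_ind <- n_ind
  ds$seed <- seed
  class(ds) <- c("sim_dataset", class(ds))
  ds
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d individual + %d abs-pair + %d noise genes, n = %d (seed %d)\n",
    x$n_ind, x$k, sum(x$gene_roles$role == "noise"), ncol(x$values), x$seed
  ))
  NextMethod()
}

#' True converted-feature matrix of a simulated dataset
#'
#' The n x k matrix of true pair features |Xa - Xb| — the "converted"
#' input-feature scheme of the simulation study.
#'
#' @param data A `sim_dataset`.
#' @return Numeric matrix (n x k).
#' @export
true_pair_features <- function(data) {
  stopifnot(inherits(data, "sim_dataset"))
  data$z_true
}

#' Raw causal-column matrix of a simulated dataset
#'
#' The n x (n_ind + 2k) matrix of the causal X columns — the
#' "not converted" input-feature scheme of the simulation study.
#'
#' @param data A `sim_dataset`.
#' @return Numeric matrix.
#' @export
causal_features <- function(data) {
  stopifnot(inherits(data, "sim_dataset"))
  causal <- data$gene_roles$gene_id[data$gene_roles$role != "noise"]
  t(data$values[causal, , drop = FALSE])
}
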