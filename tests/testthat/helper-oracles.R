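# Independent oracles and fixture builders shared across the suite.

# Textbook Welch t from group means and variances (independent of the
# sufficient-statistics route used by the package).
oracle_welch <- function(z, labels) {
  z0 <- z[labels == 0]
  z1 <- z[labels == 1]
  (mean(z0) - mean(z1)) / sqrt(var(z0) / length(z0) + var(z1) / length(z1))
}

oracle_pooled <- function(z, labels) {
  z0 <- z[labels == 0]
  z1 <- z[labels == 1]
  n0 <- length(z0); n1 <- length(z1)
  sp2 <- ((n0 - 1) * var(z0) + (n1 - 1) * var(z1)) / (n0 + n1 - 2)
  (mean(z0) - mean(z1)) / sqrt(sp2 * (1 / n0 + 1 / n1))
}

# Ranks by double argsort (tie-free input only).
oracle_rank <- function(x) {
  r <- integer(length(x))
  r[order(x)] <- seq_along(x)
  r
}

# Scalar-loop conversion of two rank rows.
oracle_convert <- function(rp, rq, conversion) {
  vapply(seq_along(rp), function(i) {
    switch(conversion,
      sum = rp[i] + rq[i],
      diff = rp[i] - rq[i],
      mul = rp[i] * rq[i],
      sign = if (rp[i] >= rq[i]) 1 else 0,
      abs = abs(rp[i] - rq[i])
    )
  }, numeric(1))
}

# Double-loop brute-force pair scan: every canonical pair converted and
# scored with t_score(), ordered by |t| then (p, q).
oracle_scan <- function(ranks_obj, conversion, top_n,
                        t_variant = "welch") {
  R <- ranks_obj$ranks
  labels <- ranks_obj$labels
  m <- nrow(R)
  rows <- list()
  for (p in seq_len(m - 1)) {
    for (q in (p + 1):m) {
      z <- oracle_convert(R[p, ], R[q, ], conversion)
      rows[[length(rows) + 1]] <- data.frame(
        p = p, q = q, t = t_score(z, labels, t_variant)
      )
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(-abs(df$t), df$p, df$q), ]
  head(df, top_n)
}

# Plug-in MI in bits by direct summation over a contingency table.
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        total <- total + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  total
}

# Small random expression dataset with balanced labels.
make_expr <- function(m = 10, n = 20, seed = 1) {
  withr::with_seed(seed, {
    values <- matrix(rnorm(m * n), nrow = m,
                     dimnames = list(paste0("g", seq_len(m)),
                                     paste0("s", seq_len(n))))
    expression_dataset(values,
                       labels = c(rep(0, floor(n / 2)), rep(1, ceiling(n / 2))))
  })
}

# Write a small genes-in-rows expression TSV and return its path.
write_expr_fixture <- function(path = tempfile(fileext = ".tsv"),
                               labels = c(0, 0, 0, 1, 1, 1),
                               gene_ids = c("gA", "gB", "gC"),
                               seed = 42) {
  values <- withr::with_seed(seed, {
    matrix(round(runif(length(gene_ids) * length(labels), 1, 10), 3),
           nrow = length(gene_ids))
  })
  samples <- paste0("s", seq_along(labels))
  lines <- c(
    paste(c("id", samples), collapse = "\t"),
    paste(c("class", labels), collapse = "\t"),
    vapply(seq_along(gene_ids), function(i) {
      paste(c(gene_ids[i], values[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}
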