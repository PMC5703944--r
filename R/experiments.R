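#' Converted vs unconverted simulation study
#'
#' For each number of abs-pairs `k`, draws one simulated dataset per seed
#' (see [simulate_table4()]; n samples, no noise genes) and cross-validates
#' every classifier on two input-feature schemes: `converted` — the k true
#' pair features Z; `not_converted` — the 2k raw causal columns X. Both
#' schemes share fold assignments within a seed, so the comparison is
#' paired. The study demonstrates that classifiers fed the raw pair
#' members degrade as k grows, while converted features stay accurate.
#'
#' @param ks Integer vector of pair counts to simulate (default 1:10).
#' @param n Samples per dataset (default 200).
#' @param seeds Integer vector of simulation seeds (default 1:20); each
#'   seed draws a fresh dataset and fold assignment.
#' @param classifiers Character vector of classifier names
#'   (default [classifiers()]).
#' @param n_folds CV folds (default 5).
#' @param scale Feature scaling passed to [run_cv()].
#' @return A `sim_study_result` tibble in long format: columns `k`,
#'   `classifier`, `scheme`, `seed`, `fold`, `accuracy` (percent).
#'   Summarize with [pivot_accuracy()] or dplyr.
#' @examples
#' \donttest{
#' res <- run_table5_experiment(ks = 1, seeds = 1:2,
#'                              classifiers = "svm_linear")
#' pivot_accuracy(res)
#' }
#' @export
run_table5_experiment <- function(ks = 1:10, n = 200, seeds = 1:20,
                                  classifiers = synpair::classifiers(),
                                  n_folds = 5,
                                  scale = c("standard", "minmax", "none")) {
  scale <- match.arg(scale)
  rows <- purrr::map(ks, function(k) {
    purrr::map(seeds, function(s) {
      ds <- simulate_table4(k = k, n = n, seed = s)
      feats <- list(converted = true_pair_features(ds),
                    not_converted = causal_features(ds))
      purrr::map(classifiers, function(clf) {
        purrr::imap(feats, function(f, scheme) {
          cv <- run_cv(f, ds$labels, clf, n_folds = n_folds,
                       seed = s + 10000L, scale = scale)
          tibble::tibble(
            k = k, classifier = clf, scheme = scheme, seed = s,
            fold = seq_len(n_folds), accuracy = cv$fold_accuracies
          )
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            n = n, seeds = seeds, scale = scale,
            class = c("sim_study_result", class(out)))
}

#' Pivot a long accuracy table into a per-condition summary
#'
#' Averages accuracy over folds and seeds and spreads
#' classifier-by-scheme combinations into columns, one row per `k` —
#' the compact view of [run_table5_experiment()] output.
#'
#' @param results Long tibble with columns `k`, `classifier`, `scheme`,
#'   `accuracy`.
#' @return Wide tibble, one row per `k`, accuracy in percent.
#' @export
pivot_accuracy <- function(results) {
  results |>
    dplyr::group_by(.data$k, .data$classifier, .data$scheme) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = c("classifier", "scheme"),
                       values_from = "accuracy") |>
    dplyr::arrange(.data$k)
}

#' Compare individual, synergic, and combined feature schemes
#'
#' Screens a dataset for its top individually discriminant genes and its
#' top converted pairs under each requested conversion type, then
#' cross-validates the schemes `Ind` (raw expression of the top genes),
#' `Syn` per conversion (converted Z features — pair members are never
#' fed raw), and `Ind+Syn` per conversion.
#'
#' By default (`nested = FALSE`) screening uses all samples, and
#' cross-validation only re-fits the classifier — the fast, conventional
#' protocol for this screen, whose accuracies are therefore optimistic
#' for feature selection. `nested = TRUE` repeats ranking, scanning, and
#' rank transformation inside every training fold; test-sample ranks are
#' then interpolated into the training ranking.
#'
#' @param data An `expr_dataset`.
#' @param top_ind Number of individual genes (0 to skip the Ind schemes).
#' @param top_syn Number of pairs per conversion (0 degenerates every
#'   scheme to Ind-only).
#' @param conversions Conversion types to screen (default `"abs"`).
#' @param classifier Classifier name (default `"svm_rbf"`).
#' @param seed Integer seed for fold assignment.
#' @param n_folds CV folds (default 5).
#' @param nested Recompute screening inside training folds (default
#'   FALSE).
#' @param scale Feature scaling passed to the classifier harness.
#' @return A `scheme_comparison` tibble: `scheme`, `conversion`,
#'   `classifier`, `n_features`, `fold`, `accuracy` (percent), with the
#'   screening mode in attribute `mode`.
#' @export
run_scheme_comparison <- function(data, top_ind = 20, top_syn = 10,
                                  conversions = "abs",
                                  classifier = "svm_rbf", seed = 1L,
                                  n_folds = 5, nested = FALSE,
                                  scale = c("standard", "minmax", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(data, "expr_dataset"))
  schemes <- build_scheme_specs(top_ind, top_syn, conversions)
  rows <- if (nested) {
    run_schemes_nested(data, schemes, classifier, seed, n_folds, scale)
  } else {
    run_schemes_flat(data, schemes, classifier, seed, n_folds, scale)
  }
  structure(dplyr::bind_rows(rows),
            mode = if (nested) "nested" else "screen_all",
            seed = as.integer(seed),
            class = c("scheme_comparison", class(tibble::tibble())))
}

build_scheme_specs <- function(top_ind, top_syn, conversions) {
  specs <- list()
  if (top_ind > 0) {
    specs[[sprintf("Top%d_Ind", top_ind)]] <-
      list(ind = top_ind, syn = 0, conversion = NA_character_)
  }
  if (top_syn > 0) {
    for (cv in conversions) {
      specs[[sprintf("Top%d_Syn_%s", top_syn, cv)]] <-
        list(ind = 0, syn = top_syn, conversion = cv)
      if (top_ind > 0) {
        specs[[sprintf("Top%d_Ind+Top%d_Syn_%s", top_ind, top_syn, cv)]] <-
          list(ind = top_ind, syn = top_syn, conversion = cv)
      }
    }
  }
  if (length(specs) == 0) abort("Nothing to compare: top_ind and top_syn are both 0.")
  specs
}

scheme_features <- function(spec, data, ranks, ind_result, syn_results) {
  parts <- list()
  if (spec$ind > 0) {
    genes <- ind_result$gene_p[seq_len(min(spec$ind, nrow(ind_result)))]
    parts$ind <- t(data$values[genes, , drop = FALSE])
  }
  if (spec$syn > 0) {
    res <- syn_results[[spec$conversion]]
    pairs <- res[seq_len(min(spec$syn, nrow(res))), ]
    parts$syn <- pair_features(ranks, pairs)
  }
  do.call(cbind, parts)
}

screen_all <- function(data, schemes, classifier) {
  top_ind <- max(c(0, vapply(schemes, `[[`, 0, "ind")))
  top_syn <- max(c(0, vapply(schemes, `[[`, 0, "syn")))
  convs <- unique(stats::na.omit(vapply(schemes, `[[`, "", "conversion")))
  ranks <- rank_transform(data)
  ind_result <- if (top_ind > 0) rank_individual(data, top_ind) else NULL
  syn_results <- setNames(
    lapply(convs, function(cv) scan_pairs(ranks, cv, top_n = top_syn)),
    convs
  )
  list(ranks = ranks, ind = ind_result, syn = syn_results)
}

run_schemes_flat <- function(data, schemes, classifier, seed, n_folds, scale) {
  sc <- screen_all(data, schemes, classifier)
  purrr::imap(schemes, function(spec, name) {
    feats <- scheme_features(spec, data, sc$ranks, sc$ind, sc$syn)
    cv <- run_cv(feats, data$labels, classifier, n_folds = n_folds,
                 seed = seed, scale = scale)
    tibble::tibble(
      scheme = name, conversion = spec$conversion, classifier = classifier,
      n_features = ncol(feats), fold = seq_len(n_folds),
      accuracy = cv$fold_accuracies
    )
  })
}

run_schemes_nested <- function(data, schemes, classifier, seed, n_folds,
                               scale) {
  labels <- data$labels
  withr::local_seed(as.integer(seed))
  folds <- stratified_folds(labels, n_folds)
  fold_rows <- lapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    d_tr <- subset_samples(data, tr)
    sc <- screen_all(d_tr, schemes, classifier)
    purrr::imap(schemes, function(spec, name) {
      train_feats <- scheme_features(spec, d_tr, sc$ranks, sc$ind, sc$syn)
      test_feats <- scheme_test_features(spec, data, tr, sc)
      sf <- scale_features(train_feats, test_feats, scale)
      train <- as.data.frame(sf$train)
      train$.y <- factor(labels[tr], levels = c(0, 1))
      pred <- fit_predict(classifier, train, as.data.frame(sf$test))
      truth <- labels[!tr]
      tibble::tibble(
        scheme = name, conversion = spec$conversion,
        classifier = classifier, n_features = ncol(train_feats), fold = f,
        accuracy = accuracy(
          tp = sum(pred == "1" & truth == 1L),
          tn = sum(pred == "0" & truth == 0L),
          fp = sum(pred == "1" & truth == 0L),
          fn = sum(pred == "0" & truth == 1L)
        )
      )
    })
  })
  purrr::flatten(fold_rows)
}

# Features of the held-out samples under a training-fold screen: raw
# expression for Ind genes; for pairs, each test value is ranked by
# insertion into the training values of its gene, then converted.
scheme_test_features <- function(spec, data, tr, sc) {
  parts <- list()
  te_values <- data$values[, !tr, drop = FALSE]
  if (spec$ind > 0) {
    genes <- sc$ind$gene_p[seq_len(min(spec$ind, nrow(sc$ind)))]
    parts$ind <- t(te_values[genes, , drop = FALSE])
  }
  if (spec$syn > 0) {
    res <- sc$syn[[spec$conversion]]
    pairs <- res[seq_len(min(spec$syn, nrow(res))), ]
    tr_values <- data$values[, tr, drop = FALSE]
    te_ranks <- rank_newdata(tr_values, te_values)
    cols <- lapply(seq_len(nrow(pairs)), function(i) {
      rp <- te_ranks[pairs$gene_p[i], ]
      rq <- te_ranks[pairs$gene_q[i], ]
      drop(convert_rows(rp, matrix(rq, nrow = 1), pairs$conversion[i]))
    })
    z <- do.call(cbind, cols)
    colnames(z) <- paste0(pairs$gene_p, "|", pairs$gene_q)
    parts$syn <- z
  }
  do.call(cbind, parts)
}

# Insertion rank of new values among a gene's training values:
# (# train < v) + (# train == v)/2 + 1, the average rank v would get if
# appended to the training sample.
rank_newdata <- function(train_values, new_values) {
  out <- matrix(0, nrow(new_values), ncol(new_values),
                dimnames = dimnames(new_values))
  for (j in seq_len(nrow(train_values))) {
    srt <- sort(train_values[j, ])
    v <- new_values[j, ]
    n_lt <- findInterval(v, srt, left.open = TRUE)
    n_le <- findInterval(v, srt)
    out[j, ] <- n_lt + (n_le - n_lt) / 2 + 1
  }
  out
}
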