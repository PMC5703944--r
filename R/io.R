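#' Read an expression matrix with class labels from delimited text
#'
#' Expects one header row and, by default, genes in rows: the first column
#' holds gene ids and one designated row (whose id equals `label_id`)
#' holds the class label of every sample. With
#' `orientation = "samples_in_rows"` the file is transposed: the first
#' column holds sample ids and the label sits in the column named
#' `label_id`.
#'
#' The label field must contain exactly two distinct raw values. Raw
#' values `"0"`/`"1"` are taken as-is; otherwise the lexicographically
#' smaller raw value maps to 0 and the mapping is reported via a message
#' and recorded in the returned object's `label_map`. Pass `label_map`
#' explicitly to override (e.g. `c("normal", "tumor")` maps `"normal"` to
#' 0 and `"tumor"` to 1).
#'
#' @param path Path to a delimited text file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param label_id Identifier of the label row/column. Default `"class"`.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the
#'   file extension (`.csv` comma, anything else tab).
#' @param label_map Optional character vector of length 2 giving the raw
#'   label values that map to 0 and 1, in that order.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            label_id = "class",
                            delim = NULL,
                            label_map = NULL) {
  orientation <- match.arg(orientation)
  delim <- delim %||% delim_for(path)
  raw <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) abort("Expected at least an id column and one data column.")
  ids <- as.character(raw[[1]])

  if (orientation == "genes_in_rows") {
    is_label <- ids == label_id
    if (sum(is_label) != 1) {
      abort(sprintf("Expected exactly one row with id '%s' carrying the labels.",
                    label_id))
    }
    raw_labels <- as.character(unlist(raw[is_label, -1], use.names = FALSE))
    body <- raw[!is_label, , drop = FALSE]
    values <- suppressWarnings(
      matrix(as.numeric(as.matrix(body[, -1, drop = FALSE])),
             nrow = nrow(body),
             dimnames = list(body[[1]], colnames(raw)[-1]))
    )
  } else {
    if (!label_id %in% colnames(raw)) {
      abort(sprintf("Expected a column named '%s' carrying the labels.", label_id))
    }
    raw_labels <- as.character(raw[[label_id]])
    keep <- setdiff(colnames(raw)[-1], label_id)
    values <- suppressWarnings(
      matrix(as.numeric(as.matrix(raw[, keep, drop = FALSE])),
             nrow = nrow(raw), dimnames = list(ids, keep))
    )
    values <- t(values)
  }

  map <- resolve_label_map(raw_labels, label_map)
  labels <- unname(map[raw_labels])
  expression_dataset(values, labels, label_map = map)
}

delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

resolve_label_map <- function(raw_labels, label_map = NULL) {
  lev <- sort(unique(raw_labels))
  if (length(lev) != 2) {
    abort(sprintf(
      "Label field must contain exactly two distinct values, found %d: %s",
      length(lev), paste(lev, collapse = ", ")
    ))
  }
  if (!is.null(label_map)) {
    if (length(label_map) != 2 || !setequal(label_map, lev)) {
      abort("`label_map` must list the two raw label values (order: 0 then 1).")
    }
    map <- setNames(c(0L, 1L), as.character(label_map))
  } else if (setequal(lev, c("0", "1"))) {
    map <- c(`0` = 0L, `1` = 1L)
  } else {
    map <- setNames(c(0L, 1L), lev)
    inform(sprintf("Label mapping: '%s' -> 0, '%s' -> 1", lev[1], lev[2]))
  }
  map
}

#' Write an expression dataset to delimited text
#'
#' Genes in rows, one header row of sample ids, and a first row with id
#' `"class"` holding the 0/1 labels — the same layout [read_expression()]
#' reads back by default.
#'
#' @param data An `expr_dataset`.
#' @param path Output path; the extension picks the delimiter
#'   (`.csv` comma, otherwise tab).
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, delim = NULL) {
  delim <- delim %||% delim_for(path)
  out <- rbind(class = data$labels, data$values)
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a screen result to delimited text
#'
#' Emits comment lines (`#`) recording the method and its parameters,
#' followed by a table with columns `rank`, `gene_p`, `gene_q` (empty for
#' individual-gene screens), `conversion` and `t_score`. Scores are
#' serialized with 6 significant digits.
#'
#' @param result A `screen_result` from [scan_pairs()] or
#'   [rank_individual()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  if (nrow(result) == 0) abort("Refusing to write an empty screen result.")
  meta <- attributes(result)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# synpair screen result",
    sprintf("# method: %s", meta$method),
    sprintf("# top_n: %d", meta$top_n),
    sprintf("# t_variant: %s", meta$t_variant),
    sprintf("# n_genes: %d", length(meta$gene_ids)),
    sprintf("# n_scored: %d", meta$n_scored)
  ), con)
  out <- data.frame(
    rank = result$rank,
    gene_p = result$gene_p,
    gene_q = ifelse(is.na(result$gene_q), "", result$gene_q),
    conversion = result$conversion,
    t_score = formatC(result$t_score, digits = 6, format = "g")
  )
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a screen result written by [write_screen_result()]
#'
#' The gene universe is not serialized, so the returned object carries
#' `gene_ids = NULL`; [overlap_matrix()] then skips its universe check.
#'
#' @param path Path to a file produced by [write_screen_result()].
#' @return A `screen_result` tibble.
#' @export
read_screen_result <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    hit <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", hit[1]))
  }
  body <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                     stringsAsFactors = FALSE)
  gene_q <- as.character(body$gene_q)
  gene_q[gene_q == "" | is.na(gene_q)] <- NA_character_
  new_screen_result(
    tibble::tibble(
      rank = as.integer(body$rank),
      gene_p = as.character(body$gene_p),
      gene_q = gene_q,
      conversion = as.character(body$conversion),
      t_score = as.numeric(body$t_score)
    ),
    method = field("method"),
    top_n = as.integer(field("top_n")),
    gene_ids = NULL,
    t_variant = field("t_variant"),
    n_scored = as.integer(field("n_scored"))
  )
}
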