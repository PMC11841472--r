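# File formats: delimited response matrices with letter or integer category
# labels, two-column answer keys, tidy CSV outputs and a JSON run summary.

default_labels <- function(C) LETTERS[seq_len(C)]

#' Read a nominal response matrix
#'
#' Reads a delimited text file with a header row of item identifiers and
#' one row per respondent; cells are category labels (letters `A`..`E` by
#' default, or integers) or a missing marker (empty cell or `NA`).  The
#' category label set must be consistent across the file.  With
#' `complete_only = TRUE` (the default, mirroring the usual restriction to
#' respondents answering every question) incomplete respondents are dropped
#' and the exclusion count is reported via a message.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (`","` default; use `"\t"` for TSV).
#' @param C Number of categories; inferred from the observed labels when
#'   `NULL`.
#' @param labels Category labels in index order; default letters, or
#'   integers when the file is numeric.
#' @param key Optional answer-key vector or path (see [read_answer_key()]).
#' @param complete_only Drop respondents with any missing response.
#' @return List with `R` (integer matrix), `design` ([mncm_design()]),
#'   `labels`, `items` (column names), `n_excluded`.
#' @export
read_responses <- function(path, sep = ",", C = NULL, labels = NULL,
                           key = NULL, complete_only = TRUE) {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), strip.white = TRUE)
  items <- colnames(raw)
  M <- as.matrix(raw)
  obs <- sort(unique(stats::na.omit(as.vector(M))))
  numeric_labels <- all(grepl("^[0-9]+$", obs))
  if (is.null(labels)) {
    if (numeric_labels) {
      if (is.null(C)) C <- max(as.integer(obs))
      labels <- as.character(seq_len(C))
    } else {
      if (is.null(C)) C <- match(max(obs), LETTERS)
      labels <- default_labels(C)
    }
  } else if (is.null(C)) C <- length(labels)
  unknown <- setdiff(obs, labels)
  if (length(unknown)) {
    loc <- which(matrix(M %in% unknown, nrow(M)), arr.ind = TRUE)[1, ]
    stop(sprintf("unknown category label '%s' at row %d, column '%s'",
                 M[loc[1], loc[2]], loc[1], items[loc[2]]))
  }
  R <- matrix(match(M, labels), nrow(M), ncol(M))
  n_excluded <- 0L
  if (complete_only) {
    keep <- stats::complete.cases(R)
    n_excluded <- sum(!keep)
    if (n_excluded > 0L)
      message(sprintf("excluded %d respondent(s) with incomplete responses", n_excluded))
    R <- R[keep, , drop = FALSE]
  }
  correct <- NULL
  if (!is.null(key)) {
    if (is.character(key) && length(key) == 1L && file.exists(key))
      key <- read_answer_key(key, items = items, labels = labels)
    correct <- as.integer(key)
  }
  design <- mncm_design(ncol(R), C, correct)
  storage.mode(R) <- "integer"
  list(R = R, design = design, labels = labels, items = items,
       n_excluded = n_excluded)
}

#' Read an answer key
#'
#' Two-column CSV (item identifier, correct category label), returned as an
#' integer vector of correct category indices in item order.
#'
#' @param path Path to the CSV.
#' @param items Item identifiers in response-matrix order; defaults to the
#'   key file's own order.
#' @param labels Category labels in index order (letters by default).
#' @return Integer vector of correct categories.
#' @export
read_answer_key <- function(path, items = NULL, labels = NULL) {
  k <- utils::read.csv(path, header = TRUE, colClasses = "character",
                       strip.white = TRUE)
  if (ncol(k) < 2) stop("answer key must have two columns: item, correct label")
  if (is.null(labels)) {
    obs <- sort(unique(k[[2]]))
    labels <- if (all(grepl("^[0-9]+$", obs)))
      as.character(seq_len(max(as.integer(obs)))) else
      default_labels(match(max(obs), LETTERS))
  }
  idx <- match(k[[2]], labels)
  if (anyNA(idx)) stop("answer key contains an unknown category label")
  if (!is.null(items)) {
    ord <- match(items, k[[1]])
    if (anyNA(ord)) stop("answer key is missing one or more items")
    idx <- idx[ord]
  }
  as.integer(idx)
}

#' Write a response matrix
#'
#' Writes responses as delimited text with category labels, the inverse of
#' [read_responses()].
#'
#' @param R Integer response matrix.
#' @param path Output path.
#' @param labels Category labels (letters by default).
#' @param items Item identifiers (default `Q1..QI`).
#' @param sep Field separator.
#' @export
write_responses <- function(R, path, labels = NULL, items = NULL, sep = ",") {
  C <- max(R, na.rm = TRUE)
  if (is.null(labels)) labels <- default_labels(C)
  if (is.null(items)) items <- paste0("Q", seq_len(ncol(R)))
  M <- matrix(labels[R], nrow(R), ncol(R))
  M[is.na(R)] <- ""
  colnames(M) <- items
  utils::write.table(M, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(x) signif(x, 6)

#' Write an identified fit to disk
#'
#' Writes tidy CSVs (slopes as item/category/dimension/value rows,
#' intercepts, abilities) at six significant digits, plus a JSON summary
#' carrying `D_hat`, the diagonal slope covariance, the intercept variance,
#' scale EAPs, the full configuration and seeds, and the package version —
#' everything needed to reproduce the run.
#'
#' @param fit An `mncm_fit`.
#' @param outdir Output directory (created if needed).
#' @param rotation Optional `mncm_rotation`; its rotated slopes/abilities
#'   are written alongside.
#' @param config Optional list recorded verbatim in the summary.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, outdir, rotation = NULL, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- fit$design
  paths <- character()
  slope_tbl <- function(A) {
    if (nrow(A) == 0L)
      return(data.frame(item = integer(), category = integer(),
                        dimension = integer(), value = numeric()))
    data.frame(item = rep(rep(seq_len(design$I), each = design$C), each = nrow(A)),
               category = rep(rep(seq_len(design$C), design$I), each = nrow(A)),
               dimension = rep(seq_len(nrow(A)), design$I * design$C),
               value = fmt6(as.vector(A)))
  }
  p <- file.path(outdir, "slopes.csv")
  utils::write.csv(slope_tbl(fit$A), p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(outdir, "intercepts.csv")
  utils::write.csv(data.frame(item = rep(seq_len(design$I), each = design$C),
                              category = rep(seq_len(design$C), design$I),
                              value = fmt6(fit$b)), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "abilities.csv")
  ab <- as.data.frame(fmt6(fit$Theta))
  if (ncol(ab)) colnames(ab) <- paste0("dim", seq_len(ncol(ab)))
  utils::write.csv(cbind(respondent = seq_len(nrow(fit$Theta)), ab), p,
                   row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(rotation)) {
    p <- file.path(outdir, "slopes_rotated.csv")
    utils::write.csv(slope_tbl(rotation$rotated_slopes), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summary <- list(
    D_hat = fit$D_hat,
    cov_A_diagonal = diag(fit$cov_A),
    var_b = fit$var_b,
    alpha = fit$alpha, beta = fit$beta,
    constraint_mode = fit$constraint_mode,
    prune_threshold = fit$prune_threshold,
    slope_norms = fit$slope_norms,
    rotation_method = if (!is.null(rotation)) rotation$method else NULL,
    config = config,
    package_version = as.character(utils::packageVersion("mncmbayes")),
    r_version = R.version.string)
  p <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Rank the most heavily weighted distractors per dimension
#'
#' For each sparse (non-general) dimension of a rotated, sign-determined
#' fit, lists the `top_k` categories by absolute slope with their signed
#' values — the table one inspects to decide whether a dimension encodes a
#' coherent misconception.  Under simple constraints correct categories have
#' exactly zero slope and so never appear.
#'
#' @param fit An `mncm_fit` (for the design and answer key).
#' @param rotation An `mncm_rotation` whose `rotated_slopes` to rank; when
#'   `NULL` the fit's own slopes are used.
#' @param item_texts Optional character vector of item descriptions.
#' @param top_k Entries per dimension (default 6); capped at `IC`.
#' @param include_general Also report dimension 1 (default FALSE).
#' @return Tibble: `dimension`, `rank`, `item`, `category`, `label`,
#'   `slope`, optional `text`.
#' @export
report_distractor_vectors <- function(fit, rotation = NULL, item_texts = NULL,
                                      top_k = 6L, include_general = FALSE) {
  design <- fit$design
  A <- if (!is.null(rotation)) rotation$rotated_slopes else fit$A
  D <- nrow(A); IC <- design$I * design$C
  top_k <- min(as.integer(top_k), IC)
  dims <- if (include_general) seq_len(D) else setdiff(seq_len(D), 1L)
  if (D == 1L) dims <- 1L
  rows <- lapply(dims, function(d) {
    ord <- order(abs(A[d, ]), decreasing = TRUE)[seq_len(top_k)]
    item <- (ord - 1L) %/% design$C + 1L
    cat <- (ord - 1L) %% design$C + 1L
    tibble::tibble(dimension = d, rank = seq_len(top_k), item = item,
                   category = cat, label = default_labels(design$C)[cat],
                   slope = A[d, ord],
                   text = if (!is.null(item_texts)) item_texts[item] else NA_character_)
  })
  out <- do.call(rbind, rows)
  if (is.null(item_texts)) out$text <- NULL
  out
}

#' Dot-grid plot of slope vectors
#'
#' Displays one or more slope dimensions as item-by-category grids of dots
#' whose size and intensity scale with the coefficient magnitude (relative
#' to the largest coefficient in the panel), colored by sign (red negative,
#' blue positive), with correct answer choices marked `+` when the design
#' has a key.  Requires ggplot2.
#'
#' @param fit An `mncm_fit` (for the design and key).
#' @param rotation Optional `mncm_rotation` whose rotated slopes to plot.
#' @param dimensions Which dimensions to show (default: all).
#' @return A ggplot object, faceted by dimension.
#' @export
plot_distractor_grid <- function(fit, rotation = NULL, dimensions = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  design <- fit$design
  A <- if (!is.null(rotation)) rotation$rotated_slopes else fit$A
  if (is.null(dimensions)) dimensions <- seq_len(nrow(A))
  df <- do.call(rbind, lapply(dimensions, function(d) data.frame(
    dimension = d,
    item = rep(seq_len(design$I), each = design$C),
    category = rep(seq_len(design$C), design$I),
    value = A[d, ],
    rel = abs(A[d, ]) / max(abs(A[d, ]), 1e-12))))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = item, y = category)) +
    ggplot2::geom_point(ggplot2::aes(size = rel, alpha = rel,
                                     color = value < 0)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "#2166ac",
                                           `TRUE` = "#b2182b"),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::scale_alpha(range = c(0.15, 1), guide = "none") +
    ggplot2::scale_y_continuous(breaks = seq_len(design$C),
                                labels = default_labels(design$C)) +
    ggplot2::facet_wrap(~dimension, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::theme_minimal()
  if (!is.null(design$correct))
    g <- g + ggplot2::geom_point(
      data = data.frame(item = seq_len(design$I), category = design$correct),
      shape = 3, size = 2)
  g
}
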