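#' Build a fragment-frequency index
#'
#' Counts, for every signature, the number of distinct molecules (UUIDs) in
#' which it occurs at least once — a document frequency, not a term
#' frequency: a molecule containing a signature several times still
#' contributes 1.
#'
#' @param sigs a tibble with columns `uuid` and `signature`, e.g. from
#'   [sign_batch()] or [read_signatures()].
#' @return an object of class `npl_index` with fields `counts` (named
#'   integer vector, signature -> molecule count) and `total_molecules`.
#' @export
build_index <- function(sigs) {
  if (!is.data.frame(sigs) || !all(c("uuid", "signature") %in% names(sigs)))
    abort("expected a tibble with columns uuid and signature",
          class = "npl_training_error")
  if (!nrow(sigs))
    abort("cannot train on an empty signature corpus",
          class = "npl_training_error")
  df <- dplyr::distinct(sigs, .data$uuid, .data$signature) |>
    dplyr::count(.data$signature)
  counts <- stats::setNames(as.integer(df$n), df$signature)
  structure(
    list(counts = counts,
         total_molecules = dplyr::n_distinct(sigs$uuid)),
    class = "npl_index"
  )
}

#' @export
print.npl_index <- function(x, ...) {
  cat(sprintf("<npl_index> %d signatures over %d molecules\n",
              length(x$counts), x$total_molecules))
  invisible(x)
}

#' Train an NP-likeness scorer
#'
#' Pairs a natural-product index with a synthetic-molecule index. A query
#' fragment's score is the log-ratio of its relative document frequencies,
#'
#' \deqn{f_i = \ln\frac{(NP_i+\alpha)}{(SM_i+\alpha)} \cdot \frac{SM_t}{NP_t}}
#'
#' where \eqn{NP_i, SM_i} are the numbers of corpus molecules containing the
#' fragment, \eqn{NP_t, SM_t} the corpus sizes, and \eqn{\alpha} a
#' pseudo-count (default 1) that keeps fragments seen in only one corpus
#' finite; with \eqn{\alpha = 0} the literal frequency ratio is used and a
#' fragment absent from either corpus is an error.
#'
#' @param np natural-product corpus: an `npl_index` or a signature tibble.
#' @param sm synthetic-molecule corpus: an `npl_index` or a signature tibble.
#' @param height signature height the corpora were generated at (default 2).
#' @param alpha pseudo-count added to both per-fragment counts (>= 0).
#' @return an object of class `npl_model`.
#' @export
scorer_model <- function(np, sm, height = 2L, alpha = 1) {
  as_index <- function(x) if (inherits(x, "npl_index")) x else build_index(x)
  stopifnot(alpha >= 0)
  structure(
    list(np_index = as_index(np), sm_index = as_index(sm),
         height = as.integer(height), alpha = as.numeric(alpha)),
    class = "npl_model"
  )
}

#' @export
print.npl_model <- function(x, ...) {
  cat(sprintf(
    "<npl_model> height %d, alpha %g\n  NP corpus: %d molecules, %d signatures\n  SM corpus: %d molecules, %d signatures\n",
    x$height, x$alpha,
    x$np_index$total_molecules, length(x$np_index$counts),
    x$sm_index$total_molecules, length(x$sm_index$counts)
  ))
  invisible(x)
}

.lookup_counts <- function(index, signatures) {
  i <- match(signatures, names(index$counts))
  out <- index$counts[i]
  out[is.na(i)] <- 0L
  as.numeric(out)
}

#' Per-fragment scores
#'
#' @param signatures character vector of signature texts.
#' @param model an `npl_model`.
#' @return a tibble with columns `signature`, `np_count`, `sm_count`,
#'   `value` (the natural-log frequency ratio).
#' @export
fragment_score <- function(signatures, model) {
  stopifnot(inherits(model, "npl_model"))
  np_i <- .lookup_counts(model$np_index, signatures)
  sm_i <- .lookup_counts(model$sm_index, signatures)
  a <- model$alpha
  if (a == 0 && any(np_i == 0 | sm_i == 0)) {
    abort(paste(
      "fragment score undefined with alpha = 0 for a signature absent from",
      "one of the corpora; use a positive pseudo-count"
    ), class = "npl_undefined_score")
  }
  # grouped so that swapping the two corpora negates every term exactly in
  # floating point (IEEE subtraction is sign-symmetric)
  value <- (log(np_i + a) - log(sm_i + a)) -
    (log(model$np_index$total_molecules) - log(model$sm_index$total_molecules))
  tibble(signature = signatures, np_count = as.integer(np_i),
         sm_count = as.integer(sm_i), value = value)
}

#' Score query molecules for NP-likeness
#'
#' Each query molecule (grouped by UUID across fragments) gets the sum of
#' its per-atom fragment scores, duplicates counted every time, normalised
#' by its number of atom signatures N — which equals the heavy-atom count —
#' so large molecules do not dominate. Higher scores mean more
#' natural-product-like.
#'
#' @param query a tibble with columns `uuid` and `signature` (query-side
#'   duplicates are scored per occurrence).
#' @param model an `npl_model`.
#' @return a tibble of class `npl_scores` with columns `uuid`, `raw_sum`,
#'   `n_atoms` and `np_likeness`, in first-appearance order of UUIDs.
#' @export
score_molecules <- function(query, model) {
  stopifnot(inherits(model, "npl_model"))
  if (!is.data.frame(query) || !all(c("uuid", "signature") %in% names(query)))
    abort("expected a tibble with columns uuid and signature")
  if (!nrow(query)) abort("empty query", class = "npl_empty_input")
  vocab <- unique(query$signature)
  fs <- fragment_score(vocab, model)
  per_atom <- fs$value[match(query$signature, fs$signature)]
  out <- tibble(uuid = query$uuid, value = per_atom) |>
    dplyr::group_by(uuid = factor(.data$uuid, levels = unique(.data$uuid))) |>
    dplyr::summarise(raw_sum = sum(.data$value), n_atoms = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(uuid = as.character(.data$uuid),
                  np_likeness = .data$raw_sum / .data$n_atoms)
  class(out) <- c("npl_scores", class(out))
  out
}

#' Tidy a scorer model: the full fragment-score table
#'
#' @param x an `npl_model`.
#' @param ... unused.
#' @return a tibble with one row per signature in either corpus.
#' @export
tidy.npl_model <- function(x, ...) {
  vocab <- sort(unique(c(names(x$np_index$counts), names(x$sm_index$counts))),
                method = "radix")
  fragment_score(vocab, x)
}

#' Summarise a scorer model
#'
#' @param x an `npl_model`.
#' @param ... unused.
#' @return a one-row tibble: corpus sizes, vocabulary sizes, height, alpha.
#' @export
glance.npl_model <- function(x, ...) {
  tibble(
    np_molecules = x$np_index$total_molecules,
    sm_molecules = x$sm_index$total_molecules,
    np_signatures = length(x$np_index$counts),
    sm_signatures = length(x$sm_index$counts),
    shared_signatures = length(intersect(names(x$np_index$counts),
                                         names(x$sm_index$counts))),
    height = x$height,
    alpha = x$alpha
  )
}

#' Most natural-product-like (or synthetic-like) fragments
#'
#' @param model an `npl_model`.
#' @param k number of fragments to return.
#' @param direction `"np_like"` (largest scores first) or
#'   `"synthetic_like"` (smallest first). Ties break lexicographically on
#'   the signature text.
#' @param decode also rebuild each fragment's structure from its signature
#'   (adds a `mol` list-column via [decode_signature()])?
#' @return a tibble with columns `signature`, `np_count`, `sm_count`,
#'   `value`, and optionally `mol`.
#' @export
top_fragments <- function(model, k = 10L,
                          direction = c("np_like", "synthetic_like"),
                          decode = FALSE) {
  direction <- match.arg(direction)
  all_fs <- tidy(model)
  ord <- order(if (direction == "np_like") -all_fs$value else all_fs$value,
               all_fs$signature, method = "radix")
  out <- all_fs[ord[seq_len(min(k, nrow(all_fs)))], ]
  if (decode) out$mol <- purrr::map(out$signature, decode_signature)
  out
}

# ---- model persistence ----------------------------------------------------

.npl_model_format <- "nplikeness-model\t1"

#' Save or load a trained scorer
#'
#' The model file is a self-describing, versioned plain-text container:
#' header lines with the format version, height, pseudo-count and corpus
#' sizes, followed by the two tab-separated count tables.
#'
#' @param model an `npl_model`.
#' @param path file path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the restored
#'   `npl_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "npl_model"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(sprintf("cannot write %s", path),
                                            class = "npl_output_error"))
  on.exit(close(con))
  dump_index <- function(tag, idx) {
    c(sprintf("[%s]\t%d\t%d", tag, idx$total_molecules, length(idx$counts)),
      paste(names(idx$counts), idx$counts, sep = "\t"))
  }
  writeLines(c(
    .npl_model_format,
    sprintf("height\t%d", model$height),
    sprintf("alpha\t%.17g", model$alpha),
    dump_index("NP", model$np_index),
    dump_index("SM", model$sm_index)
  ), con)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    abort(sprintf("model file not found: %s", path), class = "npl_input_error")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !identical(lines[1L], .npl_model_format))
    abort(sprintf(
      "unrecognised model file version (expected '%s', got '%s')",
      .npl_model_format, if (length(lines)) lines[1L] else ""
    ), class = "npl_model_version_error")
  height <- as.integer(strsplit(lines[2L], "\t")[[1L]][2L])
  alpha <- as.numeric(strsplit(lines[3L], "\t")[[1L]][2L])
  parse_index <- function(at) {
    hdr <- strsplit(lines[at], "\t")[[1L]]
    total <- as.integer(hdr[2L])
    nsig <- as.integer(hdr[3L])
    body <- lines[at + seq_len(nsig)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    counts <- stats::setNames(
      as.integer(vapply(parts, `[[`, character(1), 2L)),
      vapply(parts, `[[`, character(1), 1L)
    )
    list(index = structure(list(counts = counts, total_molecules = total),
                           class = "npl_index"),
         next_at = at + nsig + 1L)
  }
  np <- parse_index(4L)
  sm <- parse_index(np$next_at)
  scorer_model(np$index, sm$index, height = height, alpha = alpha)
}
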