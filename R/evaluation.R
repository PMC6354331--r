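#' Expert label set for a query disease
#'
#' @param query_id The query disease (must not itself be labelled).
#' @param labels data.frame with columns `disease_id` and `label`, label in
#'   `{"related", "non_related", "undefined"}`.
#' @return Object of class `expert_labels`.
#' @export
expert_labels <- function(query_id, labels) {
  stopifnot(is.data.frame(labels),
            all(c("disease_id", "label") %in% names(labels)))
  bad <- setdiff(unique(labels$label),
                 c("related", "non_related", "undefined"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (query_id %in% labels$disease_id) {
    stop("query disease must not be labelled: ", query_id)
  }
  if (anyDuplicated(labels$disease_id)) {
    stop("duplicated disease labels")
  }
  labels <- labels[order(labels$disease_id), c("disease_id", "label")]
  rownames(labels) <- NULL
  structure(list(query_id = query_id, labels = labels),
            class = "expert_labels")
}

#' @export
print.expert_labels <- function(x, ...) {
  cat("expert_labels for query", x$query_id, "-")
  print(table(x$labels$label))
  invisible(x)
}

label_set <- function(labels, which) {
  labels$labels$disease_id[labels$labels$label == which]
}

#' Aggregate five expert votes per disease into labels
#'
#' A disease is `related` if 4 or 5 of the 5 experts voted related,
#' `non_related` if 3 or more voted non-related, and `undefined` otherwise.
#'
#' @param votes Named list mapping disease id to a character vector of
#'   exactly 5 votes from `{"related", "non_related"}`, or a data.frame with
#'   a `disease_id` column plus 5 vote columns.
#' @param query_id Query disease id recorded on the result.
#' @return An `expert_labels` object.
#' @export
aggregate_expert_votes <- function(votes, query_id) {
  if (is.data.frame(votes)) {
    stopifnot("disease_id" %in% names(votes))
    ids <- as.character(votes$disease_id)
    vcols <- setdiff(names(votes), "disease_id")
    votes <- lapply(seq_along(ids),
                    function(i) as.character(unlist(votes[i, vcols])))
    names(votes) <- ids
  }
  stopifnot(is.list(votes), !is.null(names(votes)))
  lab <- vapply(names(votes), function(d) {
    v <- votes[[d]]
    if (length(v) != 5L) {
      stop("disease ", d, ": expected exactly 5 votes, got ", length(v))
    }
    if (!all(v %in% c("related", "non_related"))) {
      stop("disease ", d, ": votes must be 'related' or 'non_related'")
    }
    n_rel <- sum(v == "related")
    if (n_rel >= 4L) "related"
    else if (5L - n_rel >= 3L) "non_related"
    else "undefined"
  }, character(1))
  expert_labels(query_id,
                data.frame(disease_id = names(votes), label = unname(lab)))
}

#' Harmonic-mean F score from precision and recall
#'
#' `F = 2PR / (P + R)`; 0 when both are 0. Accepts either fractions in
#' \[0, 1\] or percentages (values > 1), returning on the same scale.
#'
#' @param precision,recall Numeric scalars or vectors.
#' @return F score(s).
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Score a predicted related set against expert labels
#'
#' Diseases labelled `undefined` are excluded from the confusion counts
#' (they are the prediction target, not ground truth). Predictions for
#' diseases absent from the labels are ignored.
#'
#' @param predicted_related Character vector of disease ids called related.
#' @param labels An `expert_labels` object.
#' @return Object of class `evaluation_report`: list with `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f_score`, `n_labelled`.
#' @export
score <- function(predicted_related, labels) {
  stopifnot(inherits(labels, "expert_labels"))
  rel <- label_set(labels, "related")
  nonrel <- label_set(labels, "non_related")
  pred <- unique(as.character(predicted_related))
  tp <- sum(rel %in% pred)
  fn <- length(rel) - tp
  fp <- sum(nonrel %in% pred)
  tn <- length(nonrel) - fp
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions among labelled diseases; precision = 0")
    0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no related labels; recall = 0")
    0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall,
                 f_score = f1_score(precision, recall),
                 n_labelled = length(rel) + length(nonrel)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: P = %.3f, R = %.3f, F = %.3f (tp %d, fp %d, fn %d, tn %d)\n",
    x$precision, x$recall, x$f_score, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Grid search over pipeline hyperparameters on the labelled split
#'
#' Runs the pipeline at every combination of the supplied ranges and keeps
#' the configuration maximising F on the related/non-related labels. Ties are
#' broken toward simpler models: smaller selected rank, then smaller `k`.
#'
#' @param corpus An `annotation_corpus`.
#' @param labels An `expert_labels` for the query disease.
#' @param grid Named list of vectors over any of `energy_target`,
#'   `energy_mode`, `r`, `k`, `min_genes` (defaults supplied for the rest).
#'   An `r` axis searches explicit ranks instead of the energy rule; the
#'   value `NA` inside it falls back to the energy rule.
#' @param seed Seed applied to every candidate run.
#' @param ... Further fixed arguments passed to [pipeline_config()].
#' @return List with `best_config` (a `pipeline_config`), `report` (its
#'   `evaluation_report`), and `leaderboard` (a data.frame of all candidates
#'   sorted best-first).
#' @export
tune <- function(corpus, labels, grid = list(), seed = 1L, ...) {
  stopifnot(inherits(corpus, "annotation_corpus"),
            inherits(labels, "expert_labels"))
  if (length(label_set(labels, "related")) == 0L ||
      length(label_set(labels, "non_related")) == 0L) {
    stop("labels must contain at least one related and one non_related disease")
  }
  defaults <- list(energy_target = 0.95, energy_mode = "sum",
                   r = NA_integer_, k = 2L, min_genes = 1L)
  for (nm in names(grid)) {
    if (!nm %in% names(defaults)) stop("unknown grid dimension: ", nm)
  }
  axes <- utils::modifyList(defaults, grid[lengths(grid) > 0])
  combos <- expand.grid(axes, stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) stop("empty tuning grid")

  rows <- vector("list", nrow(combos))
  configs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- pipeline_config(min_genes = combos$min_genes[i],
                           energy_target = combos$energy_target[i],
                           energy_mode = combos$energy_mode[i],
                           r = if (is.na(combos$r[i])) NULL else
                             as.integer(combos$r[i]),
                           k = combos$k[i], seed = seed, ...)
    res <- tryCatch(run_pipeline(corpus, labels$query_id, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- cbind(combos[i, , drop = FALSE],
                         data.frame(rank_used = NA_integer_,
                                    precision = NA_real_, recall = NA_real_,
                                    f_score = NA_real_))
      next
    }
    rep <- suppressWarnings(score(res$related, labels))
    configs[[i]] <- cfg
    rows[[i]] <- cbind(combos[i, , drop = FALSE],
                       data.frame(rank_used = res$parameters$rank_used,
                                  precision = rep$precision,
                                  recall = rep$recall,
                                  f_score = rep$f_score))
  }
  board <- do.call(rbind, rows)
  rownames(board) <- NULL
  ok <- which(!is.na(board$f_score))
  if (length(ok) == 0L) stop("every candidate configuration failed")
  ord <- ok[order(-board$f_score[ok], board$rank_used[ok], board$k[ok])]
  best_i <- ord[1L]
  best_cfg <- configs[[best_i]]
  best_res <- run_pipeline(corpus, labels$query_id, best_cfg)
  list(best_config = best_cfg,
       report = suppressWarnings(score(best_res$related, labels)),
       leaderboard = board[c(ord, setdiff(seq_len(nrow(board)), ok)), ,
                           drop = FALSE])
}

#' Predict the relationship of undefined-labelled diseases to the query
#'
#' Runs the pipeline at the tuned configuration and returns the
#' undefined-labelled diseases that fall in the query's cluster. Undefined
#' diseases dropped by the min-gene filter cannot be called and are reported
#' via a message.
#'
#' @param corpus An `annotation_corpus`.
#' @param labels An `expert_labels`.
#' @param best_config A `pipeline_config`, typically from [tune()].
#' @return Sorted character vector of disease ids.
#' @export
predict_undefined <- function(corpus, labels, best_config) {
  stopifnot(inherits(labels, "expert_labels"),
            inherits(best_config, "pipeline_config"))
  undef <- label_set(labels, "undefined")
  if (length(undef) == 0L) return(character(0))
  res <- run_pipeline(corpus, labels$query_id, best_config)
  dropped <- setdiff(undef, res$assignment$ids)
  if (length(dropped)) {
    message("undefined disease(s) removed by filtering, not callable: ",
            paste(dropped, collapse = ", "))
  }
  sort(intersect(undef, res$related))
}

#' Read an expert label table
#'
#' 2-column TSV (`disease_id`, `label`), no header.
#'
#' @param path TSV path.
#' @param query_id Query disease id.
#' @return An `expert_labels` object.
#' @export
read_labels <- function(path, query_id) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) != 2L) stop("labels file must have 2 columns")
  names(df) <- c("disease_id", "label")
  expert_labels(query_id, df)
}

#' Write an expert label table readable by [read_labels()]
#' @param labels An `expert_labels` object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "expert_labels"))
  utils::write.table(labels$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, ~0 means chance-level agreement.
#'
#' @param a,b Vectors of cluster labels (any comparable type), same length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_ij - expected) / (max_index - expected)
}
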