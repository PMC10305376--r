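#' Eligibility screening of unique publications
#'
#' Screening decisions are attached to *clusters* (unique publications), not
#' to individual database copies: eligibility is a property of the
#' publication. A labels table has one row per cluster with a binary
#' decision (`eligible` / `ineligible`) and a free-text reason, required for
#' exclusions (e.g. "not randomized", "conference abstract", "not
#' English"). Labels may reference either the `cluster_id` or any member
#' `record_id` (typically the canonical id, which is stable for human
#' labelers); both are resolved internally.
#'
#' @name screening
NULL

#' Read a screening labels CSV
#'
#' Expects columns `cluster_id` (or `id`), `decision`, `reason`.
#'
#' @param path CSV path.
#' @return A `data.frame` with columns `cluster_id`, `decision`, `reason`.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        encoding = "UTF-8")
  if ("id" %in% names(df) && !"cluster_id" %in% names(df))
    names(df)[names(df) == "id"] <- "cluster_id"
  need <- setdiff(c("cluster_id", "decision"), names(df))
  if (length(need))
    stop(sprintf("labels CSV %s: missing columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!"reason" %in% names(df)) df$reason <- NA_character_
  df[, c("cluster_id", "decision", "reason")]
}

#' Write a screening labels CSV
#' @param labels Labels `data.frame` (`cluster_id`, `decision`, `reason`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels[, c("cluster_id", "decision", "reason")], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

resolve_label_ids <- function(clusters, ids) {
  # ids may be cluster ids or member record ids
  hit <- match(ids, clusters$cluster_id)
  need <- which(is.na(hit))
  if (length(need)) {
    member_map <- rep(seq_len(nrow(clusters)), clusters$size)
    names(member_map) <- unlist(clusters$member_ids)
    hit[need] <- unname(member_map[ids[need]])
  }
  hit
}

#' Attach screening labels to a deduplicated corpus
#'
#' Validates that every cluster carries exactly one label, then builds the
#' per-database coverage map: database *d* covers cluster *c* iff any member
#' of *c* was retrieved from *d*. The result is the central object all
#' diagnostics operate on.
#'
#' @param corpus A `ref_corpus`.
#' @param clusters A `dedup_clusters` partition of `corpus`.
#' @param labels A labels `data.frame` with columns `cluster_id` (cluster id
#'   or member record id), `decision` in `{eligible, ineligible}`, `reason`.
#' @return An object of class `labeled_corpus`: list with the corpus,
#'   clusters, resolved labels, logical coverage matrix (clusters x
#'   databases), logical `eligible` vector, database labels, per-database
#'   pooled yields and the pooled corpus size.
#' @export
apply_labels <- function(corpus, clusters, labels) {
  stopifnot(inherits(clusters, "dedup_clusters"))
  if (attr(clusters, "corpus_size") != nrow(corpus))
    stop("clusters do not partition this corpus (size mismatch)", call. = FALSE)
  labels <- as.data.frame(labels)
  if (!all(c("cluster_id", "decision") %in% names(labels)))
    stop("labels need columns cluster_id and decision", call. = FALSE)
  if (!"reason" %in% names(labels)) labels$reason <- NA_character_

  bad_dec <- !labels$decision %in% c("eligible", "ineligible")
  if (any(bad_dec))
    stop(sprintf("invalid decisions (must be eligible/ineligible) for: %s",
                 paste(labels$cluster_id[bad_dec], collapse = ", ")),
         call. = FALSE)
  no_reason <- labels$decision == "ineligible" &
    (is.na(labels$reason) | !nzchar(trimws(labels$reason)))
  if (any(no_reason))
    stop(sprintf("ineligible labels must carry a reason: %s",
                 paste(labels$cluster_id[no_reason], collapse = ", ")),
         call. = FALSE)

  idx <- resolve_label_ids(clusters, labels$cluster_id)
  unknown <- is.na(idx)
  if (any(unknown))
    stop(sprintf("labels reference unknown clusters/records: %s",
                 paste(labels$cluster_id[unknown], collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(idx)) {
    dup <- clusters$cluster_id[idx[duplicated(idx)]]
    stop(sprintf("multiple labels for cluster(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  unlabeled <- setdiff(seq_len(nrow(clusters)), idx)
  if (length(unlabeled))
    stop(sprintf("missing labels for cluster(s): %s",
                 paste(clusters$cluster_id[unlabeled], collapse = ", ")),
         call. = FALSE)

  decision <- character(nrow(clusters))
  decision[idx] <- labels$decision
  reason <- rep(NA_character_, nrow(clusters))
  reason[idx] <- labels$reason

  dbs <- corpus_databases(corpus)
  rec_db <- corpus$source_db[match(unlist(clusters$member_ids), corpus$record_id)]
  cl_of_rec <- rep(seq_len(nrow(clusters)), clusters$size)
  coverage <- matrix(FALSE, nrow(clusters), length(dbs),
                     dimnames = list(clusters$cluster_id, dbs))
  coverage[cbind(cl_of_rec, match(rec_db, dbs))] <- TRUE

  structure(list(corpus = corpus, clusters = clusters,
                 labels = data.frame(cluster_id = clusters$cluster_id,
                                     decision = decision, reason = reason,
                                     stringsAsFactors = FALSE),
                 coverage = coverage,
                 eligible = decision == "eligible",
                 databases = dbs, yields = db_yields(corpus),
                 pooled = nrow(corpus)),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("Labeled corpus: %d pooled records, %d unique publications, %d eligible, %d databases\n",
              x$pooled, nrow(x$clusters), sum(x$eligible), length(x$databases)))
  invisible(x)
}

#' PRISMA-style flow ledger
#'
#' Record counts through the pipeline: pooled records, duplicate copies
#' removed, ineligible unique publications, eligible unique publications.
#' The conservation identity `pooled = duplicates + ineligible + eligible`
#' holds for every input and is asserted.
#'
#' @param x A `labeled_corpus`, or a `ref_corpus` when `clusters` and
#'   `labels` are supplied.
#' @param clusters,labels Passed to [apply_labels()] when `x` is a corpus.
#' @return A list (class `flow_ledger`) with elements `pooled`,
#'   `duplicates`, `ineligible`, `eligible`.
#' @export
flow_ledger <- function(x, clusters = NULL, labels = NULL) {
  lab <- if (inherits(x, "labeled_corpus")) x else apply_labels(x, clusters, labels)
  pooled <- lab$pooled
  uniq <- nrow(lab$clusters)
  eligible <- sum(lab$eligible)
  out <- list(pooled = pooled, duplicates = pooled - uniq,
              ineligible = uniq - eligible, eligible = eligible)
  stopifnot(out$pooled == out$duplicates + out$ineligible + out$eligible)
  structure(out, class = "flow_ledger")
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat(sprintf("records pooled:        %5d\n", x$pooled))
  cat(sprintf("duplicates removed:    %5d\n", x$duplicates))
  cat(sprintf("ineligible (unique):   %5d\n", x$ineligible))
  cat(sprintf("eligible (unique):     %5d\n", x$eligible))
  invisible(x)
}
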