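#' Duplicate detection across database exports
#'
#' The same publication retrieved from several databases (or twice from one)
#' must be collapsed to a single unique record before screening. Records are
#' linked pairwise when (a) they share a non-missing DOI, (b) they share an
#' exact dedup key (normalized title, year, first-author family name), or
#' (c) their normalized titles have edit-distance similarity at or above
#' `fuzzy_threshold` and their years agree. Clusters are the transitive
#' closure of these links; records with conflicting DOIs are never linked by
#' the fuzzy rule (a DOI mismatch is treated as stronger evidence than a
#' similar title). Records lacking both title and DOI would stay singletons,
#' but such records are rejected at corpus validation.
#'
#' @name dedup
NULL

#' Normalize a title for duplicate matching
#'
#' Lower-cases, folds diacritics to ASCII, removes every character that is
#' not a letter, digit or space, collapses whitespace runs and trims. The
#' transform is idempotent, so normalized keys can be re-normalized safely.
#'
#' @param title Character vector of titles (`NA` treated as empty).
#' @return Character vector of normalized titles.
#' @examples
#' normalize_title("Half-dose  Photodynamic Therapy!")
#' @export
normalize_title <- function(title) {
  x <- as.character(title)
  x[is.na(x)] <- ""
  x <- tolower(x)
  conv <- iconv(x, to = "ASCII//TRANSLIT")
  x <- ifelse(is.na(conv), x, conv)
  x <- gsub("[^a-z0-9 ]", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' First author's family name
#'
#' Takes the first entry of a `"; "`-joined author string; the family name
#' is the pre-comma part when a comma is present (`"Smith, J."`), otherwise
#' the last whitespace-separated token (`"J. Smith"`).
#'
#' @param authors Character vector of author strings.
#' @return Character vector of lower-cased family names (`NA` when absent).
#' @export
first_author_family <- function(authors) {
  vapply(authors, function(a) {
    if (is.na(a) || !nzchar(trimws(a))) return(NA_character_)
    first <- trimws(strsplit(a, ";", fixed = TRUE)[[1]][1])
    fam <- if (grepl(",", first, fixed = TRUE)) {
      trimws(strsplit(first, ",", fixed = TRUE)[[1]][1])
    } else {
      parts <- strsplit(first, "[[:space:]]+")[[1]]
      parts[length(parts)]
    }
    tolower(fam)
  }, character(1), USE.NAMES = FALSE)
}

# similarity = 1 - levenshtein / max length; empty-vs-empty counts as 0 so
# title-less records never fuzzy-link
title_similarity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  m <- outer(la, lb, pmax)
  d <- utils::adist(a, b)
  s <- ifelse(m == 0, 0, 1 - d / m)
  s
}

# union-find with path halving
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster duplicate records
#'
#' Partitions a pooled corpus into duplicate clusters using DOI equality,
#' exact dedup keys and fuzzy title matching (see [dedup]). The canonical
#' member of each cluster is its lexicographically smallest `record_id`.
#'
#' @param corpus A `ref_corpus`.
#' @param fuzzy_threshold Normalized edit-distance similarity in \[0, 1\]
#'   above which same-year titles are linked. Default 0.90, high enough to
#'   catch punctuation/OCR variants without merging distinct trials with
#'   similar titles.
#' @return An object of class `dedup_clusters`: a `data.frame` with columns
#'   `cluster_id`, `canonical_id`, `size` and list-column `member_ids`.
#' @export
cluster_duplicates <- function(corpus, fuzzy_threshold = 0.90) {
  stopifnot(is.numeric(fuzzy_threshold), length(fuzzy_threshold) == 1,
            fuzzy_threshold >= 0, fuzzy_threshold <= 1)
  df <- as.data.frame(corpus)
  n <- nrow(df)
  parent <- uf_new(n)
  union_ <- function(i, j) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) parent[rj] <<- ri
  }
  link_group <- function(idx) {
    if (length(idx) > 1) for (k in idx[-1]) union_(idx[1], k)
  }

  ntitle <- normalize_title(df$title)
  year_key <- ifelse(is.na(df$year), "?", as.character(df$year))

  # (a) shared DOI
  has_doi <- !is.na(df$doi)
  if (any(has_doi))
    lapply(split(which(has_doi), df$doi[has_doi]), link_group)

  # (b) exact dedup key: normalized title + year + first-author family
  has_title <- nzchar(ntitle)
  if (any(has_title)) {
    fam <- first_author_family(df$authors)
    key <- paste(ntitle, year_key, ifelse(is.na(fam), "?", fam), sep = "\r")
    lapply(split(which(has_title), key[has_title]), link_group)
  }

  # (c) fuzzy title within equal-year blocks; a DOI conflict blocks the link
  for (idx in split(which(has_title), year_key[has_title])) {
    if (length(idx) < 2) next
    sim <- title_similarity(ntitle[idx], ntitle[idx])
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        if (sim[a, b] < fuzzy_threshold) next
        i <- idx[a]; j <- idx[b]
        if (has_doi[i] && has_doi[j] && df$doi[i] != df$doi[j]) next
        union_(i, j)
      }
    }
  }

  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  members <- split(df$record_id, roots)
  canonical <- vapply(members, min, character(1))
  ord <- order(canonical)
  members <- members[ord]; canonical <- canonical[ord]
  out <- data.frame(cluster_id = sprintf("c%05d", seq_along(members)),
                    canonical_id = unname(canonical),
                    size = lengths(members), stringsAsFactors = FALSE)
  out$member_ids <- unname(members)
  structure(out, corpus_size = n, fuzzy_threshold = fuzzy_threshold,
            class = c("dedup_clusters", "data.frame"))
}

#' @export
print.dedup_clusters <- function(x, ...) {
  cat(sprintf("Dedup clustering: %d records -> %d unique (%d duplicates), fuzzy threshold %.2f\n",
              attr(x, "corpus_size"), nrow(x),
              attr(x, "corpus_size") - nrow(x), attr(x, "fuzzy_threshold")))
  invisible(x)
}

#' Summarize a dedup clustering
#'
#' @param clusters A `dedup_clusters` object.
#' @return A list (class `dedup_report`) with `pooled` (total member
#'   records), `unique` (number of clusters) and `duplicates`
#'   (`pooled - unique`). The identity `pooled = unique + duplicates` holds
#'   by construction.
#' @export
dedup_report <- function(clusters) {
  pooled <- sum(clusters$size)
  uniq <- nrow(clusters)
  structure(list(pooled = pooled, unique = uniq, duplicates = pooled - uniq),
            class = "dedup_report")
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("pooled %d = unique %d + duplicates %d\n",
              x$pooled, x$unique, x$duplicates))
  invisible(x)
}

#' Write clusters to CSV (member ids joined by "|")
#' @param clusters A `dedup_clusters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_csv <- function(clusters, path) {
  df <- data.frame(cluster_id = clusters$cluster_id,
                   canonical_id = clusters$canonical_id,
                   member_ids = vapply(clusters$member_ids, paste,
                                       character(1), collapse = "|"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
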