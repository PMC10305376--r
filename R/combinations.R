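#' Database combinations
#'
#' A set of databases is treated as one retrieval source that returns a
#' publication if any member indexes it. The contingency convention
#' generalizes the single-database one: TP counts eligible unique
#' publications covered by the union, while FP and TN are taken over the
#' pooled screening load, here the *sum* of member yields (duplicates
#' included) -- the number of raw records a reviewer would actually screen
#' when running all member searches. `universe = "dedup"` instead counts FP
#' over the unique records of the union, for readers who prefer a
#' duplicate-free universe.
#'
#' @name combinations
NULL

check_dbs <- function(labeled, databases) {
  databases <- unique(as.character(databases))
  if (length(databases) == 0)
    stop("database set must be non-empty", call. = FALSE)
  unknown <- setdiff(databases, labeled$databases)
  if (length(unknown))
    stop(sprintf("unknown database label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  databases
}

#' Screening load of a database combination
#'
#' The number of raw records a reviewer must screen when searching all
#' member databases: the sum of the members' pooled yields, duplicate
#' copies included (the workload exists before deduplication).
#'
#' @param labeled A `labeled_corpus`.
#' @param databases Character vector of member database labels (duplicates
#'   ignored). An empty set has load 0.
#' @return Integer record count.
#' @export
screening_load <- function(labeled, databases) {
  stopifnot(inherits(labeled, "labeled_corpus"))
  databases <- unique(as.character(databases))
  if (length(databases) == 0) return(0L)
  unknown <- setdiff(databases, labeled$databases)
  if (length(unknown))
    stop(sprintf("unknown database label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  as.integer(sum(labeled$yields[databases]))
}

#' Contingency table for a database union
#'
#' @param labeled A `labeled_corpus`.
#' @param databases Non-empty character vector of member labels.
#' @param universe `"pooled"` (default): FP/TN over the summed
#'   duplicate-inclusive yields, consistent with the single-database
#'   convention; `"dedup"`: FP over the union's unique records.
#' @return A `contingency_table` labeled with the joined member names.
#' @export
union_contingency <- function(labeled, databases,
                              universe = c("pooled", "dedup")) {
  stopifnot(inherits(labeled, "labeled_corpus"))
  universe <- match.arg(universe)
  databases <- check_dbs(labeled, databases)
  covered <- rowSums(labeled$coverage[, databases, drop = FALSE]) > 0
  tp <- sum(covered & labeled$eligible)
  fn <- sum(labeled$eligible) - tp
  if (universe == "pooled") {
    load <- sum(labeled$yields[databases])
    fp <- load - tp
    tn <- max(0L, labeled$pooled - load)
  } else {
    n_union <- sum(covered)
    fp <- n_union - tp
    tn <- nrow(labeled$clusters) - n_union - fn
  }
  contingency_table(tp, fp, fn, tn,
                    database = paste(databases, collapse = " + "))
}

#' Evaluate one database combination
#'
#' @inheritParams union_contingency
#' @param level Confidence level.
#' @return A list (class `combination_result`): member `databases`, the
#'   union `contingency`, `se`/`sp`/`ac` estimates and the
#'   `screening_load`.
#' @export
combination_result <- function(labeled, databases, level = 0.95,
                               universe = "pooled") {
  ct <- union_contingency(labeled, databases, universe)
  structure(list(databases = check_dbs(labeled, databases), contingency = ct,
                 se = sensitivity(ct, level), sp = specificity(ct, level),
                 ac = accuracy(ct, level),
                 screening_load = screening_load(labeled, databases)),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("{%s}: Se %s, Sp %s, Ac %s, screening load %d\n",
              paste(x$databases, collapse = ", "),
              format_pct(x$se$point), format_pct(x$sp$point),
              format_pct(x$ac$point), x$screening_load))
  invisible(x)
}

#' Diagnostics for every unordered database pair
#'
#' @param labeled A `labeled_corpus` with at least two databases.
#' @param level Confidence level.
#' @param universe See [union_contingency()].
#' @return A `data.frame` (class `pairwise_matrix`) with one row per
#'   unordered pair: `db1`, `db2`, contingency counts, `se`, `sp`, `ac`
#'   (proportions) and `screening_load`. `print()` renders the upper
#'   triangle as "Se/Sp/Ac" percent cells.
#' @export
pairwise_matrix <- function(labeled, level = 0.95, universe = "pooled") {
  stopifnot(inherits(labeled, "labeled_corpus"))
  dbs <- labeled$databases
  if (length(dbs) < 2) stop("need at least two databases", call. = FALSE)
  pairs <- utils::combn(dbs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    res <- combination_result(labeled, pairs[, j], level, universe)
    ct <- res$contingency
    data.frame(db1 = pairs[1, j], db2 = pairs[2, j],
               tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
               se = res$se$point, sp = res$sp$point, ac = res$ac$point,
               screening_load = res$screening_load, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), databases = dbs, level = level,
            universe = universe, class = c("pairwise_matrix", "data.frame"))
}

#' Render a pairwise matrix as an upper-triangular character matrix
#' @param x A `pairwise_matrix`.
#' @return Character matrix with "Se a% / Sp b% / Ac c%" cells.
#' @export
format_pairwise <- function(x) {
  dbs <- attr(x, "databases")
  m <- matrix("", length(dbs), length(dbs), dimnames = list(dbs, dbs))
  for (i in seq_len(nrow(x))) {
    m[x$db1[i], x$db2[i]] <- sprintf("Se %s / Sp %s / Ac %s",
                                     format_pct(x$se[i]), format_pct(x$sp[i]),
                                     format_pct(x$ac[i]))
  }
  m
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("Pairwise database combinations (%d pairs, %s universe)\n",
              nrow(x), attr(x, "universe")))
  out <- data.frame(pair = paste(x$db1, x$db2, sep = " + "),
                    sensitivity = format_pct(x$se),
                    specificity = format_pct(x$sp),
                    accuracy = format_pct(x$ac),
                    load = x$screening_load, stringsAsFactors = FALSE)
  print.data.frame(out, row.names = FALSE, right = FALSE)
  invisible(x)
}

subset_label <- function(databases) paste(sort(databases), collapse = " + ")

#' Minimal database combinations reaching a target sensitivity
#'
#' Searches database subsets for the smallest combinations whose union
#' sensitivity reaches `target_se`. With 15 or fewer databases the search
#' enumerates every subset up to `max_size` exhaustively; beyond that a
#' greedy marginal-coverage heuristic is used and the result is flagged.
#' Qualifying combinations are returned best-first: smallest subset, then
#' smallest screening load, then lexicographic label.
#'
#' @param labeled A `labeled_corpus`.
#' @param target_se Target sensitivity in (0, 1]; default 1 (full coverage).
#' @param max_size Largest subset size to consider; default 3.
#' @param level Confidence level for the reported estimates.
#' @param universe See [union_contingency()].
#' @return A `data.frame` (class `minimal_cover`) with columns `databases`
#'   (labels joined by " + "), `size`, `tp`, `se`, `sp`, `ac`,
#'   `screening_load`; attribute `heuristic` marks a greedy (possibly
#'   suboptimal) search, attribute `message` explains an empty result.
#' @export
minimal_cover <- function(labeled, target_se = 1.0, max_size = 3,
                          level = 0.95, universe = "pooled") {
  stopifnot(inherits(labeled, "labeled_corpus"))
  if (!is.numeric(target_se) || target_se <= 0 || target_se > 1)
    stop("target_se must be in (0, 1]", call. = FALSE)
  dbs <- labeled$databases
  max_size <- min(max_size, length(dbs))
  heuristic <- length(dbs) > 15

  subsets <- if (!heuristic) {
    unlist(lapply(seq_len(max_size), function(k)
      utils::combn(dbs, k, simplify = FALSE)), recursive = FALSE)
  } else {
    greedy_chain(labeled, max_size)
  }

  eps <- sqrt(.Machine$double.eps)
  rows <- lapply(subsets, function(s) {
    res <- combination_result(labeled, s, level, universe)
    if (res$se$point < target_se - eps) return(NULL)
    data.frame(databases = subset_label(s), size = length(s),
               tp = res$contingency$tp, se = res$se$point, sp = res$sp$point,
               ac = res$ac$point, screening_load = res$screening_load,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(databases = character(0), size = integer(0), tp = integer(0),
               se = numeric(0), sp = numeric(0), ac = numeric(0),
               screening_load = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$size, out$screening_load, out$databases), , drop = FALSE]
  rownames(out) <- NULL
  msg <- if (nrow(out) == 0)
    sprintf("no combination of up to %d database(s) reaches sensitivity %s%s",
            max_size, format_pct(target_se),
            if (heuristic) " (greedy search; an exhaustive search might)" else "")
  structure(out, heuristic = heuristic, target_se = target_se,
            message = msg, class = c("minimal_cover", "data.frame"))
}

# greedy marginal-coverage chain: at each step add the database covering the
# most still-uncovered eligible publications (ties: smaller yield, then label)
greedy_chain <- function(labeled, max_size) {
  dbs <- labeled$databases
  chosen <- character(0)
  chain <- list()
  covered <- rep(FALSE, nrow(labeled$clusters))
  for (step in seq_len(max_size)) {
    cand <- setdiff(dbs, chosen)
    gain <- vapply(cand, function(d)
      sum(labeled$coverage[, d] & labeled$eligible & !covered), integer(1))
    ord <- order(-gain, labeled$yields[cand], cand)
    best <- cand[ord[1]]
    chosen <- c(chosen, best)
    covered <- covered | labeled$coverage[, best]
    chain[[step]] <- chosen
    if (all(covered[labeled$eligible])) break
  }
  chain
}

#' @export
print.minimal_cover <- function(x, ...) {
  cat(sprintf("Combinations reaching sensitivity >= %s%s\n",
              format_pct(attr(x, "target_se")),
              if (isTRUE(attr(x, "heuristic"))) " (greedy heuristic)" else ""))
  if (nrow(x) == 0) {
    cat(attr(x, "message"), "\n")
  } else {
    out <- data.frame(databases = x$databases, size = x$size,
                      sensitivity = format_pct(x$se),
                      specificity = format_pct(x$sp),
                      accuracy = format_pct(x$ac),
                      load = x$screening_load, stringsAsFactors = FALSE)
    print.data.frame(out, row.names = FALSE, right = FALSE)
  }
  invisible(x)
}
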