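#' Fit database-coverage diagnostics to a screened corpus
#'
#' The main entry point: takes a pooled corpus plus screening labels, runs
#' duplicate clustering and label resolution, and returns the fitted
#' coverage diagnostics for every database as a single object with the
#' usual accessors (`print`, `summary`, `coef`, `confint`, `simulate`).
#'
#' @param corpus A `ref_corpus` (see [pooled_corpus()]).
#' @param labels Screening labels `data.frame` (or path handled by
#'   [read_labels_csv()] upstream).
#' @param fuzzy_threshold Title-similarity threshold for
#'   [cluster_duplicates()].
#' @param conf_level Confidence level for all interval estimates.
#' @return An object of class `db_coverage` with components `ledger`
#'   (the [flow_ledger()]), `diagnostics` (the [diagnostics_table()]),
#'   `labeled` (the underlying `labeled_corpus`) and `conf_level`.
#' @examples
#' syn <- generate_corpus(study_preset(seed = 7))
#' fit <- db_coverage(syn$corpus, syn$labels)
#' fit
#' coef(fit)
#' @export
db_coverage <- function(corpus, labels, fuzzy_threshold = 0.90,
                        conf_level = 0.95) {
  cl <- match.call()
  clusters <- cluster_duplicates(corpus, fuzzy_threshold)
  labeled <- apply_labels(corpus, clusters, labels)
  structure(list(call = cl, labeled = labeled,
                 ledger = flow_ledger(labeled),
                 diagnostics = diagnostics_table(labeled, conf_level),
                 conf_level = conf_level),
            class = "db_coverage")
}

#' @export
print.db_coverage <- function(x, ...) {
  cat("Database coverage diagnostics\n\n")
  print(x$ledger)
  d <- x$diagnostics
  top <- d[order(-d$se), ][seq_len(min(3, nrow(d))), ]
  cat(sprintf("\nBest coverage: %s\n",
              paste(sprintf("%s (%s)", top$database, format_pct(top$se)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.db_coverage <- function(object, target_se = 1.0, max_size = 3, ...) {
  structure(list(ledger = object$ledger, diagnostics = object$diagnostics,
                 cover = minimal_cover(object$labeled, target_se, max_size,
                                       object$conf_level),
                 conf_level = object$conf_level),
            class = "summary.db_coverage")
}

#' @export
print.summary.db_coverage <- function(x, ...) {
  cat("Screening flow\n"); print(x$ledger)
  cat("\nPer-database diagnostics\n"); print(x$diagnostics)
  cat("\n"); print(x$cover)
  invisible(x)
}

#' @export
coef.db_coverage <- function(object, ...) {
  d <- object$diagnostics
  m <- as.matrix(d[, c("se", "sp", "ac")])
  dimnames(m) <- list(d$database, c("sensitivity", "specificity", "accuracy"))
  m
}

#' @export
confint.db_coverage <- function(object, parm = c("sensitivity", "specificity",
                                                 "accuracy"), level = NULL, ...) {
  parm <- match.arg(parm)
  if (!is.null(level) && level != object$conf_level)
    stop("refit with conf_level to change the interval level", call. = FALSE)
  d <- object$diagnostics
  cols <- switch(parm, sensitivity = c("se_low", "se_high"),
                 specificity = c("sp_low", "sp_high"),
                 accuracy = c("ac_low", "ac_high"))
  m <- as.matrix(d[, cols])
  dimnames(m) <- list(d$database, c("lower", "upper"))
  m
}

#' Simulate new corpora from a fitted coverage model
#'
#' Parametric resampling: each database's estimated coverage probability
#' (`tp / n_eligible`) and observed irrelevant yield are fed back into the
#' synthetic generator, giving replicate corpora under the fitted indexing
#' structure.
#'
#' @param object A `db_coverage` fit.
#' @param nsim Number of replicate corpora.
#' @param seed Integer seed (replicate *i* uses `seed + i - 1`).
#' @param ... Unused.
#' @return A list of `synthetic_corpus` objects.
#' @export
simulate.db_coverage <- function(object, nsim = 1, seed = 1L, ...) {
  lab <- object$labeled
  n_el <- sum(lab$eligible)
  d <- object$diagnostics
  spec <- synthetic_spec(databases = d$database,
                         eligible_coverage = if (n_el > 0) d$tp / n_el else 0,
                         irrelevant_yield = d$fp,
                         n_eligible = n_el, seed = seed)
  lapply(seq_len(nsim), function(i) generate_corpus(spec, seed = seed + i - 1L))
}

# --- report bundle -----------------------------------------------------

md_table <- function(df) {
  df[] <- lapply(df, as.character)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- if (nrow(df))
    apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  else character(0)
  c(header, sep, body)
}

#' Run the full coverage pipeline and write a report bundle
#'
#' Orchestrates ingestion (or synthesis), deduplication, screening,
#' per-database diagnostics, the pairwise combination matrix and the
#' minimal-cover search, writing every table as CSV plus a Markdown
#' rendering, the flow ledger as JSON, and a plain-text run log with record
#' counts in and out of every stage and all convention flags.
#'
#' @param config A list or a path to a JSON/YAML file with elements:
#'   `inputs` (list of `list(path=, format=, db=)`) *or* `simulate`
#'   (`list(preset = "study"|"study_flow", seed = )` or a full
#'   [synthetic_spec()] argument list); `labels` (CSV path; unneeded when
#'   simulating); `fuzzy_threshold` (default 0.90); `conf_level` (default
#'   0.95); `universe` (`"pooled"`/`"dedup"`); `target_se` (default 1.0);
#'   `max_size` (default 3); `outdir` (required).
#' @return Invisibly, a list (class `refcover_run`) with every computed
#'   object and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  fuzzy <- config$fuzzy_threshold %||% 0.90
  level <- config$conf_level %||% 0.95
  universe <- config$universe %||% "pooled"
  target_se <- config$target_se %||% 1.0
  max_size <- config$max_size %||% 3
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # no timestamp: the bundle is byte-identical for identical config + seed
  log_lines <- c("refcover run log",
                 sprintf("flags: fuzzy_threshold=%.2f conf_level=%.2f universe=%s target_se=%g max_size=%d",
                         fuzzy, level, universe, target_se, max_size))

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    spec <- if (!is.null(sim$preset)) {
      switch(sim$preset,
             study = study_preset(seed = sim$seed %||% 1L),
             study_flow = study_flow_preset(seed = sim$seed %||% 1L),
             stop(sprintf("unknown preset '%s'", sim$preset), call. = FALSE))
    } else do.call(synthetic_spec, sim)
    syn <- generate_corpus(spec)
    corpus <- syn$corpus
    labels <- syn$labels
    log_lines <- c(log_lines,
                   sprintf("stage simulate: %d records planted (%d publications, seed %d)",
                           nrow(corpus), syn$truth$n_publications, syn$seed))
  } else {
    if (is.null(config$inputs) || !length(config$inputs))
      stop("config needs 'inputs' or 'simulate'", call. = FALSE)
    parts <- lapply(config$inputs, function(inp) {
      if (!file.exists(inp$path))
        stop(sprintf("stage ingest: input not found: %s", inp$path), call. = FALSE)
      read_records(inp$path, inp$format, inp$db)
    })
    dbs <- vapply(config$inputs, function(inp)
      inp$db %||% NA_character_, character(1))
    dbs <- dbs[!is.na(dbs)]
    corpus <- pooled_corpus(parts, databases = if (length(dbs)) dbs else NULL)
    if (is.null(config$labels))
      stop("config needs 'labels' when reading real inputs", call. = FALSE)
    labels <- read_labels_csv(config$labels)
    log_lines <- c(log_lines,
                   sprintf("stage ingest: %d records from %d files", nrow(corpus),
                           length(config$inputs)))
  }

  yt <- pooled_yield_table(corpus)
  yt_out <- rbind(yt, data.frame(database = "Total", n_records = attr(yt, "total")))
  utils::write.csv(yt_out, file.path(outdir, "yield_table.csv"), row.names = FALSE)

  clusters <- cluster_duplicates(corpus, fuzzy)
  write_clusters_csv(clusters, file.path(outdir, "clusters.csv"))
  log_lines <- c(log_lines, sprintf("stage dedup: %d records -> %d unique clusters",
                                    nrow(corpus), nrow(clusters)))

  labeled <- apply_labels(corpus, clusters, labels)
  ledger <- flow_ledger(labeled)
  jsonlite::write_json(unclass(ledger), file.path(outdir, "ledger.json"),
                       auto_unbox = TRUE)
  log_lines <- c(log_lines,
                 sprintf("stage screen: pooled=%d duplicates=%d ineligible=%d eligible=%d",
                         ledger$pooled, ledger$duplicates, ledger$ineligible,
                         ledger$eligible))

  diag <- if (ledger$eligible > 0) diagnostics_table(labeled, level)
  utils::write.csv(as.data.frame(diag), file.path(outdir, "diagnostics.csv"),
                   row.names = FALSE)
  has_eligible <- ledger$eligible > 0 && length(labeled$databases) >= 2
  pairs <- if (has_eligible) pairwise_matrix(labeled, level, universe)
  if (!is.null(pairs))
    utils::write.csv(as.data.frame(pairs), file.path(outdir, "pairwise.csv"),
                     row.names = FALSE)
  cover <- if (has_eligible) minimal_cover(labeled, target_se, max_size,
                                           level, universe)
  if (!is.null(cover))
    utils::write.csv(as.data.frame(cover), file.path(outdir, "minimal_cover.csv"),
                     row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("stage diagnostics: %d databases, %d pairs, %d qualifying covers",
                         if (is.null(diag)) 0L else nrow(diag),
                         if (is.null(pairs)) 0L else nrow(pairs),
                         if (is.null(cover)) 0L else nrow(cover)))

  md <- c("# Coverage report", "", "## Per-database yields", md_table(yt_out), "",
          "## Screening flow",
          md_table(data.frame(stage = names(unclass(ledger)),
                              records = unlist(ledger))))
  if (!is.null(diag))
    md <- c(md, "", "## Per-database diagnostics",
            md_table(data.frame(database = diag$database,
                                sensitivity = render_est(diag$se, diag$se_low, diag$se_high),
                                specificity = render_est(diag$sp, diag$sp_low, diag$sp_high),
                                accuracy = render_est(diag$ac, diag$ac_low, diag$ac_high))))
  if (!is.null(cover) && nrow(cover))
    md <- c(md, "", sprintf("## Minimal combinations at sensitivity >= %s",
                            format_pct(target_se)),
            md_table(data.frame(databases = cover$databases,
                                sensitivity = format_pct(cover$se),
                                load = cover$screening_load)))
  writeLines(md, file.path(outdir, "report.md"))
  writeLines(log_lines, file.path(outdir, "run.log"))

  invisible(structure(list(corpus = corpus, clusters = clusters,
                           labeled = labeled, ledger = ledger,
                           yield_table = yt, diagnostics = diag,
                           pairwise = pairs, minimal_cover = cover,
                           outdir = outdir),
                      class = "refcover_run"))
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
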