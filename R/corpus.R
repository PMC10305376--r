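#' Bibliographic records and pooled corpora
#'
#' A *record* is one bibliographic entry as exported from one literature
#' database. Records are held in a plain `data.frame` with columns
#' `record_id`, `source_db`, `title`, `authors` (names joined by `"; "`),
#' `year` (integer or `NA`), `journal`, `doi` (normalized, see
#' [normalize_doi()]) and `abstract`. A *pooled corpus* is the concatenation
#' of all per-database yields before duplicate removal -- the set of records
#' a reviewer would screen -- together with the ordered list of database
#' labels searched (databases with zero yield stay in the list).
#'
#' @name corpus
NULL

RECORD_COLS <- c("record_id", "source_db", "title", "authors", "year",
                 "journal", "doi", "abstract")

new_record_df <- function(n = 0L) {
  data.frame(record_id = character(n), source_db = character(n),
             title = rep(NA_character_, n), authors = rep(NA_character_, n),
             year = rep(NA_integer_, n), journal = rep(NA_character_, n),
             doi = rep(NA_character_, n), abstract = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

#' Normalize a DOI string
#'
#' Lower-cases the DOI and strips any `https://doi.org/` (or `dx.doi.org`,
#' or a literal `doi:`) prefix, so that the same article exported from two
#' databases carries an identical key.
#'
#' @param doi Character vector of raw DOI strings (`NA` allowed).
#' @return Character vector of normalized DOIs.
#' @examples
#' normalize_doi("https://doi.org/10.1000/XYZ")  # "10.1000/xyz"
#' @export
normalize_doi <- function(doi) {
  x <- trimws(tolower(as.character(doi)))
  x <- sub("^https?://(dx\\.)?doi\\.org/", "", x)
  x <- sub("^doi:\\s*", "", x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

validate_records <- function(df, where = "records") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(RECORD_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$record_id))
    stop(sprintf("%s: duplicated record_id values: %s", where,
                 paste(unique(df$record_id[duplicated(df$record_id)]),
                       collapse = ", ")), call. = FALSE)
  if (any(is.na(df$source_db) | df$source_db == ""))
    stop(sprintf("%s: source_db must be non-empty for every record", where),
         call. = FALSE)
  no_handle <- (is.na(df$doi) | df$doi == "") & (is.na(df$title) | df$title == "")
  if (any(no_handle))
    stop(sprintf("%s: records with neither DOI nor title: %s", where,
                 paste(df$record_id[no_handle], collapse = ", ")),
         call. = FALSE)
  invisible(df)
}

parse_year <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^\\d{4}", x)
  out[ok] <- as.integer(substr(x[ok], 1, 4))
  out
}

# --- RIS ---------------------------------------------------------------

# Tag mapping follows the common reference-manager RIS profile:
# TI/T1 -> title, AU -> authors, PY -> year, DO -> doi, JO/T2 -> journal,
# AB -> abstract, ID -> record id (kept when present).
parse_ris_text <- function(lines, source_db, path = "<ris>") {
  entries <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (trimws(ln) == "") next
    m <- regmatches(ln, regexec("^([A-Z][A-Z0-9])  ?- ?(.*)$", ln))[[1]]
    if (length(m) == 0) {
      # continuation line of the previous field
      if (is.null(cur) || length(cur) == 0)
        stop(sprintf("RIS parse error in %s at line %d: '%s'", path, i, ln),
             call. = FALSE)
      last <- length(cur)
      cur[[last]]$value <- paste(cur[[last]]$value, trimws(ln))
      next
    }
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "TY") {
      if (!is.null(cur))
        stop(sprintf("RIS parse error in %s at line %d: TY before ER", path, i),
             call. = FALSE)
      cur <- list()
    } else if (tag == "ER") {
      if (is.null(cur))
        stop(sprintf("RIS parse error in %s at line %d: ER without TY", path, i),
             call. = FALSE)
      entries[[length(entries) + 1L]] <- cur
      cur <- NULL
    } else {
      if (is.null(cur))
        stop(sprintf("RIS parse error in %s at line %d: field outside record",
                     path, i), call. = FALSE)
      cur[[length(cur) + 1L]] <- list(tag = tag, value = val)
    }
  }
  if (!is.null(cur))
    stop(sprintf("RIS parse error in %s: record not terminated by ER", path),
         call. = FALSE)
  ris_entries_to_df(entries, source_db)
}

ris_entries_to_df <- function(entries, source_db) {
  n <- length(entries)
  df <- new_record_df(n)
  for (i in seq_len(n)) {
    tags <- vapply(entries[[i]], `[[`, "", "tag")
    vals <- vapply(entries[[i]], `[[`, "", "value")
    first <- function(want) {
      hit <- which(tags %in% want)
      if (length(hit)) vals[hit[1]] else NA_character_
    }
    df$record_id[i] <- first("ID")
    df$title[i]    <- first(c("TI", "T1"))
    au <- vals[tags == "AU"]
    df$authors[i]  <- if (length(au)) paste(au, collapse = "; ") else NA_character_
    df$year[i]     <- parse_year(first("PY"))
    df$journal[i]  <- first(c("JO", "T2"))
    df$doi[i]      <- first("DO")
    df$abstract[i] <- first("AB")
  }
  finish_record_df(df, source_db)
}

write_ris <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    out <- c("TY  - JOUR", sprintf("ID  - %s", r$record_id))
    if (!is.na(r$title)) out <- c(out, sprintf("TI  - %s", r$title))
    if (!is.na(r$authors))
      out <- c(out, sprintf("AU  - %s", strsplit(r$authors, "; ", fixed = TRUE)[[1]]))
    if (!is.na(r$year))    out <- c(out, sprintf("PY  - %d", r$year))
    if (!is.na(r$journal)) out <- c(out, sprintf("JO  - %s", r$journal))
    if (!is.na(r$doi))     out <- c(out, sprintf("DO  - %s", r$doi))
    if (!is.na(r$abstract)) out <- c(out, sprintf("AB  - %s", r$abstract))
    writeLines(c(out, "ER  - ", ""), con)
  }
  invisible(path)
}

# --- MEDLINE flat text -------------------------------------------------

parse_medline_text <- function(lines, source_db, path = "<medline>") {
  # entries separated by blank lines; fields are "TAG - value" with the tag
  # padded to four characters; continuation lines start with spaces
  blocks <- split(lines, cumsum(trimws(lines) == "") )
  entries <- list()
  for (b in blocks) {
    b <- b[trimws(b) != ""]
    if (!length(b)) next
    fields <- list()
    for (ln in b) {
      m <- regmatches(ln, regexec("^([A-Z]{1,4})\\s*- (.*)$", ln))[[1]]
      if (length(m)) {
        fields[[length(fields) + 1L]] <- list(tag = m[2], value = trimws(m[3]))
      } else if (grepl("^\\s+\\S", ln) && length(fields)) {
        last <- length(fields)
        fields[[last]]$value <- paste(fields[[last]]$value, trimws(ln))
      } else {
        stop(sprintf("MEDLINE parse error in %s: cannot parse line '%s'",
                     path, ln), call. = FALSE)
      }
    }
    entries[[length(entries) + 1L]] <- fields
  }
  n <- length(entries)
  df <- new_record_df(n)
  for (i in seq_len(n)) {
    tags <- vapply(entries[[i]], `[[`, "", "tag")
    vals <- vapply(entries[[i]], `[[`, "", "value")
    first <- function(want) {
      hit <- which(tags %in% want)
      if (length(hit)) vals[hit[1]] else NA_character_
    }
    df$record_id[i] <- first("PMID")
    df$title[i] <- first("TI")
    au <- vals[tags %in% c("AU", "FAU")]
    df$authors[i] <- if (length(au)) paste(au, collapse = "; ") else NA_character_
    df$year[i] <- parse_year(first("DP"))
    df$journal[i] <- first(c("JT", "TA"))
    # DOI lives in LID or AID with a "[doi]" qualifier
    doi_vals <- vals[tags %in% c("LID", "AID") & grepl("\\[doi\\]", vals)]
    df$doi[i] <- if (length(doi_vals)) sub("\\s*\\[doi\\]\\s*$", "", doi_vals[1]) else NA_character_
    df$abstract[i] <- first("AB")
  }
  finish_record_df(df, source_db)
}

# --- CSV ---------------------------------------------------------------

# Fixed dialect: UTF-8, comma-separated, header row with the record columns,
# authors joined by "; ".
parse_record_csv <- function(path, source_db = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        encoding = "UTF-8")
  missing_cols <- setdiff(RECORD_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("CSV %s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[, RECORD_COLS]
  df[df == ""] <- NA
  df$year <- parse_year(df$year)
  finish_record_df(df, source_db, keep_source = is.null(source_db))
}

#' Write records to CSV
#'
#' Emits the package's fixed CSV dialect (UTF-8, comma-separated, header row
#' `record_id,source_db,title,authors,year,journal,doi,abstract`, authors
#' joined by `"; "`). [read_records()] with `format = "csv"` reads it back
#' field-identically.
#'
#' @param records A record `data.frame` or a `ref_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- as.data.frame(records)[, RECORD_COLS]
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

finish_record_df <- function(df, source_db, keep_source = FALSE) {
  if (!keep_source) {
    if (is.null(source_db) || !nzchar(source_db))
      stop("source_db label must be a non-empty string", call. = FALSE)
    df$source_db <- rep(source_db, nrow(df))
  }
  df$doi <- normalize_doi(df$doi)
  need_id <- is.na(df$record_id) | df$record_id == ""
  if (any(need_id)) {
    slug <- gsub("[^A-Za-z0-9]+", "", df$source_db[need_id])
    df$record_id[need_id] <- sprintf("%s-%04d", slug, which(need_id))
  }
  rownames(df) <- NULL
  validate_records(df)
}

#' Read bibliographic records from a database export
#'
#' Parses one per-database export file and stamps every record with the
#' database label. DOIs are normalized ([normalize_doi()]); years are taken
#' from a leading 4-digit prefix (so RIS `PY  - 2020/01/01` gives 2020);
#' records without an explicit identifier get one derived from the database
#' label and their position in the file.
#'
#' @param path Path to the export file.
#' @param format One of `"ris"`, `"medline"`, `"csv"`.
#' @param source_db Database label stamped on every record (for `"csv"`,
#'   defaults to the file's own `source_db` column when omitted).
#' @return A record `data.frame` (see [corpus]).
#' @export
read_records <- function(path, format = c("ris", "medline", "csv"),
                         source_db = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop(
                       sprintf("unknown format '%s' (use ris, medline or csv)",
                               format[1]), call. = FALSE))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "csv") return(parse_record_csv(path, source_db))
  if (is.null(source_db) || !nzchar(source_db))
    stop("source_db label must be a non-empty string", call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  switch(format,
         ris = parse_ris_text(lines, source_db, path),
         medline = parse_medline_text(lines, source_db, path))
}

#' Assemble a pooled multi-database corpus
#'
#' Concatenates per-database record sets into the pooled screening corpus.
#' The database list fixes reporting order and keeps zero-yield databases
#' visible in every downstream table.
#'
#' @param records A record `data.frame` or a list of them (one per database).
#' @param databases Ordered character vector of database labels. Defaults to
#'   the order of first appearance in `records`; supply it explicitly to
#'   retain databases whose search yielded nothing.
#' @return An object of class `ref_corpus`: the record `data.frame` with a
#'   `databases` attribute.
#' @export
pooled_corpus <- function(records, databases = NULL) {
  if (is.data.frame(records)) records <- list(records)
  df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)[, RECORD_COLS]))
  if (is.null(df)) df <- new_record_df(0L)
  rownames(df) <- NULL
  validate_records(df, "pooled corpus")
  if (is.null(databases)) databases <- unique(df$source_db)
  unknown <- setdiff(unique(df$source_db), databases)
  if (length(unknown))
    stop(sprintf("records from databases not in the database list: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  structure(df, databases = as.character(databases),
            class = c("ref_corpus", "data.frame"))
}

#' @export
as.data.frame.ref_corpus <- function(x, ...) {
  attr(x, "databases") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.ref_corpus <- function(x, ...) {
  dbs <- attr(x, "databases")
  cat(sprintf("Pooled corpus: %d records from %d databases\n", nrow(x),
              length(dbs)))
  yt <- pooled_yield_table(x)
  print.data.frame(yt, row.names = FALSE)
  invisible(x)
}

corpus_databases <- function(corpus) attr(corpus, "databases")

#' Per-database yield table
#'
#' Counts pooled records per database, in corpus order, with the recomputed
#' total as an attribute (and available via `sum()`). The total is always the
#' recount of the records actually present, never a stored figure.
#'
#' @param corpus A `ref_corpus`.
#' @return A `data.frame` with columns `database` and `n_records`; attribute
#'   `total` holds the pooled size.
#' @export
pooled_yield_table <- function(corpus) {
  dbs <- corpus_databases(corpus)
  n <- vapply(dbs, function(d) sum(corpus$source_db == d), integer(1))
  structure(data.frame(database = dbs, n_records = unname(n),
                       stringsAsFactors = FALSE),
            total = sum(n))
}

db_yields <- function(corpus) {
  yt <- pooled_yield_table(corpus)
  stats::setNames(yt$n_records, yt$database)
}
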