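# small fixtures built in code

make_record <- function(id, db, title = "A title", authors = "Smith, J.",
                        year = 2020L, journal = "Retina", doi = NA_character_,
                        abstract = NA_character_) {
  data.frame(record_id = id, source_db = db, title = title, authors = authors,
             year = year, journal = journal, doi = doi, abstract = abstract,
             stringsAsFactors = FALSE)
}

# a tiny labeled corpus with known coverage structure:
# pubs A..E; A,B,C eligible; D,E not.
# db1 indexes A,B,D; db2 indexes B,C; db3 indexes E twice? no - E once.
tiny_labeled <- function() {
  recs <- rbind(
    make_record("r01", "db1", "Alpha trial of eplerenone", doi = "10.1/a"),
    make_record("r02", "db1", "Beta trial of laser", doi = "10.1/b"),
    make_record("r03", "db1", "Delta observational cohort", doi = "10.1/d"),
    make_record("r04", "db2", "Beta trial of laser", doi = "10.1/b"),
    make_record("r05", "db2", "Gamma trial of verteporfin", doi = "10.1/c"),
    make_record("r06", "db3", "Epsilon case series", doi = "10.1/e"))
  corpus <- pooled_corpus(recs, databases = c("db1", "db2", "db3"))
  clusters <- cluster_duplicates(corpus)
  labels <- data.frame(
    cluster_id = c("r01", "r02", "r05", "r03", "r06"),
    decision = c("eligible", "eligible", "eligible", "ineligible", "ineligible"),
    reason = c(NA, NA, NA, "not randomized", "not randomized"),
    stringsAsFactors = FALSE)
  apply_labels(corpus, clusters, labels)
}

# independent recount of a union contingency straight from the record table,
# bypassing the coverage matrix (oracle for the combinations engine)
brute_union_contingency <- function(syn, dbs) {
  corpus <- syn$corpus
  truth <- syn$truth
  present <- !is.na(truth$canonical_id)
  covered <- apply(truth$indexing[, dbs, drop = FALSE], 1, any)
  tp <- sum(covered & truth$eligible & present)
  fn <- sum(truth$eligible & present) - tp
  load <- sum(corpus$source_db %in% dbs)
  list(tp = tp, fp = load - tp, fn = fn,
       tn = max(0L, nrow(corpus) - load), load = load)
}

table3_counts <- function() {
  data.frame(
    database = c("BIOSIS Previews", "CINAHL", "Cochrane Central",
                 "Current Contents Connect", "Data Citation Index",
                 "Derwent Innovations Index", "EMBASE",
                 "KCI-Korean Journal Database", "MEDLINE", "PubMed",
                 "SciELO Citation Index", "Web of Science Core Collection"),
    tp = c(32, 12, 66, 44, 0, 0, 67, 4, 28, 57, 0, 51),
    fp = c(48, 14, 75, 53, 0, 0, 117, 0, 74, 81, 2, 75),
    fn = c(44, 64, 10, 32, 76, 76, 9, 72, 48, 19, 76, 25),
    tn = c(768, 822, 707, 751, 848, 848, 664, 844, 746, 710, 846, 722),
    stringsAsFactors = FALSE)
}

pct <- function(p) floor(100 * p + 0.5)
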