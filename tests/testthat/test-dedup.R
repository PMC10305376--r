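test_that("title normalization applies the stated rules and is idempotent", {
  expect_equal(normalize_title("Half-dose  Photodynamic Therapy!"),
               "halfdose photodynamic therapy")
  expect_equal(normalize_title(""), "")
  expect_equal(normalize_title(NA), "")
  expect_equal(normalize_title("  \tRetina:  a review.  "), "retina a review")

  set.seed(42)
  for (i in 1:50) {
    raw <- paste(sample(c(letters, LETTERS, 0:9, "-", ":", "!", " ", "  "),
                        sample(5:40, 1), replace = TRUE), collapse = "")
    once <- normalize_title(raw)
    expect_identical(normalize_title(once), once)
    expect_false(grepl("[^a-z0-9 ]", once))
  }
})

test_that("first-author family name handles both name orders", {
  expect_equal(first_author_family("Smith, J.; Jones, K."), "smith")
  expect_equal(first_author_family("J. van der Smith"), "smith")
  expect_equal(first_author_family("Boberg-Ans, L. C."), "boberg-ans")
  expect_true(is.na(first_author_family(NA_character_)))
})

test_that("distinct records stay singletons; planted variants cluster", {
  # all-distinct DOIs and titles -> singletons
  recs <- do.call(rbind, lapply(1:6, function(i)
    make_record(sprintf("r%02d", i), "db1",
                title = paste("Unique trial number", i, "of therapy", i * 7),
                doi = sprintf("10.9/%d", i), year = 2000L + i)))
  cl <- cluster_duplicates(pooled_corpus(recs))
  expect_equal(nrow(cl), 6)
  expect_true(all(cl$size == 1))

  # one publication in 3 databases with punctuation-variant titles
  v <- rbind(
    make_record("a1", "db1", "Half-dose photodynamic therapy: a randomized trial",
                year = 2015L),
    make_record("a2", "db2", "Half dose  photodynamic therapy - a randomized trial",
                year = 2015L),
    make_record("a3", "db3", "HALF-DOSE PHOTODYNAMIC THERAPY: A RANDOMIZED TRIAL",
                year = 2015L),
    make_record("b1", "db1", "Full-dose photodynamic therapy outcomes",
                year = 2015L, authors = "Chen, L."))
  cl2 <- cluster_duplicates(pooled_corpus(v))
  expect_equal(sort(cl2$size), c(1L, 3L))
  trio <- cl2$member_ids[[which(cl2$size == 3)]]
  expect_setequal(trio, c("a1", "a2", "a3"))
  expect_equal(cl2$canonical_id[which(cl2$size == 3)], "a1")
})

test_that("DOI agreement links and DOI conflict blocks fuzzy links", {
  recs <- rbind(
    make_record("x1", "db1", "Completely different title one", doi = "10.5/same",
                year = 2010L),
    make_record("x2", "db2", "Another unrelated wording here", doi = "10.5/same",
                year = 2011L),
    # near-identical titles, same year, conflicting DOIs: must NOT merge
    make_record("y1", "db1", "Micropulse laser for chronic disease trial",
                doi = "10.5/y1", year = 2012L),
    make_record("y2", "db2", "Micropulse laser for chronic disease trials",
                doi = "10.5/y2", year = 2012L, authors = "Chen, L."))
  cl <- cluster_duplicates(pooled_corpus(recs))
  sizes <- setNames(cl$size, cl$canonical_id)
  expect_equal(unname(sizes["x1"]), 2L)
  expect_equal(unname(sizes["y1"]), 1L)
  expect_equal(unname(sizes["y2"]), 1L)
})

test_that("transitive closure matches an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:4) {
    syn <- generate_corpus(synthetic_spec(
      databases = LETTERS[1:5], eligible_coverage = runif(5, 0.2, 0.9),
      irrelevant_yield = sample(3:12, 5), n_eligible = 25,
      duplicate_noise = 0.3, seed = 100 + s))
    corpus <- syn$corpus
    if (nrow(corpus) > 200)
      corpus <- pooled_corpus(as.data.frame(corpus)[1:200, ],
                              attr(corpus, "databases"))
    cl <- cluster_duplicates(corpus, 0.9)

    # oracle: test every pair directly, take graph components
    df <- as.data.frame(corpus)
    nt <- normalize_title(df$title)
    fam <- first_author_family(df$authors)
    yr <- ifelse(is.na(df$year), "?", df$year)
    n <- nrow(df)
    edges <- matrix(integer(0), ncol = 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      doi_link <- !is.na(df$doi[i]) && !is.na(df$doi[j]) && df$doi[i] == df$doi[j]
      key_link <- nzchar(nt[i]) && nt[i] == nt[j] && yr[i] == yr[j] &&
        identical(fam[i], fam[j])
      sim <- if (nzchar(nt[i]) && nzchar(nt[j]))
        1 - adist(nt[i], nt[j])[1, 1] / max(nchar(nt[i]), nchar(nt[j])) else 0
      doi_conflict <- !is.na(df$doi[i]) && !is.na(df$doi[j]) && df$doi[i] != df$doi[j]
      fuzzy_link <- sim >= 0.9 && yr[i] == yr[j] && !doi_conflict
      if (doi_link || key_link || fuzzy_link)
        edges <- rbind(edges, c(i, j))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    got <- rep(NA_integer_, n)
    for (k in seq_len(nrow(cl)))
      got[match(cl$member_ids[[k]], df$record_id)] <- k
    # same partition: cluster labels are a bijection of component labels
    expect_equal(length(unique(comp)), nrow(cl))
    expect_true(all(tapply(comp, got, function(v) length(unique(v))) == 1))
  }
})

test_that("lowering the fuzzy threshold never increases the cluster count", {
  syn <- generate_corpus(synthetic_spec(
    databases = LETTERS[1:4], eligible_coverage = 0.6,
    irrelevant_yield = 8, n_eligible = 20, duplicate_noise = 0.4, seed = 9))
  thresholds <- c(1, 0.95, 0.9, 0.8, 0.6, 0.4, 0.2, 0)
  counts <- vapply(thresholds, function(th)
    nrow(cluster_duplicates(syn$corpus, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dedup report satisfies the conservation identity", {
  recs <- do.call(rbind, lapply(1:10, function(i)
    make_record(sprintf("s%02d", i), "db1",
                title = paste("Singleton record", i, "entirely unlike others", i * 13),
                year = 1990L + i)))
  rep0 <- dedup_report(cluster_duplicates(pooled_corpus(recs)))
  expect_equal(unclass(rep0)[c("pooled", "unique", "duplicates")],
               list(pooled = 10L, unique = 10L, duplicates = 0L))

  syn <- generate_corpus(study_flow_preset(seed = 2))
  rep1 <- dedup_report(cluster_duplicates(syn$corpus))
  expect_equal(rep1$pooled, rep1$unique + rep1$duplicates)
})

test_that("study-scale flow reconstruction recovers 301 unique and 547 duplicates", {
  syn <- generate_corpus(study_flow_preset(seed = 4))
  expect_equal(nrow(syn$corpus), 848)
  rep <- dedup_report(cluster_duplicates(syn$corpus))
  expect_equal(rep$unique, 301)
  expect_equal(rep$duplicates, 547)
})
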