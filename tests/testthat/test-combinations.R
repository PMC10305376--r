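test_that("union with itself or with an empty database changes nothing", {
  lab <- tiny_labeled()
  single <- build_contingency(lab, "db1")
  self_union <- union_contingency(lab, c("db1", "db1"))
  expect_equal(unclass(self_union)[c("tp", "fp", "fn", "tn")],
               unclass(single)[c("tp", "fp", "fn", "tn")])

  recs <- rbind(make_record("r1", "full", "Trial of alpha drug", doi = "10.4/1"),
                make_record("r2", "full", "Cohort of beta drug", doi = "10.4/2"))
  corpus <- pooled_corpus(recs, databases = c("full", "void"))
  lab2 <- apply_labels(corpus, cluster_duplicates(corpus),
                       data.frame(cluster_id = c("r1", "r2"),
                                  decision = c("eligible", "ineligible"),
                                  reason = c(NA, "not randomized")))
  with_void <- union_contingency(lab2, c("full", "void"))
  alone <- build_contingency(lab2, "full")
  expect_equal(unclass(with_void)[c("tp", "fp", "fn", "tn")],
               unclass(alone)[c("tp", "fp", "fn", "tn")])
  expect_error(union_contingency(lab2, character(0)), "non-empty")
})

test_that("screening load sums duplicate-inclusive member yields", {
  syn <- generate_corpus(study_preset(seed = 1))
  lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
  expect_equal(screening_load(lab, c("Cochrane Central", "PubMed")), 279L)
  expect_equal(screening_load(lab, character(0)), 0L)
  expect_equal(screening_load(lab, lab$databases), nrow(syn$corpus))
  expect_error(screening_load(lab, "Scopus"), "unknown database")
})

test_that("every unordered pair appears once and is order-invariant", {
  syn <- generate_corpus(study_preset(seed = 2))
  lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
  pm <- pairwise_matrix(lab)
  expect_equal(nrow(pm), choose(12, 2))
  ab <- union_contingency(lab, c("EMBASE", "PubMed"))
  ba <- union_contingency(lab, c("PubMed", "EMBASE"))
  expect_equal(unclass(ab)[c("tp", "fp", "fn", "tn")],
               unclass(ba)[c("tp", "fp", "fn", "tn")])
})

test_that("pairwise engine agrees with a record-level recount oracle", {
  syn <- generate_corpus(synthetic_spec(
    databases = paste0("db", 1:5), eligible_coverage = c(0.8, 0.6, 0.5, 0.3, 0.1),
    irrelevant_yield = c(20, 15, 10, 5, 2), n_eligible = 30,
    duplicate_noise = 0.2, seed = 77))
  lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
  pm <- pairwise_matrix(lab)
  for (i in seq_len(nrow(pm))) {
    oracle <- brute_union_contingency(syn, c(pm$db1[i], pm$db2[i]))
    expect_equal(pm$tp[i], oracle$tp)
    expect_equal(pm$fp[i], oracle$fp)
    expect_equal(pm$fn[i], oracle$fn)
    expect_equal(pm$tn[i], oracle$tn)
    expect_equal(pm$screening_load[i], oracle$load)
  }
})

test_that("adding databases never lowers union sensitivity", {
  syn <- generate_corpus(synthetic_spec(
    databases = LETTERS[1:6], eligible_coverage = runif(6, 0.1, 0.9),
    irrelevant_yield = sample(0:25, 6), n_eligible = 40, seed = 55))
  lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
  set.seed(55)
  for (rep in 1:10) {
    perm <- sample(lab$databases)
    se_chain <- vapply(seq_along(perm), function(k)
      sensitivity(union_contingency(lab, perm[1:k]))$point, numeric(1))
    expect_true(all(diff(se_chain) >= -1e-12))
  }
})

test_that("exhaustive minimal cover equals brute-force subset enumeration", {
  for (s in 1:3) {
    syn <- generate_corpus(synthetic_spec(
      databases = paste0("d", 1:6), eligible_coverage = runif(6, 0.2, 0.8),
      irrelevant_yield = sample(0:20, 6), n_eligible = 25, seed = 300 + s))
    lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
    target <- 0.9
    mc <- minimal_cover(lab, target_se = target, max_size = 3)
    expect_false(attr(mc, "heuristic"))

    # oracle: enumerate all subsets of size <= 3 with direct recounts
    qualifying <- list()
    for (k in 1:3) for (subset in combn(lab$databases, k, simplify = FALSE)) {
      o <- brute_union_contingency(syn, subset)
      se <- o$tp / (o$tp + o$fn)
      if (se >= target - 1e-12)
        qualifying[[length(qualifying) + 1]] <-
          data.frame(databases = paste(sort(subset), collapse = " + "),
                     size = k, load = o$load)
    }
    oracle <- do.call(rbind, qualifying)
    oracle <- oracle[order(oracle$size, oracle$load, oracle$databases), ]
    expect_equal(mc$databases, oracle$databases)
    expect_equal(mc$screening_load, oracle$load)
  }
})

test_that("specificity drops when adding pure noise and target misses are reported", {
  recs <- rbind(make_record("r1", "good", "Trial of alpha drug", doi = "10.6/1"),
                make_record("r2", "noise", "Cohort of beta drug", doi = "10.6/2"),
                make_record("r3", "noise", "Cohort of gamma drug", doi = "10.6/3"))
  corpus <- pooled_corpus(recs, databases = c("good", "noise"))
  lab <- apply_labels(corpus, cluster_duplicates(corpus),
                      data.frame(cluster_id = c("r1", "r2", "r3"),
                                 decision = c("eligible", "ineligible", "ineligible"),
                                 reason = c(NA, "x", "x")))
  sp_alone <- specificity(build_contingency(lab, "good"))$point
  sp_union <- specificity(union_contingency(lab, c("good", "noise")))$point
  expect_lt(sp_union, sp_alone)

  # unreachable target -> empty result with a diagnostic message
  lab2 <- tiny_labeled()  # db3 carries no eligible publication
  mc <- minimal_cover(lab2, target_se = 1, max_size = 1)
  has_full <- any(vapply(lab2$databases, function(d)
    sensitivity(build_contingency(lab2, d))$point == 1, logical(1)))
  if (!has_full) {
    expect_equal(nrow(mc), 0)
    expect_match(attr(mc, "message"), "no combination")
  }
})

test_that("study reconstruction: Cochrane Central + PubMed is the best full-coverage pair", {
  syn <- generate_corpus(study_preset(seed = 3))
  lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
  u <- union_contingency(lab, c("Cochrane Central", "PubMed"))
  expect_equal(sensitivity(u)$point, 1.0)
  mc <- minimal_cover(lab, target_se = 1.0, max_size = 2)
  expect_gte(nrow(mc), 1)
  # singletons cannot reach 100% (no database covers all 76), so the top
  # result is the pair with the smallest screening load
  expect_equal(mc$size[1], 2)
  expect_equal(mc$databases[1], "Cochrane Central + PubMed")
  expect_equal(mc$screening_load[1], 279L)
})

test_that("greedy heuristic never beats the exhaustive optimum", {
  for (s in 1:2) {
    syn <- generate_corpus(synthetic_spec(
      databases = paste0("g", 1:6), eligible_coverage = runif(6, 0.2, 0.9),
      irrelevant_yield = sample(0:15, 6), n_eligible = 20, seed = 400 + s))
    lab <- apply_labels(syn$corpus, cluster_duplicates(syn$corpus), syn$labels)
    # greedy chain evaluated directly against the exhaustive result
    exhaustive <- minimal_cover(lab, target_se = 1, max_size = 3)
    greedy_sets <- refcover:::greedy_chain(lab, 3)
    best_greedy_se <- max(vapply(greedy_sets, function(sset)
      sensitivity(union_contingency(lab, sset))$point, numeric(1)))
    best_exhaustive_se <- max(vapply(1:3, function(k)
      max(vapply(combn(lab$databases, k, simplify = FALSE), function(sset)
        sensitivity(union_contingency(lab, sset))$point, numeric(1))),
      numeric(1)))
    expect_lte(best_greedy_se, best_exhaustive_se + 1e-12)
  }
})
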