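test_that("group_consensus follows the frequency definition", {
  expect_equal(group_consensus(c("W", "W", "W")), "W")
  expect_true(is.na(group_consensus(c("W", "W", "F"))))
  expect_equal(group_consensus(c("W", "W", "F"), 0.66), "W")
  expect_true(is.na(group_consensus(c("-", "-", "-"))))
  # gappier than max_gap_frac -> no consensus even if non-gaps agree
  expect_true(is.na(group_consensus(c("W", "-", "-"), 1, max_gap_frac = 0.25)))
  expect_equal(group_consensus(c("W", "W", "W", "-"), 1,
                               max_gap_frac = 0.25), "W")
  expect_error(group_consensus(character(0)), "empty group")
  expect_error(group_consensus("W", threshold = 0.4), "threshold")
})

test_that("group_consensus matches a brute-force frequency count", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    col <- sample(c("A", "V", "W", "-"), n, replace = TRUE)
    thr <- sample(c(0.51, 0.66, 0.75, 1), 1)
    got <- group_consensus(col, thr)
    want <- oracle_consensus(col, thr)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(want)) expect_identical(unname(got), want)
  }
})

test_that("property mode calls class-level conservation", {
  # all hydrophobic but not identical: no identity consensus, class consensus
  col <- c("V", "L", "I", "V")
  expect_true(is.na(group_consensus(col, 1, mode = "identity")))
  got <- group_consensus(col, 1, mode = "property")
  expect_equal(attr(got, "aa_class"), "hydrophobic")
  expect_equal(as.character(got), "V")  # most frequent member
  # mixed classes fail
  expect_true(is.na(group_consensus(c("V", "D", "V", "D"), 1,
                                    mode = "property")))
})

test_that("classify_column implements the four-category Venn scheme", {
  mk <- function(d, w, q) {
    # pad with a constant second column so single-residue rows stay valid
    grouped_alignment(
      ids = c("d1", "d2", "w1", "w2", "q"),
      aligned = paste0(c(d[1], d[2], w[1], w[2], q), "A"),
      groups = c("delta12", "delta12", "omega3", "omega3", "query"))
  }
  cls <- function(ga) classify_column(column_profile(ga, 1))
  # delta conserved, query matches, omega mixed -> 1
  expect_equal(cls(mk(c("V", "V"), c("I", "L"), "V")), 1L)
  # delta conserved, query differs -> 2
  expect_equal(cls(mk(c("V", "V"), c("I", "L"), "K")), 2L)
  # omega conserved, query matches -> 3
  expect_equal(cls(mk(c("I", "L"), c("W", "W"), "W")), 3L)
  # omega conserved, query differs -> 4
  expect_equal(cls(mk(c("I", "L"), c("W", "W"), "F")), 4L)
  # both sides conserved at different residues, query follows omega -> 2 and 3
  expect_equal(cls(mk(c("V", "V"), c("I", "I"), "I")), c(2L, 3L))
  # identically conserved column carries no signal
  expect_equal(cls(mk(c("A", "A"), c("A", "A"), "A")), integer(0))
  # neither group conserved -> nothing
  expect_equal(cls(mk(c("V", "I"), c("W", "F"), "A")), integer(0))
  # query gap -> skipped with a notice
  expect_message(out <- cls(mk(c("V", "V"), c("I", "L"), "-")), "gap")
  expect_equal(out, integer(0))
})

test_that("scan_candidates recovers planted sites exactly (precision and recall 1)", {
  sim <- simulate_family(seed = 42)
  cand <- scan_candidates(sim$alignment, threshold = 1)
  truth <- sim$truth$planted
  expect_setequal(cand$ref_position, truth$ref_position)
  got <- cand[match(truth$ref_position, cand$ref_position), ]
  expect_equal(as.integer(got$categories), truth$category)
  # a fully conserved alignment yields no candidates
  flat <- grouped_alignment(
    ids = c("d1", "d2", "w1", "w2", "q"),
    aligned = rep("ACDEF", 5),
    groups = c("delta12", "delta12", "omega3", "omega3", "query"))
  expect_equal(nrow(scan_candidates(flat)), 0)
})

test_that("scan_candidates is invariant to row order and gap-only columns", {
  sim <- simulate_family(width = 150, planted = plant_default_sites(8, 150, 9),
                         seed = 9)
  ga <- sim$alignment
  base <- scan_candidates(ga)

  perm <- sample(seq_along(ga$ids))
  shuffled <- grouped_alignment(ga$ids[perm], unname(ga$aligned[perm]),
                                unname(ga$groups[perm]), ga$reference_id)
  got <- scan_candidates(shuffled)
  expect_equal(got[c("ref_position", "categories", "query_residue")],
               base[c("ref_position", "categories", "query_residue")])

  # splice an all-gap column into the middle: positions must not move
  at <- 75
  spliced <- vapply(ga$aligned, function(s) {
    paste0(substr(s, 1, at), "-", substr(s, at + 1, nchar(s)))
  }, character(1))
  ga2 <- grouped_alignment(ga$ids, unname(spliced), unname(ga$groups),
                           ga$reference_id)
  got2 <- scan_candidates(ga2)
  expect_equal(got2[c("ref_position", "categories", "query_residue")],
               base[c("ref_position", "categories", "query_residue")])
})

test_that("raising the threshold never adds consensus columns", {
  sim <- simulate_family(width = 200, n_delta12 = 5, n_omega3 = 5,
                         planted = plant_default_sites(6, 200, 2), seed = 2)
  ga <- sim$alignment
  thresholds <- c(0.6, 0.8, 1.0)
  counts <- vapply(thresholds, function(th) {
    n <- 0L
    for (j in seq_len(ga$width)) {
      prof <- column_profile(ga, j, threshold = th)
      n <- n + !is.na(prof$delta12_consensus) + !is.na(prof$omega3_consensus)
    }
    n
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("divergent_sites matches a brute-force re-scan", {
  sim <- simulate_family(width = 100, n_delta12 = 3, n_omega3 = 3,
                         planted = plant_default_sites(4, 100, 8),
                         n_query_gaps = 5, seed = 8)
  ga <- sim$alignment
  # add a second query-role paralog: copy of query1 with some edits
  q1 <- ga$aligned[["query1"]]
  set.seed(81)
  cc <- strsplit(q1, "")[[1]]
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  edit_cols <- sample(which(cc != "-"), 15)
  for (j in edit_cols) cc[j] <- setdiff(aa20, cc[j])[1]
  ga2 <- grouped_alignment(c(ga$ids, "query2"),
                           c(unname(ga$aligned), paste(cc, collapse = "")),
                           c(unname(ga$groups), "other"), "query1")
  got <- divergent_sites(ga2, "query1", "query2")

  # oracle: per-column explicit check
  cm <- build_column_map(ga2, "query1")
  c1 <- strsplit(ga2$aligned[["query1"]], "")[[1]]
  c2 <- strsplit(ga2$aligned[["query2"]], "")[[1]]
  want <- integer(0)
  for (j in seq_len(ga2$width)) {
    if (c1[j] == "-" || c2[j] == "-" || c1[j] == c2[j]) next
    d12 <- vapply(ga2$ids[ga2$groups == "delta12"],
                  function(id) substr(ga2$aligned[[id]], j, j), character(1))
    w3 <- vapply(ga2$ids[ga2$groups == "omega3"],
                 function(id) substr(ga2$aligned[[id]], j, j), character(1))
    if (is.na(oracle_consensus(d12, 1)) && is.na(oracle_consensus(w3, 1))) {
      want <- c(want, cm$col_to_res[j])
    }
  }
  expect_equal(got$ref_position, sort(want))
  expect_error(divergent_sites(ga2, "query1", "query1"), "must differ")
})

test_that("category lists merge to the published 44 unique Fm1 positions", {
  sets <- fm1_candidate_sets()
  merged <- merge_category_lists(sets)
  expect_length(merged, 44)
  # the shared-omega3 subset lies inside the omega3 listing
  expect_true(all(sets$shared_omega3 %in% sets$omega3_only))
})
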