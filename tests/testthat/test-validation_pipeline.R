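simple_community <- function(scaffolds, group = "Alpha", donor = "Beta") {
  set.seed(301)
  list(
    m1 = mag_record("m1", group, "Bacteria", scaffolds = scaffolds),
    m2 = mag_record("m2", donor, "Bacteria", scaffolds = c(d_s1 = random_dna(400))))
}

test_that("virus overlap step removes virus-to-virus and shared-scaffold calls", {
  fx <- make_funnel_fixture()
  res <- remove_cross_catalogue_overlap(fx$candidates, fx$community)
  expect_false("c01" %in% res$survivors$candidate_id)
  expect_equal(nrow(res$survivors), 9L)
  expect_equal(res$decisions[candidate_id == "c01", detail], "virus-to-virus")

  # same scaffold id under a viral and a cellular MAG -> catalogue overlap
  community <- fx$community
  community$magX <- mag_record("magX", "Gamma", "Bacteria",
                               scaffolds = c(sV2 = random_dna(300)))
  res2 <- remove_cross_catalogue_overlap(fx$candidates, community)
  expect_equal(res2$decisions[candidate_id == "c01", detail], "virus-to-virus")
  cand_gamma <- make_candidates(data.table::data.table(
    candidate_id = "cx", recipient_mag = "magX", recipient_group = "Gamma",
    scaffold_id = "sV2", start = 0L, end = 150L, donor_group = "Beta"))
  res3 <- remove_cross_catalogue_overlap(cand_gamma, community)
  expect_equal(res3$decisions$detail, "catalogue overlap")
  expect_equal(nrow(res3$survivors), 0L)
})

test_that("length filter uses the published strict-< boundary", {
  community <- simple_community(c(s1 = strrep("A", 2000)))
  cand <- make_candidates(data.table::data.table(
    candidate_id = c("k99", "k100", "k946"),
    recipient_mag = "m1", recipient_group = "Alpha", scaffold_id = "s1",
    start = 0L, end = c(99L, 100L, 946L), donor_group = "Beta"))
  res <- filter_min_length(cand)
  expect_identical(sort(res$survivors$candidate_id), c("k100", "k946"))
  expect_equal(res$decisions[candidate_id == "k99", status], "discard")
})

test_that("scaffold saturation filter keeps exactly 95% and drops above", {
  set.seed(11)
  community <- simple_community(c(s1 = random_dna(1000)))
  cand <- make_candidates(data.table::data.table(
    candidate_id = c("sat950", "sat951", "sat960", "whole"),
    recipient_mag = "m1", recipient_group = "Alpha", scaffold_id = "s1",
    start = 0L, end = c(950L, 951L, 960L, 1000L), donor_group = "Beta"))
  res <- filter_scaffold_saturation(cand, community)
  expect_identical(res$survivors$candidate_id, "sat950")
  expect_equal(res$decisions[candidate_id != "sat950", status], rep("discard", 3))

  cand_bad <- make_candidates(data.table::data.table(
    candidate_id = "x", recipient_mag = "m1", recipient_group = "Alpha",
    scaffold_id = "nope", start = 0L, end = 10L, donor_group = "Beta"))
  expect_error(filter_scaffold_saturation(cand_bad, community), "absent")
})

test_that("tandem repeat detector finds arrays by definition", {
  r1 <- detect_simple_repeats("ACACACACACAC")
  expect_equal(as.integer(c(r1$start, r1$end)), c(0L, 12L))
  expect_equal(nrow(detect_simple_repeats("ACGTACGTTTTT")), 0L)
  # homopolymer
  r2 <- detect_simple_repeats(paste0("GATTACA", strrep("T", 15), "GATTACA"))
  expect_equal(nrow(r2), 1L)
  expect_true(r2$start <= 7L && r2$end >= 22L)
  # N runs are not repeats
  expect_equal(nrow(detect_simple_repeats(strrep("N", 50))), 0L)

  # planted arrays of span >= 12 are recovered
  set.seed(53)
  for (i in 1:10) {
    motif <- random_dna(sample(2:6, 1))
    copies <- ceiling(14 / nchar(motif)) + sample(0:3, 1)
    arr <- strrep(motif, copies)
    at <- sample(50:120, 1)
    seq <- paste0(random_dna(at), arr, random_dna(60))
    hits <- detect_simple_repeats(seq)
    covered <- any(hits$start <= at & hits$end >= at + nchar(arr))
    expect_true(covered,
                info = sprintf("motif %s x %d at %d", motif, copies, at))
  }
})

test_that("repeat and N content filters measure the whole scaffold", {
  set.seed(71)
  community <- simple_community(c(
    rep55 = paste0(strrep("AT", 275), random_dna(450)),   # 55% repeat
    n501 = paste0(strrep("N", 501), random_dna(499)),     # 50.1% N
    n500 = paste0(strrep("N", 500), random_dna(500)),     # 50.0% N
    clean = random_dna(1000)))
  cand <- make_candidates(data.table::data.table(
    candidate_id = c("r55", "n501", "n500", "ok"),
    recipient_mag = "m1", recipient_group = "Alpha",
    scaffold_id = c("rep55", "n501", "n500", "clean"),
    start = 600L, end = 750L, donor_group = "Beta"))
  res <- filter_repeat_and_n(cand, community)
  expect_identical(sort(res$survivors$candidate_id), c("n500", "ok"))

  # external mask overrides the built-in detector; 50.0% passes, 50.1% fails
  mask_pass <- data.table::data.table(scaffold_id = "clean", start = 0L,
                                      end = 500L, kind = "simple_repeat")
  mask_fail <- data.table::data.table(scaffold_id = "clean", start = 0L,
                                      end = 501L, kind = "simple_repeat")
  ok_cand <- cand[candidate_id == "ok"]
  expect_equal(nrow(filter_repeat_and_n(ok_cand, community, mask_pass)$survivors), 1L)
  expect_equal(nrow(filter_repeat_and_n(ok_cand, community, mask_fail)$survivors), 0L)
  # 37% repeat coverage passes comfortably
  mask37 <- data.table::data.table(scaffold_id = "clean", start = 0L,
                                   end = 370L, kind = "simple_repeat")
  expect_equal(nrow(filter_repeat_and_n(ok_cand, community, mask37)$survivors), 1L)
})

test_that("taxonomic consistency follows top-hit class with lenient/strict modes", {
  set.seed(83)
  community <- simple_community(c(s1 = random_dna(1000)))
  cand <- make_candidates(data.table::data.table(
    candidate_id = c("hitRec", "hitDon", "noHit", "hitOther"),
    recipient_mag = "m1", recipient_group = "Alpha", scaffold_id = "s1",
    start = c(0L, 150L, 300L, 450L), end = c(120L, 270L, 420L, 570L),
    donor_group = "Beta"))
  hom <- hgtweave:::as_homology_table(data.table::data.table(
    query_id = c("hitRec.nonhgt", "hitDon.nonhgt", "hitOther.nonhgt"),
    subject_accession = c("a1", "a2", "a3"),
    subject_class = c("Alpha", "Beta", "Gammaproteobacteria"),
    percent_identity = 80, bitscore = 100))
  res <- taxonomic_consistency_filter(cand, community, hom)
  d <- res$decisions
  expect_equal(d[candidate_id == "hitRec", status], "pass")
  expect_equal(d[candidate_id == "hitDon", status], "discard")
  expect_equal(d[candidate_id == "noHit", c(status, detail)], c("flag", "no-hit"))
  expect_equal(d[candidate_id == "hitOther", status], "flag")
  expect_equal(sort(res$survivors$candidate_id), c("hitOther", "hitRec", "noHit"))

  strict <- taxonomic_consistency_filter(cand, community, hom, mode = "strict")
  expect_equal(strict$decisions[candidate_id == "hitOther", status], "discard")
  expect_equal(sort(strict$survivors$candidate_id), c("hitRec", "noHit"))

  bad <- hgtweave:::as_homology_table(data.table::data.table(
    query_id = "hitRec", subject_accession = "a", subject_class = "X",
    percent_identity = 50, bitscore = 10))
  expect_error(taxonomic_consistency_filter(cand, community, bad), "malformed")
})

test_that("coverage congruence counts aberrant samples against the MAG's own spread", {
  set.seed(89)
  scafs <- stats::setNames(replicate(4, random_dna(500)), paste0("cs", 1:4))
  community <- simple_community(scafs)
  samples <- sprintf("s%02d", 1:12)
  env <- rep(c("creek", "endolithic", "soil"), each = 4)
  base <- data.table::CJ(sample_id = samples, scaffold_id = paste0("cs", 1:4))
  base[, sample_environment := env[match(sample_id, samples)]]
  base[, mean_depth := 10]
  base[, scaffold_length := 500L]
  cand <- make_candidates(data.table::data.table(
    candidate_id = "cv", recipient_mag = "m1", recipient_group = "Alpha",
    scaffold_id = "cs1", start = 0L, end = 200L, donor_group = "Beta"))

  depth_with <- function(n_aberrant) {
    d <- data.table::copy(base)
    d[scaffold_id == "cs1" & sample_id %in% samples[seq_len(n_aberrant)],
      mean_depth := 50]   # |50 - 20| = 30 > sd 20 => aberrant
    hgtweave:::as_depth_table(
      d[, list(sample_id, sample_environment, scaffold_id, mean_depth, scaffold_length)])
  }
  r0 <- coverage_congruence_filter(cand, community, depth_with(0))
  expect_equal(r0$decisions$status, "pass")
  expect_match(r0$decisions$detail, "aberrant in 0 of 12")
  r2 <- coverage_congruence_filter(cand, community, depth_with(2))
  expect_equal(r2$decisions$status, "flag")
  expect_equal(nrow(r2$survivors), 1L)
  r3 <- coverage_congruence_filter(cand, community, depth_with(3))
  expect_equal(r3$decisions$status, "discard")
  expect_equal(nrow(r3$survivors), 0L)

  # scaffold absent from the depth table passes with a flag
  no_rows <- hgtweave:::as_depth_table(
    base[scaffold_id != "cs1",
         list(sample_id, sample_environment, scaffold_id, mean_depth, scaffold_length)])
  rn <- coverage_congruence_filter(cand, community, no_rows)
  expect_equal(rn$decisions$detail, "no-coverage-data")
  expect_equal(nrow(rn$survivors), 1L)
})

test_that("eukaryote recipients are judged only in their own environment's samples", {
  set.seed(91)
  community <- list(
    alga = mag_record("alga", "Cyanidio1", "Eukaryota", environment = "soil",
                      scaffolds = stats::setNames(replicate(3, random_dna(400)),
                                                  paste0("es", 1:3))),
    other = mag_record("other", "Beta", "Bacteria",
                       scaffolds = c(os1 = random_dna(400))))
  samples <- sprintf("s%02d", 1:12)
  env <- rep(c("creek", "endolithic", "soil"), each = 4)
  d <- data.table::CJ(sample_id = samples, scaffold_id = paste0("es", 1:3))
  d[, sample_environment := env[match(sample_id, samples)]]
  d[, mean_depth := 10]
  d[, scaffold_length := 400L]
  # wildly aberrant in all 8 non-soil samples; congruent in the 4 soil ones
  d[scaffold_id == "es1" & sample_environment != "soil", mean_depth := 99]
  depths <- hgtweave:::as_depth_table(
    d[, list(sample_id, sample_environment, scaffold_id, mean_depth, scaffold_length)])
  cand <- make_candidates(data.table::data.table(
    candidate_id = "ec", recipient_mag = "alga", recipient_group = "Cyanidio1",
    scaffold_id = "es1", start = 0L, end = 150L, donor_group = "Beta"))
  res <- coverage_congruence_filter(cand, community, depths)
  expect_equal(res$decisions$status, "pass")
  expect_match(res$decisions$detail, "0 of 4")
})

test_that("GC annotation excludes N and never filters", {
  community <- simple_community(c(gcs = "GGCCATATGCNN"))
  cand <- make_candidates(data.table::data.table(
    candidate_id = c("g1", "g2", "g3"),
    recipient_mag = "m1", recipient_group = "Alpha", scaffold_id = "gcs",
    start = c(0L, 4L, 8L), end = c(4L, 8L, 12L), donor_group = "Beta"))
  ann <- annotate_gc(cand, community)
  expect_equal(ann$gc_region, c(1.0, 0.0, 1.0))
  expect_equal(nrow(ann), 3L)
  # all-N region -> missing
  community2 <- simple_community(c(gcs = "NNNNACGT"))
  cand2 <- make_candidates(data.table::data.table(
    candidate_id = "gn", recipient_mag = "m1", recipient_group = "Alpha",
    scaffold_id = "gcs", start = 0L, end = 4L, donor_group = "Beta"))
  expect_true(is.na(annotate_gc(cand2, community2)$gc_region))
})

test_that("coding classification splits candidates by region hits", {
  cand <- make_candidates(data.table::data.table(
    candidate_id = sprintf("r%02d", 1:39),
    recipient_mag = "m1", recipient_group = "Alpha", scaffold_id = "s1",
    start = 0L, end = 150L, donor_group = "Beta"))
  hom <- hgtweave:::as_homology_table(data.table::data.table(
    query_id = paste0(sprintf("r%02d", 1:17), ".region"),
    subject_accession = sprintf("P%02d", 1:17),
    subject_class = "SomeClass", percent_identity = 70, bitscore = 120))
  cls <- classify_coding(cand, hom)
  expect_equal(sum(cls$coding_status == "coding"), 17L)
  expect_equal(sum(cls$coding_status == "non_coding"), 22L)
  expect_equal(cls$hit_accession[1], "P01")
  expect_true(all(is.na(cls$hit_accession[cls$coding_status == "non_coding"])))
})

test_that("the funnel runs steps in order, skips on missing evidence, and is deterministic", {
  fx <- make_funnel_fixture()
  res <- run_funnel(fx$candidates, fx$community, depths = fx$depths,
                    homology = fx$homology)
  expect_equal(res$funnel$survivors, fx$expected_funnel)
  expect_identical(sort(res$candidates$candidate_id), fx$expected_survivors)
  # funnel monotone
  expect_false(is.unsorted(rev(res$funnel$survivors)))
  # discarded candidates have no decisions at later steps
  disc <- res$decisions[status == "discard"]
  for (i in seq_len(nrow(disc))) {
    later <- res$decisions[candidate_id == disc$candidate_id[i]]
    expect_equal(which(FUNNEL_STEPS == disc$step[i]),
                 max(match(later$step, FUNNEL_STEPS)))
  }
  # byte-identical on re-run
  res2 <- run_funnel(fx$candidates, fx$community, depths = fx$depths,
                     homology = fx$homology)
  expect_identical(res$decisions, res2$decisions)

  # missing evidence skips the dependent steps with a funnel note
  expect_warning(
    expect_warning(res3 <- run_funnel(fx$candidates, fx$community),
                   "homology"),
    "depth")
  expect_equal(res3$funnel[step == "taxonomic_consistency", note], "skipped")
  expect_equal(res3$funnel[step == "coverage_congruence", note], "skipped")

  # empty candidate list: all-zero funnel, no error
  res0 <- run_funnel(fx$candidates[0], fx$community, depths = fx$depths,
                     homology = fx$homology)
  expect_true(all(res0$funnel$survivors == 0L))

  # reordering refused
  expect_error(run_funnel(fx$candidates, fx$community,
                          steps = rev(FUNNEL_STEPS)), "allow_reorder")
})

test_that("each filter is idempotent", {
  fx <- make_funnel_fixture()
  once <- filter_min_length(fx$candidates)
  twice <- filter_min_length(once$survivors)
  expect_identical(as.data.frame(once$survivors), as.data.frame(twice$survivors))
  o2 <- filter_repeat_and_n(fx$candidates, fx$community)
  t2 <- filter_repeat_and_n(o2$survivors, fx$community)
  expect_identical(as.data.frame(o2$survivors), as.data.frame(t2$survivors))
  o3 <- coverage_congruence_filter(fx$candidates, fx$community, fx$depths)
  t3 <- coverage_congruence_filter(o3$survivors, fx$community, fx$depths)
  expect_identical(as.data.frame(o3$survivors), as.data.frame(t3$survivors))
})
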