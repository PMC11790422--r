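# Shared designed fixtures built in code.

make_candidates <- function(df) {
  dt <- data.table::as.data.table(df)
  dt[, length := end - start]
  if (!"n_flagged_kmers" %in% names(dt)) dt[, n_flagged_kmers := pmax(1L, length - 24L)]
  if (!"score" %in% names(dt)) dt[, score := 0.01]
  if (!"p_value" %in% names(dt)) dt[, p_value := 1e-6]
  dt
}

# 10-candidate community where each funnel step removes exactly one
# designated candidate: c01 virus-to-virus, c02 too short, c03 saturates
# its scaffold, c04 sits on a repeat-heavy scaffold, c05 has a donor-like
# flanking top hit, c06 has aberrant coverage in 3 samples; c07-c10 pass.
make_funnel_fixture <- function() {
  set.seed(97)
  community <- list(
    magV1 = mag_record("magV1", "VgrpA", "Virus",
                       scaffolds = c(sV1 = random_dna(500))),
    magV2 = mag_record("magV2", "VgrpB", "Virus",
                       scaffolds = c(sV2 = random_dna(1000))),
    magA1 = mag_record("magA1", "Alpha", "Bacteria", scaffolds = c(
      sA1 = random_dna(2000),
      sA2 = random_dna(500),
      sA3 = paste0(strrep("AC", 300), random_dna(400)),
      sA4 = random_dna(2000),
      sA5 = random_dna(2000),
      sA6 = random_dna(2000))),
    magB1 = mag_record("magB1", "Beta", "Bacteria",
                       scaffolds = c(sB1 = random_dna(1000))))

  candidates <- make_candidates(data.table::data.table(
    candidate_id = sprintf("c%02d", 1:10),
    recipient_mag = c("magV2", rep("magA1", 9)),
    recipient_group = c("VgrpB", rep("Alpha", 9)),
    scaffold_id = c("sV2", "sA1", "sA2", "sA3", "sA4", "sA5",
                    "sA1", "sA1", "sA6", "sA6"),
    start = c(0L, 0L, 5L, 650L, 0L, 0L, 100L, 400L, 0L, 1000L),
    end = c(200L, 99L, 495L, 800L, 200L, 150L, 300L, 550L, 946L, 1100L),
    donor_group = c("VgrpA", rep("Beta", 9))))

  samples <- data.table::data.table(
    sample_id = sprintf("s%02d", 1:12),
    sample_environment = rep(c("creek", "endolithic", "soil"), each = 4L))
  rows <- data.table::CJ(sample_id = samples$sample_id,
                         scaffold_id = sprintf("sA%d", 1:6))
  rows <- merge(rows, samples, by = "sample_id")
  rows[, mean_depth := 10]
  rows[scaffold_id == "sA5" & sample_id %in% c("s01", "s02", "s03"),
       mean_depth := 50]
  rows[, scaffold_length := 2000L]
  rows[scaffold_id == "sA2", scaffold_length := 500L]
  rows[scaffold_id == "sA3", scaffold_length := 1000L]
  depths <- hgtweave:::as_depth_table(
    rows[, list(sample_id, sample_environment, scaffold_id, mean_depth, scaffold_length)])

  hom <- data.table::data.table(
    query_id = paste0(sprintf("c%02d", 5:10), ".nonhgt"),
    subject_accession = sprintf("ACC%02d", 5:10),
    subject_class = c("Beta", rep("Alpha", 5)),
    percent_identity = 80, bitscore = 150)
  homology <- hgtweave:::as_homology_table(hom)

  list(community = community, candidates = candidates, depths = depths,
       homology = homology,
       expected_survivors = sprintf("c%02d", 7:10),
       expected_funnel = c(10L, 9L, 8L, 7L, 6L, 5L, 4L))
}
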