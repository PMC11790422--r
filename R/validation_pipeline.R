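# Candidate validation funnel. Six steps applied in fixed order, each
# producing per-candidate decisions (pass / flag / discard) so the whole
# trace is auditable:
#   virus_overlap -> min_length -> scaffold_saturation -> repeat_n_content
#   -> taxonomic_consistency -> coverage_congruence
# Boundary semantics are strict as published: "< 100 bp discarded" (100
# passes), "> 95% discarded" (95.0% passes), "> 50% removed" (50.0%
# passes), "> 2 aberrant samples discarded" (2 passes with a flag).

#' Canonical validation-funnel step order
#'
#' The fixed order in which [run_funnel()] applies the validation steps.
#' @export
FUNNEL_STEPS <- c("virus_overlap", "min_length", "scaffold_saturation",
                  "repeat_n_content", "taxonomic_consistency",
                  "coverage_congruence")

make_decisions <- function(candidate_id, step, status, detail) {
  data.table::data.table(candidate_id = candidate_id, step = step,
                         status = status, detail = detail)
}

split_survivors <- function(candidates, decisions) {
  drop <- decisions[status == "discard", candidate_id]
  list(survivors = candidates[!candidates$candidate_id %in% drop],
       decisions = decisions)
}

group_domain_map <- function(community) {
  cs <- community_summary(community)
  dm <- unique(cs[, list(group, domain)])
  conflicting <- dm[, .N, by = group][N > 1L]
  if (nrow(conflicting)) {
    stop("group with conflicting domains: ", conflicting$group[1L], call. = FALSE)
  }
  stats::setNames(dm$domain, dm$group)
}

#' Remove viral/cellular catalogue overlap and virus-to-virus calls
#'
#' Discards candidates whose donor and recipient groups are both viral
#' (taxonomy inside viral bins is too imprecise to exclude homology-driven
#' false positives) and candidates sitting on a scaffold id present in both
#' a viral and a cellular MAG (an artefact of independently binned
#' catalogues).
#'
#' @param candidates candidate table ([call_candidate_hgts()]).
#' @param community named list of [mag_record()] objects.
#' @return list with `survivors` and `decisions`.
#' @export
remove_cross_catalogue_overlap <- function(candidates, community) {
  gd <- group_domain_map(community)
  lens <- scaffold_length_table(community)
  dom_by_scaffold <- lens[, list(n_dom = data.table::uniqueN(domain),
                                 viral = any(domain == "Virus"),
                                 cellular = any(domain != "Virus")),
                          by = scaffold_id]
  overlap_ids <- dom_by_scaffold[viral & cellular, scaffold_id]
  don_dom <- gd[candidates$donor_group]
  rec_dom <- gd[candidates$recipient_group]
  vv <- don_dom == "Virus" & rec_dom == "Virus"
  xcat <- candidates$scaffold_id %in% overlap_ids
  status <- ifelse(vv | xcat, "discard", "pass")
  detail <- ifelse(vv, "virus-to-virus",
                   ifelse(xcat, "catalogue overlap", "ok"))
  split_survivors(candidates,
                  make_decisions(candidates$candidate_id, "virus_overlap", status, detail))
}

#' Discard candidates shorter than the minimum length
#'
#' Events shorter than `min_length_bp` (default 100 bp) carry too few
#' supporting k-mers; exactly 100 bp passes.
#'
#' @inheritParams remove_cross_catalogue_overlap
#' @param params [pipeline_params()].
#' @return list with `survivors` and `decisions`.
#' @export
filter_min_length <- function(candidates, params = pipeline_params()) {
  keep <- candidates$length >= params$min_length_bp
  split_survivors(candidates, make_decisions(
    candidates$candidate_id, "min_length",
    ifelse(keep, "pass", "discard"),
    sprintf("length %d vs min %d", candidates$length, params$min_length_bp)))
}

#' Discard candidates saturating their scaffold
#'
#' Candidates covering more than `max_scaffold_fraction` (default 95%) of
#' their scaffold leave too little flanking sequence to anchor the scaffold
#' to its MAG; exactly 95% passes.
#'
#' @inheritParams filter_min_length
#' @param community named list of [mag_record()] objects.
#' @return list with `survivors` and `decisions`.
#' @export
filter_scaffold_saturation <- function(candidates, community,
                                       params = pipeline_params()) {
  lens <- scaffold_length_table(community)
  idx <- match(candidates$scaffold_id, lens$scaffold_id)
  if (anyNA(idx)) {
    stop("candidate scaffold absent from community: ",
         candidates$scaffold_id[which(is.na(idx))[1L]], call. = FALSE)
  }
  frac <- candidates$length / lens$scaffold_length[idx]
  keep <- frac <= params$max_scaffold_fraction
  split_survivors(candidates, make_decisions(
    candidates$candidate_id, "scaffold_saturation",
    ifelse(keep, "pass", "discard"),
    sprintf("saturation %.4f vs max %.2f", frac, params$max_scaffold_fraction)))
}

#' Detect simple tandem repeats in a sequence
#'
#' Built-in simple-repeat finder: reports every maximal interval that
#' consists of at least `min_copies` exact tandem copies of a motif of
#' `min_motif`..`max_motif` bp and spans at least `min_span` bp. Overlapping
#' reports (e.g. the same array seen at period 2 and 4) are unioned. `N`
#' positions never match. An external RepeatMasker-derived mask, when
#' available, is preferred by [filter_repeat_and_n()].
#'
#' @param seq a single sequence over `{A,C,G,T,N}`.
#' @param min_motif,max_motif motif length range in bp (defaults 1 and 6).
#' @param min_span minimal repeat-array span in bp (default 12).
#' @param min_copies minimal number of complete motif copies (default 3).
#' @return data.table `(start, end)` of disjoint 0-based half-open intervals.
#' @export
detect_simple_repeats <- function(seq, min_motif = 1L, max_motif = 6L,
                                  min_span = 12L, min_copies = 3L) {
  L <- nchar(seq)
  starts <- integer(0); ends <- integer(0)
  if (L >= min_span) {
    b <- charToRaw(seq)
    rawN <- charToRaw("N")
    for (m in seq.int(min_motif, max_motif)) {
      if (L <= m) break
      same <- b[seq_len(L - m)] == b[seq.int(m + 1L, L)] & b[seq_len(L - m)] != rawN
      r <- rle(same)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      ok <- r$values & (r$lengths + m >= min_span) &
        (r$lengths >= (min_copies - 1L) * m)
      if (any(ok)) {
        starts <- c(starts, run_start[ok] - 1L)           # 0-based
        ends <- c(ends, run_start[ok] - 1L + r$lengths[ok] + m)
      }
    }
  }
  interval_union(starts, ends)
}

scaffold_mask_fraction <- function(scaffold_id, seq, mask = NULL) {
  if (!is.null(mask)) {
    iv <- mask[mask$scaffold_id == scaffold_id]
    iv <- interval_union(iv$start, iv$end)
  } else {
    iv <- detect_simple_repeats(seq)
  }
  sum(iv$end - iv$start) / nchar(seq)
}

#' Discard candidates on repeat-heavy or N-heavy scaffolds
#'
#' Computes, on the *whole scaffold* (not the candidate region), the
#' fraction covered by simple repeats (external mask if supplied, else the
#' built-in [detect_simple_repeats()]) and the fraction of `N` characters;
#' discards when either exceeds 50%. Simple repeats occur in unrelated
#' species without transfer, and N-rich scaffolds are dominated by joins
#' rather than sequence, so neither can support a transfer call.
#'
#' @inheritParams filter_scaffold_saturation
#' @param mask optional `repeat_mask` from [read_repeat_mask()].
#' @return list with `survivors` and `decisions`.
#' @export
filter_repeat_and_n <- function(candidates, community, mask = NULL,
                                params = pipeline_params()) {
  mag_of <- scaffold_length_table(community)
  uniq <- unique(data.table::data.table(mag_id = candidates$recipient_mag,
                                        scaffold_id = candidates$scaffold_id))
  uniq[, seq := mapply(function(m, s) get_scaffold_seq(community, m, s),
                       mag_id, scaffold_id)]
  uniq[, rep_frac := mapply(function(s, sq) scaffold_mask_fraction(s, sq, mask),
                            scaffold_id, seq)]
  uniq[, n_frac := stringi::stri_count_fixed(seq, "N") / nchar(seq)]
  idx <- match(paste(candidates$recipient_mag, candidates$scaffold_id),
               paste(uniq$mag_id, uniq$scaffold_id))
  rep_frac <- uniq$rep_frac[idx]
  n_frac <- uniq$n_frac[idx]
  bad_rep <- rep_frac > params$max_repeat_fraction
  bad_n <- n_frac > params$max_n_fraction
  status <- ifelse(bad_rep | bad_n, "discard", "pass")
  split_survivors(candidates, make_decisions(
    candidates$candidate_id, "repeat_n_content", status,
    sprintf("repeat_fraction %.4f, n_fraction %.4f vs max %.2f/%.2f",
            rep_frac, n_frac, params$max_repeat_fraction, params$max_n_fraction)))
}

#' Top-hit taxonomic consistency filter
#'
#' Uses homology hits of each candidate's flanking non-transferred scaffold
#' region (query ids `<candidate_id>.nonhgt`). If the top hit's class
#' matches the recipient's class the scaffold is confirmed in place and the
#' candidate passes; if it matches the donor's class the scaffold itself
#' looks foreign (mis-binned or chimeric) and the candidate is discarded.
#' Candidates with no hits pass with a `no-hit` flag: their provenance
#' cannot be assessed, and missing evidence never silently discards.
#' Ambiguous top hits (another class, or unknown) pass with a flag in
#' `lenient` mode (the default, avoiding over-filtering of under-sampled
#' taxa) and are discarded in `strict` mode.
#'
#' @inheritParams filter_scaffold_saturation
#' @param homology a `homology_table` ([read_homology_table()]).
#' @param mode `"lenient"` (default) or `"strict"`.
#' @return list with `survivors` and `decisions`.
#' @export
taxonomic_consistency_filter <- function(candidates, community, homology,
                                         mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  hom <- data.table::as.data.table(homology)
  # malformed query ids: a query naming a known candidate without the
  # .nonhgt/.region convention cannot be attributed to a flank or region
  base <- sub("\\.(nonhgt|region)$", "", unique(hom$query_id))
  malformed <- unique(hom$query_id)[
    base %in% candidates$candidate_id &
      !grepl("\\.(nonhgt|region)$", unique(hom$query_id))]
  if (length(malformed)) {
    stop("malformed homology query id (expected <candidate_id>.nonhgt): ",
         malformed[1L], call. = FALSE)
  }
  top <- hom[rank == 1L & grepl("\\.nonhgt$", query_id)]
  top[, candidate_id := sub("\\.nonhgt$", "", query_id)]
  idx <- match(candidates$candidate_id, top$candidate_id)
  top_class <- top$subject_class[idx]
  status <- character(nrow(candidates))
  detail <- character(nrow(candidates))
  no_hit <- is.na(top_class)
  status[no_hit] <- "flag"; detail[no_hit] <- "no-hit"
  consistent <- !no_hit & top_class == candidates$recipient_group
  status[consistent] <- "pass"
  detail[consistent] <- "top hit matches recipient class"
  donor_like <- !no_hit & top_class == candidates$donor_group
  status[donor_like] <- "discard"
  detail[donor_like] <- "top hit matches donor class"
  other <- !no_hit & !consistent & !donor_like
  status[other] <- if (mode == "lenient") "flag" else "discard"
  detail[other] <- sprintf("ambiguous top hit class '%s' (%s mode)",
                           top_class[other], mode)
  split_survivors(candidates, make_decisions(
    candidates$candidate_id, "taxonomic_consistency", status, detail))
}

#' Per-(MAG, sample) coverage statistics
#'
#' Mean and standard deviation of per-scaffold mean depths of each MAG in
#' each sample, treating scaffolds as the sampling unit (unweighted by
#' scaffold length), consistent with assuming scaffold coverages within a
#' MAG are normally distributed.
#'
#' @param depths a `depth_table` ([read_depth_table()]).
#' @param community named list of [mag_record()] objects.
#' @return data.table `(mag_id, sample_id, sample_environment, mag_mean,
#'   mag_sd, n_scaffolds)`.
#' @export
coverage_stats <- function(depths, community) {
  lens <- scaffold_length_table(community)
  d <- merge(data.table::as.data.table(depths),
             lens[, list(scaffold_id, mag_id)], by = "scaffold_id",
             allow.cartesian = TRUE)
  st <- d[, list(mag_mean = mean(mean_depth),
                 mag_sd = if (.N > 1L) stats::sd(mean_depth) else 0,
                 n_scaffolds = .N),
          by = list(mag_id, sample_id, sample_environment)]
  st[]
}

#' Coverage-congruence filter
#'
#' A correctly binned scaffold should track its MAG's depth across samples.
#' For each candidate, every relevant sample in which the scaffold's mean
#' depth lies more than `sd_multiplier` standard deviations from its MAG's
#' mean is counted as aberrant; more than `max_aberrant_samples` (default
#' 2) aberrant samples discard the candidate, 1-2 pass with a flag (to be
#' scrutinised downstream), 0 pass clean. Relevant samples are all samples
#' for prokaryote and virus recipients; for eukaryote recipients only
#' samples whose environment matches the MAG's (eukaryote MAGs are
#' assembled and mapped per environment, so cross-environment depths are
#' not comparable). Candidates whose scaffold has no depth rows pass with a
#' `no-coverage-data` flag.
#'
#' @inheritParams filter_scaffold_saturation
#' @param depths a `depth_table`.
#' @return list with `survivors` and `decisions`.
#' @export
coverage_congruence_filter <- function(candidates, community, depths,
                                       params = pipeline_params()) {
  stats_tbl <- coverage_stats(depths, community)
  d <- data.table::as.data.table(depths)
  n <- nrow(candidates)
  status <- character(n); detail <- character(n)
  for (i in seq_len(n)) {
    mag <- community[[candidates$recipient_mag[i]]]
    rows <- d[scaffold_id == candidates$scaffold_id[i]]
    ms <- stats_tbl[mag_id == mag$mag_id]
    if (mag$domain == "Eukaryota") {
      rows <- rows[sample_environment == mag$environment]
      ms <- ms[sample_environment == mag$environment]
    }
    rows <- merge(rows, ms[, list(sample_id, mag_mean, mag_sd)], by = "sample_id")
    if (nrow(rows) == 0L) {
      status[i] <- "flag"; detail[i] <- "no-coverage-data"
      next
    }
    aberrant <- abs(rows$mean_depth - rows$mag_mean) >
      params$sd_multiplier * rows$mag_sd
    n_ab <- sum(aberrant)
    if (n_ab > params$max_aberrant_samples) {
      status[i] <- "discard"
    } else if (n_ab > 0L) {
      status[i] <- "flag"
    } else {
      status[i] <- "pass"
    }
    detail[i] <- sprintf("aberrant in %d of %d sample(s)", n_ab, nrow(rows))
  }
  split_survivors(candidates, make_decisions(
    candidates$candidate_id, "coverage_congruence", status, detail))
}

#' Annotate candidates with GC content
#'
#' GC fraction over unambiguous bases (`N` excluded from the denominator)
#' of the candidate region and of its whole recipient MAG, plus their
#' difference. Annotation only -- GC never filters.
#'
#' @inheritParams filter_scaffold_saturation
#' @return the candidate table with `gc_region`, `gc_mag`, `delta_gc` added
#'   (`NA` when the region has no unambiguous base).
#' @export
annotate_gc <- function(candidates, community) {
  out <- data.table::copy(data.table::as.data.table(candidates))
  mag_gc <- vapply(community, function(m) gc_fraction(paste(m$scaffolds, collapse = "")), 0)
  out[, gc_region := vapply(seq_len(.N), function(i) {
    seq <- get_scaffold_seq(community, recipient_mag[i], scaffold_id[i])
    gc_fraction(substring(seq, start[i] + 1L, end[i]))
  }, 0)]
  out[, gc_mag := mag_gc[recipient_mag]]
  out[, delta_gc := gc_region - gc_mag]
  out[]
}

#' Classify candidates as putatively coding or non-coding
#'
#' Uses homology hits of the transferred region itself (query ids
#' `<candidate_id>.region`): any hit makes the candidate putatively
#' protein-coding (best hit's class, accession and percent identity are
#' attached); no hit, or absence from the table, makes it non-coding on the
#' available evidence.
#'
#' @param candidates candidate table.
#' @param homology a `homology_table`.
#' @return candidate table with `coding_status`, `hit_class`,
#'   `hit_accession`, `hit_percent_identity` columns added.
#' @export
classify_coding <- function(candidates, homology) {
  out <- data.table::copy(data.table::as.data.table(candidates))
  hom <- data.table::as.data.table(homology)
  top <- hom[rank == 1L & grepl("\\.region$", query_id)]
  top[, candidate_id := sub("\\.region$", "", query_id)]
  idx <- match(out$candidate_id, top$candidate_id)
  out[, coding_status := ifelse(is.na(idx), "non_coding", "coding")]
  out[, hit_class := top$subject_class[idx]]
  out[, hit_accession := top$subject_accession[idx]]
  out[, hit_percent_identity := top$percent_identity[idx]]
  out[]
}

#' Run the full validation funnel
#'
#' Applies the six validation steps in their fixed order and records, after
#' each, the surviving candidate count. Steps whose required evidence is
#' missing (`homology` for taxonomic consistency, `depths` for coverage
#' congruence) are skipped with a warning and a funnel row marked
#' `skipped`. The step order is part of the method; passing a reordered
#' `steps` vector without `allow_reorder = TRUE` is an error.
#'
#' @inheritParams filter_scaffold_saturation
#' @param depths optional `depth_table`.
#' @param homology optional `homology_table` with `<candidate_id>.nonhgt`
#'   queries.
#' @param mask optional `repeat_mask`.
#' @param mode taxonomic-consistency mode, `"lenient"` or `"strict"`.
#' @param steps character vector of steps to run, default all six in order.
#' @param allow_reorder permit a non-canonical step order.
#' @return list with `candidates` (final survivors, with `status` `pass` or
#'   `flag`), `funnel` (a `filter_funnel` table: step, survivors, note) and
#'   `decisions` (all per-step decisions).
#' @export
run_funnel <- function(candidates, community, depths = NULL, homology = NULL,
                       mask = NULL, params = pipeline_params(),
                       mode = c("lenient", "strict"),
                       steps = FUNNEL_STEPS, allow_reorder = FALSE) {
  mode <- match.arg(mode)
  if (!all(steps %in% FUNNEL_STEPS)) {
    stop("unknown funnel step: ", setdiff(steps, FUNNEL_STEPS)[1L], call. = FALSE)
  }
  if (!identical(steps, FUNNEL_STEPS[FUNNEL_STEPS %in% steps]) && !allow_reorder) {
    stop("funnel step order is part of the method; pass allow_reorder = TRUE to override",
         call. = FALSE)
  }
  cur <- data.table::as.data.table(candidates)
  funnel <- data.table::data.table(step = "raw", survivors = nrow(cur),
                                   note = NA_character_)
  decisions <- list()
  for (st in steps) {
    skipped <- FALSE
    res <- NULL
    if (st == "virus_overlap") {
      res <- remove_cross_catalogue_overlap(cur, community)
    } else if (st == "min_length") {
      res <- filter_min_length(cur, params)
    } else if (st == "scaffold_saturation") {
      res <- filter_scaffold_saturation(cur, community, params)
    } else if (st == "repeat_n_content") {
      res <- filter_repeat_and_n(cur, community, mask, params)
    } else if (st == "taxonomic_consistency") {
      if (is.null(homology)) {
        warning("no homology table; skipping taxonomic_consistency", call. = FALSE)
        skipped <- TRUE
      } else {
        res <- taxonomic_consistency_filter(cur, community, homology, mode)
      }
    } else if (st == "coverage_congruence") {
      if (is.null(depths)) {
        warning("no depth table; skipping coverage_congruence", call. = FALSE)
        skipped <- TRUE
      } else {
        res <- coverage_congruence_filter(cur, community, depths, params)
      }
    }
    if (skipped) {
      funnel <- rbind(funnel, data.table::data.table(
        step = st, survivors = nrow(cur), note = "skipped"))
      next
    }
    cur <- res$survivors
    decisions[[length(decisions) + 1L]] <- res$decisions
    funnel <- rbind(funnel, data.table::data.table(
      step = st, survivors = nrow(cur), note = NA_character_))
  }
  decisions <- if (length(decisions)) {
    data.table::rbindlist(decisions)
  } else {
    make_decisions(character(0), character(0), character(0), character(0))
  }
  flagged <- unique(decisions[status == "flag", candidate_id])
  cur <- data.table::copy(cur)
  if (nrow(cur)) {
    cur[, status := ifelse(candidate_id %in% flagged, "flag", "pass")]
  } else {
    cur[, status := character(0)]
  }
  data.table::setattr(funnel, "class", c("filter_funnel", class(data.table::data.table())))
  list(candidates = cur, funnel = funnel, decisions = decisions)
}
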