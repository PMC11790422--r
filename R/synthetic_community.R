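# Seeded synthetic MAG communities with planted transfer events, decoy
# scaffolds, depth tables and homology tables. The generator emulates the
# structure that makes TF-IDF detection possible: groups drawn from
# independent random ancestors (hence essentially disjoint k-mer content),
# members diverged from their group ancestor by i.i.d. substitutions, and
# donor fragments copied verbatim into recipient scaffolds.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults mirror the study design at desk scale: 6 taxonomic groups of 4
#' MAGs, 5 scaffolds of 20 kb per MAG (100 kb per MAG, 2.4 Mb community),
#' 2% within-group divergence, 20 planted events of 150-1000 bp, and a
#' 12-sample (4 creek biofilm, 4 endolithic, 4 soil) depth design.
#'
#' @param seed integer RNG seed; every generator is fully deterministic
#'   under it.
#' @param n_groups number of taxonomic groups (default 6).
#' @param mags_per_group MAGs per group (default 4).
#' @param scaffolds_per_mag scaffolds per MAG (default 5).
#' @param scaffold_len_bp scaffold length in bp (default 20000).
#' @param within_group_divergence per-site substitution probability between
#'   a group ancestor and each member (default 0.02; must be in [0, 0.25]).
#' @param n_events number of planted donor-to-recipient events (default 20).
#' @param event_len_range planted fragment length range in bp (default
#'   c(150, 1000); minimum 100).
#' @param n_repeat_decoys,n_n_decoys number of repeat-heavy / N-heavy decoy
#'   scaffolds added by [plant_decoys()] (defaults 0).
#' @param decoy_len_bp decoy scaffold length (default 2000).
#' @param n_contaminant_scaffolds number of scaffolds given incongruent
#'   depth by [simulate_depths()] (default 0).
#' @param depth_mean_range range of per-(MAG, sample) base depths (default
#'   c(10, 60) fold).
#' @param depth_sd per-scaffold depth standard deviation around the MAG
#'   base (default 2 fold).
#' @param contaminant_depth_shift depth offset applied to contaminant
#'   scaffolds in the shifted samples (default 20 fold).
#' @param contaminant_n_samples number of samples in which a contaminant is
#'   shifted (default 4, i.e. more than the 2-sample tolerance).
#' @param group_domains optional character vector of length `n_groups`
#'   giving each group's domain (default all `Bacteria`).
#' @param group_environments optional character vector of length `n_groups`
#'   giving each group's environment label (default `none`).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_groups = 6L, mags_per_group = 4L,
                       scaffolds_per_mag = 5L, scaffold_len_bp = 20000L,
                       within_group_divergence = 0.02, n_events = 20L,
                       event_len_range = c(150L, 1000L),
                       n_repeat_decoys = 0L, n_n_decoys = 0L,
                       decoy_len_bp = 2000L, n_contaminant_scaffolds = 0L,
                       depth_mean_range = c(10, 60), depth_sd = 2,
                       contaminant_depth_shift = 20, contaminant_n_samples = 4L,
                       group_domains = NULL, group_environments = NULL) {
  stopifnot(n_groups >= 2L, mags_per_group >= 1L, scaffolds_per_mag >= 1L,
            scaffold_len_bp >= 100L,
            within_group_divergence >= 0, within_group_divergence <= 0.25,
            n_events >= 0L, length(event_len_range) == 2L,
            event_len_range[1L] >= 100L,
            event_len_range[1L] <= event_len_range[2L],
            depth_sd > 0)
  if (is.null(group_domains)) group_domains <- rep("Bacteria", n_groups)
  if (is.null(group_environments)) group_environments <- rep("none", n_groups)
  stopifnot(length(group_domains) == n_groups,
            all(group_domains %in% DOMAINS),
            length(group_environments) == n_groups,
            all(group_environments %in% ENVIRONMENTS))
  structure(
    list(seed = as.integer(seed), n_groups = as.integer(n_groups),
         mags_per_group = as.integer(mags_per_group),
         scaffolds_per_mag = as.integer(scaffolds_per_mag),
         scaffold_len_bp = as.integer(scaffold_len_bp),
         within_group_divergence = within_group_divergence,
         n_events = as.integer(n_events),
         event_len_range = as.integer(event_len_range),
         n_repeat_decoys = as.integer(n_repeat_decoys),
         n_n_decoys = as.integer(n_n_decoys),
         decoy_len_bp = as.integer(decoy_len_bp),
         n_contaminant_scaffolds = as.integer(n_contaminant_scaffolds),
         depth_mean_range = depth_mean_range, depth_sd = depth_sd,
         contaminant_depth_shift = contaminant_depth_shift,
         contaminant_n_samples = as.integer(contaminant_n_samples),
         group_domains = group_domains,
         group_environments = group_environments),
    class = "sim_config"
  )
}

with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

int_to_seq <- function(v) paste(BASES[v], collapse = "")

#' Simulate a MAG community with planted transfer events
#'
#' Each group gets an ancestor drawn i.i.d. uniform over `{A,C,G,T}`; each
#' member MAG is the ancestor with i.i.d. substitutions at the divergence
#' rate, cut into scaffolds. Planted events copy a verbatim segment from a
#' donor MAG (as generated, before any planting) over an equal-length block
#' of a recipient scaffold in a different group, so scaffold lengths are
#' unchanged. Event placements never overlap on a recipient scaffold.
#' Fully deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `community` (named list of [mag_record()]) and `truth`
#'   (data.table of planted events: event_id, donor/recipient MAG, group,
#'   scaffold, interval, length).
#' @export
simulate_community <- function(config = sim_config()) {
  if (config$event_len_range[2L] > config$scaffold_len_bp) {
    stop("event length exceeds scaffold length", call. = FALSE)
  }
  with_sim_seed(config$seed, 0L, {
    gids <- sprintf("class%02d", seq_len(config$n_groups))
    L <- config$scaffold_len_bp
    S <- config$scaffolds_per_mag
    community <- list()
    for (g in seq_len(config$n_groups)) {
      anc <- sample.int(4L, L * S, replace = TRUE)
      for (m in seq_len(config$mags_per_group)) {
        v <- anc
        mut <- which(stats::runif(length(v)) < config$within_group_divergence)
        if (length(mut)) {
          v[mut] <- ((v[mut] - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
        }
        mag_id <- sprintf("mag_%s_%02d", gids[g], m)
        scafs <- vapply(seq_len(S), function(s) {
          int_to_seq(v[seq.int((s - 1L) * L + 1L, s * L)])
        }, "")
        names(scafs) <- sprintf("%s_s%d", mag_id, seq_len(S))
        community[[mag_id]] <- mag_record(
          mag_id = mag_id, group = gids[g],
          domain = config$group_domains[g],
          environment = config$group_environments[g],
          scaffolds = scafs)
      }
    }
    pristine <- community
    truth <- list()
    used <- list()  # per recipient scaffold: planted intervals
    mag_ids <- names(community)
    mag_groups <- vapply(community, `[[`, "", "group")
    for (e in seq_len(config$n_events)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        don_mag <- sample(mag_ids, 1L)
        rec_choices <- mag_ids[mag_groups != mag_groups[[don_mag]]]
        rec_mag <- sample(rec_choices, 1L)
        len <- sample(seq.int(config$event_len_range[1L], config$event_len_range[2L]), 1L)
        don_scaf <- sample(names(pristine[[don_mag]]$scaffolds), 1L)
        rec_scaf <- sample(names(community[[rec_mag]]$scaffolds), 1L)
        don_start <- sample.int(L - len + 1L, 1L) - 1L
        rec_start <- sample.int(L - len + 1L, 1L) - 1L
        prior <- used[[rec_scaf]]
        if (!is.null(prior) &&
            any(interval_overlap_len(rec_start, rec_start + len,
                                     prior$start, prior$end) > 0L)) {
          next
        }
        frag <- substring(pristine[[don_mag]]$scaffolds[[don_scaf]],
                          don_start + 1L, don_start + len)
        seq <- community[[rec_mag]]$scaffolds[[rec_scaf]]
        community[[rec_mag]]$scaffolds[[rec_scaf]] <- paste0(
          substring(seq, 1L, rec_start),
          frag,
          substring(seq, rec_start + len + 1L, nchar(seq)))
        used[[rec_scaf]] <- rbind(
          prior %||% data.table::data.table(start = integer(0), end = integer(0)),
          data.table::data.table(start = rec_start, end = rec_start + len))
        truth[[length(truth) + 1L]] <- data.table::data.table(
          event_id = sprintf("EV%03d", e),
          donor_mag = don_mag, donor_group = mag_groups[[don_mag]],
          donor_scaffold = don_scaf, donor_start = don_start,
          donor_end = don_start + len,
          recipient_mag = rec_mag, recipient_group = mag_groups[[rec_mag]],
          recipient_scaffold = rec_scaf, start = rec_start,
          end = rec_start + len, length = len)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted event ", e, call. = FALSE)
    }
    truth <- if (length(truth)) data.table::rbindlist(truth) else
      data.table::data.table(
        event_id = character(0), donor_mag = character(0),
        donor_group = character(0), donor_scaffold = character(0),
        donor_start = integer(0), donor_end = integer(0),
        recipient_mag = character(0), recipient_group = character(0),
        recipient_scaffold = character(0), start = integer(0),
        end = integer(0), length = integer(0))
    list(community = community, truth = truth)
  })
}

#' Add decoy scaffolds exercising the repeat/N filter
#'
#' Appends, round-robin across existing MAGs, scaffolds that are about 60%
#' a tandem `AC` array (repeat decoys) and scaffolds that are about 60% `N`
#' (N decoys); both exceed the funnel's 50% thresholds. The added scaffold
#' ids are recorded in the `decoy_scaffolds` attribute of the returned
#' community.
#'
#' @param community named list of [mag_record()] objects.
#' @param config a [sim_config()] (uses `n_repeat_decoys`, `n_n_decoys`,
#'   `decoy_len_bp`, `seed`).
#' @return the community with decoy scaffolds added.
#' @export
plant_decoys <- function(community, config = sim_config()) {
  n_rep <- config$n_repeat_decoys
  n_n <- config$n_n_decoys
  if (n_rep + n_n == 0L) return(community)
  with_sim_seed(config$seed, 7919L, {
    L <- config$decoy_len_bp
    rep_len <- as.integer(ceiling(0.6 * L))
    if (rep_len %% 2L == 1L) rep_len <- rep_len + 1L
    mag_ids <- names(community)
    decoys <- character(0)
    add_scaffold <- function(i, id, seq) {
      mag <- mag_ids[((i - 1L) %% length(mag_ids)) + 1L]
      sid <- paste0(mag, "_", id)
      community[[mag]]$scaffolds[[sid]] <<- seq
      decoys <<- c(decoys, sid)
    }
    for (i in seq_len(n_rep)) {
      tail_len <- L - rep_len
      seq <- paste0(strrep("AC", rep_len %/% 2L),
                    int_to_seq(sample.int(4L, tail_len, replace = TRUE)))
      add_scaffold(i, sprintf("decoy_rep%d", i), seq)
    }
    for (i in seq_len(n_n)) {
      n_len <- as.integer(ceiling(0.6 * L))
      seq <- paste0(strrep("N", n_len),
                    int_to_seq(sample.int(4L, L - n_len, replace = TRUE)))
      add_scaffold(n_rep + i, sprintf("decoy_n%d", i), seq)
    }
    attr(community, "decoy_scaffolds") <- decoys
    community
  })
}

#' Simulate a 12-sample depth table
#'
#' Emulates the study's sampling design: 12 samples, 4 per environment
#' (creek, endolithic, soil). Each (MAG, sample) pair draws a base depth
#' uniform over `depth_mean_range`; resident scaffolds get depth
#' `Normal(base, depth_sd)` (truncated at 0). Designated contaminant
#' scaffolds additionally get `contaminant_depth_shift` added in
#' `contaminant_n_samples` samples, so the coverage-congruence filter
#' fires. Eukaryote MAGs receive depth rows only for samples matching
#' their own environment.
#'
#' @param community named list of [mag_record()] objects.
#' @param config a [sim_config()].
#' @return a `depth_table`; contaminant scaffold ids are recorded in its
#'   `contaminant_scaffolds` attribute.
#' @export
simulate_depths <- function(community, config = sim_config()) {
  with_sim_seed(config$seed, 104729L, {
    samples <- data.table::data.table(
      sample_id = sprintf("s%02d", 1:12),
      sample_environment = rep(c("creek", "endolithic", "soil"), each = 4L))
    lens <- scaffold_length_table(community)
    contaminants <- character(0)
    if (config$n_contaminant_scaffolds > 0L) {
      contaminants <- sample(lens$scaffold_id,
                             min(config$n_contaminant_scaffolds, nrow(lens)))
    }
    rows <- list()
    for (m in community) {
      sub <- if (m$domain == "Eukaryota") {
        samples[sample_environment == m$environment]
      } else samples
      if (nrow(sub) == 0L) next
      scafs <- names(m$scaffolds)
      slen <- nchar(m$scaffolds)
      for (j in seq_len(nrow(sub))) {
        base <- stats::runif(1L, config$depth_mean_range[1L], config$depth_mean_range[2L])
        depth <- pmax(0, stats::rnorm(length(scafs), base, config$depth_sd))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          sample_id = sub$sample_id[j],
          sample_environment = sub$sample_environment[j],
          scaffold_id = scafs, mean_depth = depth,
          scaffold_length = as.integer(slen))
      }
    }
    dt <- data.table::rbindlist(rows)
    for (cid in contaminants) {
      shift_samples <- sample(samples$sample_id, config$contaminant_n_samples)
      dt[scaffold_id == cid & sample_id %in% shift_samples,
         mean_depth := mean_depth + config$contaminant_depth_shift]
    }
    dt <- as_depth_table(dt)
    data.table::setattr(dt, "contaminant_scaffolds", contaminants)
    dt
  })
}

#' Simulate a homology table for the taxonomic-consistency filter
#'
#' Emits rank-1 hits for each candidate's flanking-region query
#' (`<candidate_id>.nonhgt`) according to the scenario: `consistent` top
#' hits match the recipient class, `donor_like` the donor class, `no_hit`
#' emits nothing, and `mixed` cycles the three deterministically in
#' candidate order.
#'
#' @param candidates table with `candidate_id`, `recipient_group`,
#'   `donor_group` columns (detector output or truth renamed accordingly).
#' @param scenario `"consistent"`, `"donor_like"`, `"no_hit"` or `"mixed"`.
#' @return a `homology_table`.
#' @export
simulate_homology <- function(candidates,
                              scenario = c("consistent", "donor_like", "no_hit", "mixed")) {
  scenario <- match.arg(scenario)
  n <- nrow(candidates)
  per <- switch(scenario,
                consistent = rep("consistent", n),
                donor_like = rep("donor_like", n),
                no_hit = rep("no_hit", n),
                mixed = rep(c("consistent", "donor_like", "no_hit"), length.out = n))
  keep <- per != "no_hit"
  if (!any(keep)) return(empty_homology_table())
  cls <- ifelse(per == "consistent", candidates$recipient_group,
                candidates$donor_group)
  dt <- data.table::data.table(
    query_id = paste0(candidates$candidate_id[keep], ".nonhgt"),
    subject_accession = sprintf("SIM%06d", which(keep)),
    subject_class = cls[keep],
    percent_identity = 85, bitscore = 200)
  as_homology_table(dt)
}

#' Evaluate recovery of planted events
#'
#' A truth event is recovered when some called region on the same recipient
#' scaffold overlaps it reciprocally by at least `min_overlap`.
#' `donor_accuracy` is the fraction of recovered events whose best
#' recovering call names the true donor group. `precision` is the fraction
#' of called regions at least `min_overlap` of whose own length lies within
#' some truth event on that scaffold (a sub-fragment call inside a true
#' event is correct, not a false positive). With no calls at all precision
#' is reported as 1 with the note `no calls`.
#'
#' @param truth truth table from [simulate_community()].
#' @param called candidate table from [call_candidate_hgts()].
#' @param min_overlap overlap threshold (default 0.5).
#' @return list: `recall`, `precision`, `donor_accuracy`, `mean_overlap`
#'   (mean recovered-overlap fraction of truth length), `n_truth`,
#'   `n_called`, `note`.
#' @export
evaluate_recovery <- function(truth, called, min_overlap = 0.5) {
  truth <- data.table::as.data.table(truth)
  called <- data.table::as.data.table(called)
  n_truth <- nrow(truth); n_called <- nrow(called)
  note <- NA_character_
  if (n_truth == 0L) {
    return(list(recall = NA_real_, precision = if (n_called == 0L) 1 else 0,
                donor_accuracy = NA_real_, mean_overlap = NA_real_,
                n_truth = 0L, n_called = n_called,
                note = "no truth events"))
  }
  recovered <- logical(n_truth)
  donor_ok <- logical(n_truth)
  ovl_frac <- rep(NA_real_, n_truth)
  for (i in seq_len(n_truth)) {
    cc <- called[scaffold_id == truth$recipient_scaffold[i] &
                   recipient_mag == truth$recipient_mag[i]]
    if (nrow(cc) == 0L) next
    ov <- interval_overlap_len(truth$start[i], truth$end[i], cc$start, cc$end)
    rec <- ov >= min_overlap * truth$length[i] & ov >= min_overlap * (cc$end - cc$start)
    if (any(rec)) {
      recovered[i] <- TRUE
      best <- which(rec)[which.max(ov[rec])]
      donor_ok[i] <- cc$donor_group[best] == truth$donor_group[i]
      ovl_frac[i] <- ov[best] / truth$length[i]
    }
  }
  if (n_called == 0L) {
    precision <- 1
    note <- "no calls"
  } else {
    correct <- logical(n_called)
    for (j in seq_len(n_called)) {
      tt <- truth[recipient_scaffold == called$scaffold_id[j] &
                    recipient_mag == called$recipient_mag[j]]
      if (nrow(tt) == 0L) next
      ov <- interval_overlap_len(called$start[j], called$end[j], tt$start, tt$end)
      correct[j] <- any(ov >= min_overlap * (called$end[j] - called$start[j]))
    }
    precision <- mean(correct)
  }
  list(recall = mean(recovered),
       precision = precision,
       donor_accuracy = if (any(recovered)) mean(donor_ok[recovered]) else NA_real_,
       mean_overlap = if (any(recovered)) mean(ovl_frac[recovered]) else NA_real_,
       n_truth = n_truth, n_called = n_called, note = note)
}
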