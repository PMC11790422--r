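# TF-IDF detector core. Taxonomic groups of MAGs are the "documents" and
# canonical k-mers the "words": a k-mer occurrence on a recipient scaffold
# is flagged as foreign when the k-mer is common among the MAGs of another
# (donor) group, absent from the rest of the recipient's own group, and
# confined to few groups overall. Flagged k-mer starts are merged into
# candidate intervals whose significance is bounded by a run-length
# argument under an independent-flags null.
#
# Internally k-mers are packed 2 bits per base (A=0, C=1, G=2, T=3) into
# doubles; with k <= 26 every code is an exact integer below 2^53, and the
# numeric order of codes equals the lexicographic order of the strings, so
# min(code, revcomp code) is the canonical form.

#' Canonical form of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement, making
#' counting strand-independent. Vectorised. k-mers containing `N` are not
#' countable and yield `NA` (callers skip them; this is a signal, not an
#' error).
#'
#' @param kmer character vector of k-mers over `{A,C,G,T}` (same length each).
#' @return character vector of canonical k-mers, `NA` where `N` occurs.
#' @export
canonical_form <- function(kmer) {
  rc <- revcomp(kmer)
  out <- ifelse(kmer <= rc, kmer, rc)
  out[stringi::stri_detect_fixed(kmer, "N")] <- NA_character_
  out
}

# base characters -> 0..3 (NA for N); raw-compare based, vectorised
seq_to_ints <- function(seq) {
  b <- charToRaw(seq)
  v <- rep(NA_integer_, length(b))
  v[b == charToRaw("A")] <- 0L
  v[b == charToRaw("C")] <- 1L
  v[b == charToRaw("G")] <- 2L
  v[b == charToRaw("T")] <- 3L
  v
}

encode_kmer_string <- function(kmer) {
  v <- seq_to_ints(kmer)
  if (anyNA(v)) return(NA_real_)
  sum(v * 4^(rev(seq_along(v)) - 1))
}

decode_kmers <- function(codes, k) {
  out <- character(length(codes))
  for (i in seq_along(codes)) {
    c0 <- codes[i]
    digs <- integer(k)
    for (j in seq.int(k, 1L)) {
      digs[j] <- c0 %% 4
      c0 <- c0 %/% 4
    }
    out[i] <- paste(BASES[digs + 1L], collapse = "")
  }
  out
}

# all valid (N-free) canonical k-mer occurrences of one scaffold as
# data.table(pos [0-based start], kmer [numeric canonical code])
kmer_occurrences <- function(seq, k) {
  if (k > 26L) stop("k > 26 exceeds exact 2-bit packing in doubles", call. = FALSE)
  L <- nchar(seq)
  if (L < k) {
    return(data.table::data.table(pos = integer(0), kmer = numeric(0)))
  }
  v <- seq_to_ints(seq)
  bad <- is.na(v)
  v0 <- ifelse(bad, 0L, v)
  # window codes by sliding convolution, aligned at window end
  fwd_end <- stats::filter(v0, 4^(0:(k - 1L)), sides = 1L)
  rc_end <- stats::filter(3L - v0, 4^((k - 1L):0), sides = 1L)
  ends <- seq.int(k, L)
  fwd <- as.numeric(fwd_end[ends])
  rc <- as.numeric(rc_end[ends])
  pos <- ends - k  # 0-based start
  if (any(bad)) {
    nN <- cumsum(bad)
    with_n <- nN[ends] - c(0L, nN)[ends - k + 1L] > 0L
    fwd <- fwd[!with_n]; rc <- rc[!with_n]; pos <- pos[!with_n]
  }
  data.table::data.table(pos = as.integer(pos), kmer = pmin(fwd, rc))
}

#' Build per-group canonical k-mer profiles for a community
#'
#' Counts every N-free canonical k-mer occurrence of every scaffold, per
#' taxonomic group and per MAG. Singleton groups are legal (e.g. each algal
#' species kept as its own group).
#'
#' @param community named list of [mag_record()] objects, spanning at least
#'   two groups.
#' @param params [detector_params()].
#' @return object of class `kmer_profiles`: occurrence table, per-(k-mer,
#'   group) counts and MAG document frequencies, per-k-mer group document
#'   frequencies, token totals, group sizes. k-mers are stored as packed
#'   numeric codes; [kmer_stats()] accepts the string form.
#' @export
build_group_profiles <- function(community, params = detector_params()) {
  mag_group <- vapply(community, `[[`, "", "group")
  groups <- unique(mag_group)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  k <- params$k
  occ <- data.table::rbindlist(lapply(community, function(m) {
    per_scaf <- data.table::rbindlist(lapply(names(m$scaffolds), function(sid) {
      o <- kmer_occurrences(m$scaffolds[[sid]], k)
      if (nrow(o)) o[, scaffold_id := sid]
      o
    }), fill = TRUE)
    if (nrow(per_scaf)) per_scaf[, mag_id := m$mag_id]
    per_scaf
  }), fill = TRUE)
  if (nrow(occ) == 0L) stop("community contains no countable k-mers at k = ", k, call. = FALSE)
  occ[, group := mag_group[mag_id]]

  presence <- unique(occ[, list(kmer, mag_id, group)])
  kmer_group <- occ[, list(count = .N), by = list(kmer, group)]
  mag_df <- presence[, list(mag_df = .N), by = list(kmer, group)]
  kmer_group <- merge(kmer_group, mag_df, by = c("kmer", "group"))
  group_df <- unique(presence[, list(kmer, group)])[, list(group_df = .N), by = kmer]
  data.table::setkey(occ, mag_id)
  data.table::setkey(kmer_group, group, kmer)
  data.table::setkey(group_df, kmer)

  structure(
    list(occ = occ,
         kmer_group = kmer_group,
         group_df = group_df,
         tokens = {
           tk <- occ[, .N, by = group]
           stats::setNames(tk$N, tk$group)
         },
         group_sizes = stats::setNames(
           as.integer(table(mag_group)[groups]), groups),
         mag_group = mag_group,
         n_groups = length(groups),
         k = k),
    class = "kmer_profiles"
  )
}

#' @export
print.kmer_profiles <- function(x, ...) {
  cat(sprintf("<kmer_profiles> k=%d  %d groups, %d MAGs, %s k-mer tokens, %s distinct canonical k-mers\n",
              x$k, x$n_groups, length(x$mag_group),
              format(sum(x$tokens), big.mark = ","),
              format(nrow(x$group_df), big.mark = ",")))
  invisible(x)
}

#' TF-IDF statistics of one k-mer across groups
#'
#' Term frequency `tf(t,G)` is the occurrence count of `t` in group `G`
#' divided by the total k-mer tokens of `G`; `idf(t) = ln(N_groups /
#' group_df(t))` where `group_df` is the number of groups containing `t`;
#' `tfidf = tf * idf`. `idf` is zero exactly when the k-mer occurs in every
#' group.
#'
#' @param profiles a `kmer_profiles` object.
#' @param t a single k-mer string (canonicalised internally).
#' @return data.table with one row per group containing `t`: `group`,
#'   `count`, `mag_df`, `tf`, `group_df`, `idf`, `tfidf`.
#' @export
kmer_stats <- function(profiles, t) {
  assert_scalar_string(t, "t")
  t <- toupper(t)
  if (nchar(t) != profiles$k) stop("k-mer length != profile k", call. = FALSE)
  tc <- canonical_form(t)
  if (is.na(tc)) stop("k-mer contains N", call. = FALSE)
  code <- encode_kmer_string(tc)
  rows <- profiles$kmer_group[kmer == code]
  if (nrow(rows) == 0L) stop("unknown k-mer: ", t, call. = FALSE)
  gdf <- profiles$group_df[kmer == code, group_df]
  out <- rows[, list(group, count, mag_df)]
  out[, tf := count / as.numeric(profiles$tokens[group])]
  out[, group_df := gdf]
  out[, idf := log(profiles$n_groups / gdf)]
  out[, tfidf := tf * idf]
  out[]
}

# flagging thresholds: minimum donor MAG count implied by donor_prevalence
donor_mag_threshold <- function(params, group_size) {
  as.integer(ceiling(params$donor_prevalence * group_size - 1e-9))
}

#' Flag foreign k-mer occurrences on a recipient MAG
#'
#' A k-mer occurrence at a position of a recipient scaffold is flagged iff
#' (a) the k-mer is present in at least `ceiling(donor_prevalence * |B|)`
#' MAGs of the donor group B; (b) within the recipient's own group it occurs
#' in at most `recipient_rarity` MAGs other than the recipient itself; and
#' (c) its overall group document frequency is at most `max_group_df`.
#'
#' @param recipient a [mag_record()] or a mag_id present in `profiles`.
#' @param donor_group donor group label (must differ from the recipient's).
#' @param profiles a `kmer_profiles` object covering the community.
#' @param params [detector_params()].
#' @return data.table `(scaffold_id, pos, kmer, tfidf_donor)` of flagged
#'   k-mer starts (0-based, `kmer` as string), sorted by scaffold then
#'   position. May be empty.
#' @export
flag_foreign_kmers <- function(recipient, donor_group, profiles,
                               params = detector_params()) {
  rid <- if (inherits(recipient, "mag_record")) recipient$mag_id else recipient
  rgroup <- profiles$mag_group[[rid]]
  if (is.null(rgroup)) stop("unknown recipient MAG: ", rid, call. = FALSE)
  if (identical(donor_group, rgroup)) stop("donor_group must differ from the recipient's group", call. = FALSE)
  if (!donor_group %in% names(profiles$group_sizes)) stop("unknown donor group: ", donor_group, call. = FALSE)
  occ_r <- recipient_occurrences(profiles, rid, rgroup)
  fl <- flag_occurrences(occ_r, donor_table(profiles, donor_group), donor_group,
                         profiles, params)
  fl[, kmer := decode_kmers(kmer, profiles$k)]
  fl[]
}

# recipient occurrences with recipient-group mag_df and group_df attached
recipient_occurrences <- function(profiles, rid, rgroup) {
  occ_r <- profiles$occ[list(rid), list(scaffold_id, pos, kmer)]
  rec <- profiles$kmer_group[list(rgroup), list(kmer, rec_mag_df = mag_df)]
  data.table::setkey(rec, kmer)
  occ_r <- rec[occ_r, on = "kmer"]
  occ_r <- profiles$group_df[occ_r, on = "kmer"]
  occ_r
}

donor_table <- function(profiles, donor_group) {
  don <- profiles$kmer_group[list(donor_group),
                             list(kmer, don_mag_df = mag_df, don_count = count)]
  data.table::setkey(don, kmer)
  don
}

# flagging kernel on pre-joined tables
flag_occurrences <- function(occ_r, don, donor_group, profiles, params) {
  x <- don[occ_r, on = "kmer"]
  thr <- donor_mag_threshold(params, profiles$group_sizes[[donor_group]])
  x <- x[!is.na(don_mag_df) & don_mag_df >= thr &
           (rec_mag_df - 1L) <= params$recipient_rarity &
           group_df <= params$max_group_df]
  if (nrow(x) == 0L) {
    return(data.table::data.table(scaffold_id = character(0), pos = integer(0),
                                  kmer = numeric(0), tfidf_donor = numeric(0)))
  }
  idf <- log(profiles$n_groups / x$group_df)
  x[, tfidf_donor := (don_count / as.numeric(profiles$tokens[[donor_group]])) * idf]
  data.table::setorder(x, scaffold_id, pos)
  x[, list(scaffold_id, pos, kmer, tfidf_donor)]
}

#' Merge flagged k-mer starts into maximal runs
#'
#' Consecutive flagged starts (on one scaffold) at most `merge_gap` apart
#' belong to the same run; a run of starts `s_1 .. s_m` becomes the interval
#' `[s_1, s_m + k)`. Output intervals are disjoint and sorted.
#'
#' @param positions strictly increasing integer vector of flagged k-mer
#'   start positions (0-based) on one scaffold.
#' @param params [detector_params()] supplying `k` and `merge_gap`.
#' @return data.table `(start, end, m)` where `m` is the number of flagged
#'   starts in the run.
#' @export
merge_flagged_runs <- function(positions, params = detector_params()) {
  if (length(positions) == 0L) {
    return(data.table::data.table(start = integer(0), end = integer(0), m = integer(0)))
  }
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  run <- cumsum(c(1L, as.integer(diff(positions) > params$merge_gap)))
  dt <- data.table::data.table(pos = positions, run = run)
  dt[, list(start = min(pos), end = max(pos) + params$k, m = .N), by = run][, run := NULL][]
}

#' Run-length significance bound for a flagged region
#'
#' Upper bound on the probability of observing at least one run of `m` or
#' more flagged k-mer starts anywhere in the recipient, if flags arose
#' independently at the genome-wide rate `q`: `p = min(1, n_positions *
#' q^m)` (a Bonferroni-style bound over possible run start positions). It is
#' monotone decreasing in `m` and increasing in `q`. With `q = 0` and
#' `m >= 1` the flags exist only inside the region and `p = 0`.
#'
#' @param m number of flagged starts in the region (>= 1).
#' @param q genome-wide flagged fraction for the (recipient, donor) pair.
#' @param n_positions total number of valid k-mer starts in the recipient.
#' @return p-value bound in `[0, 1]`.
#' @export
region_pvalue <- function(m, q, n_positions) {
  stopifnot(m >= 1, q >= 0, q <= 1, n_positions >= 1)
  if (q == 0) {
    message("region_pvalue: q = 0 with m >= 1 (flags exist only in the region); p = 0")
    return(0)
  }
  min(1, n_positions * q^m)
}

#' Call candidate horizontally transferred regions across a community
#'
#' For every ordered (donor group, recipient MAG) pair with donor group
#' different from the recipient's, flags foreign k-mer occurrences, merges
#' them into runs, and keeps regions whose run-length p-value is at most
#' `alpha`. When the same interval (>= 50% reciprocal overlap) is called
#' for several donor groups, the donor with the highest region score (sum
#' of donor-group TF-IDF over flagged k-mers) is kept; ties break by
#' lexicographic donor name. Candidate ids are zero-padded ranks by
#' (recipient, scaffold, start) and therefore deterministic.
#'
#' @param community named list of [mag_record()] objects.
#' @param params [detector_params()].
#' @param profiles optional precomputed `kmer_profiles` for `community`.
#' @return data.table of class `hgt_candidates`: `candidate_id`,
#'   `recipient_mag`, `recipient_group`, `scaffold_id`, `start`, `end`
#'   (0-based half-open), `length`, `donor_group`, `n_flagged_kmers`,
#'   `score`, `p_value`.
#' @export
call_candidate_hgts <- function(community, params = detector_params(),
                                profiles = NULL) {
  if (is.null(profiles)) profiles <- build_group_profiles(community, params)
  groups <- names(profiles$group_sizes)
  donor_tables <- lapply(stats::setNames(groups, groups),
                         function(g) donor_table(profiles, g))
  pieces <- list()
  for (rid in names(community)) {
    rgroup <- profiles$mag_group[[rid]]
    occ_r <- recipient_occurrences(profiles, rid, rgroup)
    n_pos <- nrow(occ_r)
    if (n_pos == 0L) next
    for (dg in setdiff(groups, rgroup)) {
      fl <- flag_occurrences(occ_r, donor_tables[[dg]], dg, profiles, params)
      if (nrow(fl) == 0L) next
      q <- nrow(fl) / n_pos
      regions <- fl[, {
        runs <- merge_flagged_runs(pos, params)
        runs[, score := vapply(seq_len(.N), function(i) {
          sum(tfidf_donor[pos >= runs$start[i] & pos < runs$end[i]])
        }, 0)]
        runs
      }, by = scaffold_id]
      regions[, p_value := pmin(1, n_pos * q^m)]
      regions <- regions[p_value <= params$alpha]
      if (nrow(regions) == 0L) next
      regions[, `:=`(recipient_mag = rid, recipient_group = rgroup, donor_group = dg)]
      pieces[[length(pieces) + 1L]] <- regions
    }
  }
  empty <- data.table::data.table(
    candidate_id = character(0), recipient_mag = character(0),
    recipient_group = character(0), scaffold_id = character(0),
    start = integer(0), end = integer(0), length = integer(0),
    donor_group = character(0), n_flagged_kmers = integer(0),
    score = numeric(0), p_value = numeric(0))
  if (length(pieces) == 0L) {
    data.table::setattr(empty, "class", c("hgt_candidates", class(data.table::data.table())))
    return(empty)
  }
  all_regions <- data.table::rbindlist(pieces, use.names = TRUE)

  # cross-donor resolution: within (recipient, scaffold), greedily keep the
  # best-scoring region; drop lower-scoring regions from *other* donors that
  # reciprocally overlap (>= 50%) a kept one
  data.table::setorder(all_regions, recipient_mag, scaffold_id, -score, donor_group, start)
  kept <- all_regions[, {
    keep <- rep(TRUE, .N)
    for (i in seq_len(.N)) {
      if (!keep[i]) next
      if (i < .N) {
        for (j in seq.int(i + 1L, .N)) {
          if (!keep[j] || donor_group[j] == donor_group[i]) next
          if (reciprocal_overlap(start[i], end[i], start[j], end[j], 0.5)) {
            keep[j] <- FALSE
          }
        }
      }
    }
    .SD[keep]
  }, by = list(recipient_mag, scaffold_id)]

  data.table::setorder(kept, recipient_mag, scaffold_id, start)
  width <- max(4L, nchar(nrow(kept)))
  out <- kept[, list(
    candidate_id = sprintf(paste0("HGT%0", width, "d"), seq_len(.N)),
    recipient_mag, recipient_group, scaffold_id,
    start = as.integer(start), end = as.integer(end),
    length = as.integer(end - start),
    donor_group, n_flagged_kmers = as.integer(m), score, p_value)]
  data.table::setattr(out, "class", c("hgt_candidates", class(data.table::data.table())))
  out
}
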