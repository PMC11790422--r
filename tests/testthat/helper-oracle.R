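# Independent brute-force oracles: naive character-level implementations
# used to pin down expected values. Deliberately share no code with the
# package internals (no packed codes, no data.table joins).

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# every N-free canonical k-mer occurrence of a sequence, by explicit loop
oracle_kmers <- function(seq, k) {
  out_pos <- integer(0); out_kmer <- character(0)
  if (nchar(seq) >= k) {
    for (i in seq_len(nchar(seq) - k + 1L)) {
      km <- substr(seq, i, i + k - 1L)
      if (!grepl("N", km, fixed = TRUE)) {
        out_pos <- c(out_pos, i - 1L)
        out_kmer <- c(out_kmer, oracle_canonical(km))
      }
    }
  }
  data.frame(pos = out_pos, kmer = out_kmer, stringsAsFactors = FALSE)
}

# dictionary of per-group counts / MAG presence built by direct enumeration
oracle_profiles <- function(community, k) {
  group_counts <- list()   # group -> named integer vector
  mag_presence <- list()   # mag -> character set of kmers
  tokens <- list()
  for (m in community) {
    kms <- character(0)
    for (s in m$scaffolds) kms <- c(kms, oracle_kmers(s, k)$kmer)
    mag_presence[[m$mag_id]] <- unique(kms)
    g <- m$group
    tokens[[g]] <- (tokens[[g]] %||% 0L) + length(kms)
    tab <- table(kms)
    prev <- group_counts[[g]] %||% integer(0)
    for (km in names(tab)) prev[km] <- (prev[km] %||% 0L) + tab[[km]]
    group_counts[[g]] <- prev
  }
  mag_group <- vapply(community, function(m) m$group, "")
  list(group_counts = group_counts, mag_presence = mag_presence,
       tokens = tokens, mag_group = mag_group,
       groups = unique(mag_group))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

oracle_group_df <- function(op, kmer) {
  sum(vapply(op$groups, function(g) {
    kmer %in% names(op$group_counts[[g]]) && op$group_counts[[g]][[kmer]] > 0
  }, TRUE))
}

oracle_mag_df <- function(op, kmer, group, exclude_mag = NULL) {
  mags <- names(op$mag_group)[op$mag_group == group]
  if (!is.null(exclude_mag)) mags <- setdiff(mags, exclude_mag)
  sum(vapply(mags, function(m) kmer %in% op$mag_presence[[m]], TRUE))
}

# brute-force flagged set for a recipient MAG / donor group
oracle_flags <- function(community, op, rid, donor_group, params) {
  rgroup <- op$mag_group[[rid]]
  thr <- ceiling(params$donor_prevalence * sum(op$mag_group == donor_group) - 1e-9)
  res <- list()
  m <- community[[rid]]
  for (sid in names(m$scaffolds)) {
    occ <- oracle_kmers(m$scaffolds[[sid]], params$k)
    for (r in seq_len(nrow(occ))) {
      km <- occ$kmer[r]
      ok <- oracle_mag_df(op, km, donor_group) >= thr &&
        oracle_mag_df(op, km, rgroup, exclude_mag = rid) <= params$recipient_rarity &&
        oracle_group_df(op, km) <= params$max_group_df
      if (ok) res[[length(res) + 1L]] <- data.frame(
        scaffold_id = sid, pos = occ$pos[r], stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(scaffold_id = character(0), pos = integer(0))
}

# partition positions by transitive closure of |a - b| <= g, then intervals
oracle_merge <- function(positions, k, g) {
  if (length(positions) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), m = integer(0)))
  }
  positions <- sort(positions)
  n <- length(positions)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(positions[i] - positions[j]) <= g && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(cc) {
    p <- positions[comp == cc]
    data.frame(start = min(p), end = max(p) + k, m = length(p))
  })
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

# exact P(at least one run of >= m successes in n Bernoulli(q) trials),
# by full 2^n enumeration
oracle_run_prob <- function(n, q, m) {
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    r <- rle(bits)
    if (any(r$values == 1L & r$lengths >= m)) {
      ones <- sum(bits)
      total <- total + q^ones * (1 - q)^(n - ones)
    }
  }
  total
}

# random DNA of length n from a given RNG state
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny hand-buildable community: groups of MAGs from per-group random
# ancestors, optional planted fragment
make_toy_community <- function(n_groups = 2, mags_per_group = 2, len = 600,
                               divergence = 0, k_seed = 1) {
  set.seed(k_seed)
  community <- list()
  for (g in seq_len(n_groups)) {
    anc <- strsplit(random_dna(len), "")[[1]]
    for (m in seq_len(mags_per_group)) {
      v <- anc
      mut <- which(runif(len) < divergence)
      for (i in mut) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      id <- sprintf("g%dm%d", g, m)
      community[[id]] <- mag_record(
        mag_id = id, group = paste0("grp", g), domain = "Bacteria",
        scaffolds = stats::setNames(paste(v, collapse = ""), paste0(id, "_s1")))
    }
  }
  community
}

# replace a block of a scaffold with a fragment (0-based start)
splice_fragment <- function(community, mag_id, scaffold_id, at, fragment) {
  seq <- community[[mag_id]]$scaffolds[[scaffold_id]]
  community[[mag_id]]$scaffolds[[scaffold_id]] <- paste0(
    substr(seq, 1, at), fragment,
    substr(seq, at + nchar(fragment) + 1, nchar(seq)))
  community
}

reverse_complement_community <- function(community) {
  for (id in names(community)) {
    community[[id]]$scaffolds[] <- oracle_revcomp(community[[id]]$scaffolds)
  }
  community
}
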