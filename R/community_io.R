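# Reading and writing every external artefact the pipeline touches:
# MAG FASTAs + manifest, depth tables, homology tables, repeat masks and
# result files. The manifest, not FASTA filenames, is the source of truth
# for taxonomic grouping.

#' Construct a MAG record
#'
#' One genome bin: an ordered set of scaffolds plus its taxonomic class
#' ("group", the document-grouping unit of the detector), domain, and an
#' optional environment label used by the coverage-congruence filter for
#' eukaryote MAGs.
#'
#' @param mag_id unique MAG identifier (no whitespace).
#' @param group taxonomic class label.
#' @param domain one of `Bacteria`, `Archaea`, `Eukaryota`, `Virus`.
#' @param environment one of `soil`, `creek`, `endolithic`, `none`.
#' @param scaffolds named character vector of uppercase sequences over
#'   `{A,C,G,T,N}`; names are scaffold ids, unique within the MAG.
#' @return object of class `mag_record`.
#' @export
mag_record <- function(mag_id, group, domain, environment = "none", scaffolds) {
  assert_scalar_string(mag_id, "mag_id")
  if (grepl("\\s", mag_id)) stop("mag_id must not contain whitespace: ", mag_id, call. = FALSE)
  assert_scalar_string(group, "group")
  domain <- match.arg(domain, DOMAINS)
  environment <- match.arg(environment, ENVIRONMENTS)
  if (length(scaffolds) == 0L) stop("MAG ", mag_id, " has no scaffolds", call. = FALSE)
  if (is.null(names(scaffolds)) || anyNA(names(scaffolds)) || any(!nzchar(names(scaffolds)))) {
    stop("scaffolds must be a named character vector", call. = FALSE)
  }
  dup <- names(scaffolds)[duplicated(names(scaffolds))]
  if (length(dup)) stop("duplicate scaffold_id in MAG ", mag_id, ": ", dup[1L], call. = FALSE)
  if (any(!nzchar(scaffolds))) stop("empty scaffold sequence in MAG ", mag_id, call. = FALSE)
  bad <- grepl("[^ACGTN]", scaffolds)
  if (any(bad)) stop("scaffold sequences must be normalised to {A,C,G,T,N}", call. = FALSE)
  structure(
    list(mag_id = mag_id, group = group, domain = domain,
         environment = environment, scaffolds = scaffolds),
    class = "mag_record"
  )
}

#' @export
print.mag_record <- function(x, ...) {
  cat(sprintf("<mag_record> %s  group=%s domain=%s env=%s  %d scaffold(s), %d bp\n",
              x$mag_id, x$group, x$domain, x$environment,
              length(x$scaffolds), sum(nchar(x$scaffolds))))
  invisible(x)
}

# uppercase; non-ACGTN -> N; returns list(seq, n_replaced)
normalise_sequence <- function(seq) {
  seq <- toupper(seq)
  n_bad <- sum(stringi::stri_count_regex(seq, "[^ACGTN]"))
  if (n_bad > 0L) seq <- gsub("[^ACGTN]", "N", seq)
  list(seq = seq, n_replaced = n_bad)
}

#' Summarise a community as a table
#'
#' @param community list of [mag_record()] objects.
#' @return data.table with one row per MAG (mag_id, group, domain,
#'   environment, n_scaffolds, total_bp).
#' @export
community_summary <- function(community) {
  data.table::rbindlist(lapply(community, function(m) {
    data.table::data.table(mag_id = m$mag_id, group = m$group, domain = m$domain,
                           environment = m$environment,
                           n_scaffolds = length(m$scaffolds),
                           total_bp = sum(nchar(m$scaffolds)))
  }))
}

# scaffold_id -> length lookup across the community (errors on conflicting
# duplicates are *not* raised here; cross-catalogue duplicates are the
# business of remove_cross_catalogue_overlap)
scaffold_length_table <- function(community) {
  data.table::rbindlist(lapply(community, function(m) {
    data.table::data.table(mag_id = m$mag_id, scaffold_id = names(m$scaffolds),
                           scaffold_length = nchar(m$scaffolds), domain = m$domain)
  }))
}

get_scaffold_seq <- function(community, mag_id, scaffold_id) {
  m <- community[[mag_id]]
  if (is.null(m)) stop("unknown mag_id: ", mag_id, call. = FALSE)
  s <- m$scaffolds[[scaffold_id]]
  if (is.null(s)) stop("unknown scaffold ", scaffold_id, " in MAG ", mag_id, call. = FALSE)
  s
}

#' Read a MAG community from FASTA files and a manifest
#'
#' The manifest is a TSV with header columns `mag_id`, `group`, `domain`,
#' `environment`, `fasta`. The `fasta` column names each MAG's FASTA file;
#' it is resolved against `fasta_paths` by basename when supplied, otherwise
#' relative to the manifest's directory. Sequences are uppercased and any
#' character outside `{A,C,G,T,N}` (ambiguous IUPAC codes and the like) is
#' replaced by `N`, with the replacement count reported via `message()` --
#' MAG assemblies routinely contain such bases and N-containing k-mers are
#' simply skipped downstream.
#'
#' @param manifest_path path to the manifest TSV.
#' @param fasta_paths optional character vector of FASTA paths overriding
#'   manifest-relative resolution (matched by basename).
#' @return named list of [mag_record()] objects (names are mag_ids).
#' @export
read_community <- function(manifest_path, fasta_paths = NULL) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- data.table::fread(manifest_path, sep = "\t", colClasses = "character")
  need <- c("mag_id", "group", "domain", "environment", "fasta")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  dup <- man$mag_id[duplicated(man$mag_id)]
  if (length(dup)) stop("duplicate mag_id in manifest: ", dup[1L], call. = FALSE)
  if (!is.null(fasta_paths)) {
    lookup <- stats::setNames(fasta_paths, basename(fasta_paths))
  }
  community <- vector("list", nrow(man))
  total_replaced <- 0L
  for (i in seq_len(nrow(man))) {
    fa <- man$fasta[i]
    path <- if (!is.null(fasta_paths) && basename(fa) %in% names(lookup)) {
      lookup[[basename(fa)]]
    } else if (file.exists(fa)) fa else file.path(dirname(manifest_path), fa)
    if (!file.exists(path)) {
      stop("FASTA for MAG ", man$mag_id[i], " not found: ", path, call. = FALSE)
    }
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(ss))
    dup_s <- ids[duplicated(ids)]
    if (length(dup_s)) {
      stop("duplicate scaffold_id '", dup_s[1L], "' in FASTA ", path, call. = FALSE)
    }
    seqs <- as.character(ss)
    norm <- normalise_sequence(seqs)
    total_replaced <- total_replaced + norm$n_replaced
    env <- man$environment[i]
    if (is.na(env) || env == "" || env == "-") env <- "none"
    community[[i]] <- mag_record(
      mag_id = man$mag_id[i], group = man$group[i], domain = man$domain[i],
      environment = env, scaffolds = stats::setNames(norm$seq, ids)
    )
  }
  if (total_replaced > 0L) {
    message(total_replaced, " non-ACGTN character(s) replaced by N")
  }
  stats::setNames(community, man$mag_id)
}

#' Write a MAG community as FASTA files plus a manifest
#'
#' Inverse of [read_community()]; one FASTA per MAG named `<mag_id>.fasta`
#' and a `manifest.tsv` in `out_dir`.
#'
#' @param community named list of [mag_record()] objects.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_community <- function(community, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- community_summary(community)[, c("mag_id", "group", "domain", "environment")]
  man$fasta <- paste0(man$mag_id, ".fasta")
  for (m in community) {
    ss <- Biostrings::DNAStringSet(m$scaffolds)
    Biostrings::writeXStringSet(ss, file.path(out_dir, paste0(m$mag_id, ".fasta")), width = 80L)
  }
  path <- file.path(out_dir, "manifest.tsv")
  data.table::fwrite(man, path, sep = "\t")
  invisible(path)
}

#' Read a per-sample per-scaffold depth table
#'
#' TSV with header `sample_id`, `environment`, `scaffold_id`, `mean_depth`,
#' `length`. One row per (sample, scaffold); duplicates and negative depths
#' are hard errors.
#'
#' @param path TSV path.
#' @return data.table of class `depth_table` with columns `sample_id`,
#'   `sample_environment`, `scaffold_id`, `mean_depth`, `scaffold_length`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t")
  need <- c("sample_id", "environment", "scaffold_id", "mean_depth", "length")
  if (!all(need %in% names(dt))) {
    stop("depth table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  dt <- dt[, list(sample_id = as.character(sample_id),
                  sample_environment = as.character(environment),
                  scaffold_id = as.character(scaffold_id),
                  mean_depth = as.numeric(mean_depth),
                  scaffold_length = as.integer(length))]
  as_depth_table(dt)
}

as_depth_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (any(dt$mean_depth < 0)) stop("negative depth in depth table", call. = FALSE)
  if (any(dt$scaffold_length <= 0L)) stop("non-positive scaffold length in depth table", call. = FALSE)
  bad_env <- setdiff(unique(dt$sample_environment), ENVIRONMENTS)
  if (length(bad_env)) stop("unknown sample environment: ", bad_env[1L], call. = FALSE)
  if (anyDuplicated(dt, by = c("sample_id", "scaffold_id"))) {
    stop("duplicate (sample_id, scaffold_id) in depth table", call. = FALSE)
  }
  data.table::setattr(dt, "class", c("depth_table", class(data.table::data.table())))
  dt
}

#' Write a depth table
#' @param depths a `depth_table` (see [read_depth_table()]).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_depth_table <- function(depths, path) {
  out <- data.table::data.table(
    sample_id = depths$sample_id, environment = depths$sample_environment,
    scaffold_id = depths$scaffold_id, mean_depth = depths$mean_depth,
    length = depths$scaffold_length)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a tabular homology (BLAST/DIAMOND outfmt-6 style) table
#'
#' Expects the 12 standard outfmt-6 columns plus a trailing `subject_class`
#' column, with or without a header line. `-` or empty classes become
#' `UNKNOWN`. Rows are grouped per query and ranked by descending bitscore;
#' bitscore ties keep input order (stable).
#'
#' @param path TSV path.
#' @return data.table of class `homology_table` with columns `query_id`,
#'   `subject_accession`, `subject_class`, `percent_identity`, `bitscore`,
#'   `rank`.
#' @export
read_homology_table <- function(path) {
  if (!file.exists(path)) stop("homology table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("query_id", first, fixed = TRUE)
  raw <- data.table::fread(path, sep = "\t", header = has_header)
  if (nrow(raw) == 0L) return(empty_homology_table())
  if (!has_header) {
    if (ncol(raw) < 13L) {
      stop("headerless homology table needs >= 13 columns (outfmt 6 + subject_class)", call. = FALSE)
    }
    dt <- data.table::data.table(
      query_id = as.character(raw[[1L]]),
      subject_accession = as.character(raw[[2L]]),
      percent_identity = as.numeric(raw[[3L]]),
      bitscore = as.numeric(raw[[12L]]),
      subject_class = as.character(raw[[13L]]))
  } else {
    need <- c("query_id", "subject_accession", "percent_identity", "bitscore", "subject_class")
    if (!all(need %in% names(raw))) {
      stop("homology table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
    dt <- raw[, list(query_id = as.character(query_id),
                     subject_accession = as.character(subject_accession),
                     percent_identity = as.numeric(percent_identity),
                     bitscore = as.numeric(bitscore),
                     subject_class = as.character(subject_class))]
  }
  as_homology_table(dt)
}

empty_homology_table <- function() {
  dt <- data.table::data.table(
    query_id = character(0), subject_accession = character(0),
    subject_class = character(0), percent_identity = numeric(0),
    bitscore = numeric(0), rank = integer(0))
  data.table::setattr(dt, "class", c("homology_table", class(data.table::data.table())))
  dt
}

as_homology_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) == 0L) return(empty_homology_table())
  dt[is.na(subject_class) | subject_class %in% c("", "-"), subject_class := "UNKNOWN"]
  if (any(dt$percent_identity < 0 | dt$percent_identity > 100)) {
    stop("percent identity outside [0,100]", call. = FALSE)
  }
  # stable rank by descending bitscore within query; ties keep input order
  dt[, .row := seq_len(.N)]
  data.table::setorder(dt, query_id, -bitscore, .row)
  dt[, rank := seq_len(.N), by = query_id]
  dt[, .row := NULL]
  out <- dt[, list(query_id, subject_accession, subject_class,
                   percent_identity, bitscore, rank)]
  data.table::setattr(out, "class", c("homology_table", class(data.table::data.table())))
  out
}

#' Write a homology table
#' @param homology a `homology_table`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_homology_table <- function(homology, path) {
  data.table::fwrite(data.table::as.data.table(homology), path, sep = "\t")
  invisible(path)
}

#' Read a simple-repeat / low-complexity mask
#'
#' Only `simple_repeat` and `low_complexity` intervals are retained (other
#' repeat classes such as interspersed elements are dropped with a message).
#' BED input is 0-based half-open and used as-is; RepeatMasker `.out` input
#' is 1-based inclusive and converted. All intervals are stored 0-based
#' half-open.
#'
#' @param path input path.
#' @param dialect `"bed"` or `"repeatmasker_out"`.
#' @param community optional community; when given, interval ends are
#'   validated against scaffold lengths.
#' @return data.table of class `repeat_mask` with columns `scaffold_id`,
#'   `start`, `end`, `kind`.
#' @export
read_repeat_mask <- function(path, dialect = c("bed", "repeatmasker_out"),
                             community = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("repeat mask not found: ", path, call. = FALSE)
  classify_kind <- function(x) {
    x0 <- tolower(x)
    out <- rep(NA_character_, length(x))
    out[grepl("simple_repeat|^\\(.*\\)n$", x0)] <- "simple_repeat"
    out[grepl("low_complexity", x0)] <- "low_complexity"
    out
  }
  if (dialect == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
    if (length(lines) == 0L) {
      dt <- data.table::data.table(scaffold_id = character(0), start = integer(0),
                                   end = integer(0), kind = character(0))
    } else {
      parts <- stringi::stri_split_regex(lines, "\\s+")
      dt <- data.table::data.table(
        scaffold_id = vapply(parts, `[[`, "", 1L),
        start = as.integer(vapply(parts, `[[`, "", 2L)),
        end = as.integer(vapply(parts, `[[`, "", 3L)),
        kind_raw = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "simple_repeat", ""))
      dt[, kind := classify_kind(kind_raw)]
      dt[, kind_raw := NULL]
    }
  } else {
    lines <- readLines(path)
    # RepeatMasker .out: 3 header lines then whitespace-separated records
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L) {
      dt <- data.table::data.table(scaffold_id = character(0), start = integer(0),
                                   end = integer(0), kind = character(0))
    } else {
      parts <- stringi::stri_split_regex(trimws(body), "\\s+")
      dt <- data.table::data.table(
        scaffold_id = vapply(parts, `[[`, "", 5L),
        start = as.integer(vapply(parts, `[[`, "", 6L)) - 1L,  # 1-based -> 0-based
        end = as.integer(vapply(parts, `[[`, "", 7L)),
        kind = classify_kind(vapply(parts, `[[`, "", 11L)))
    }
  }
  n_drop <- sum(is.na(dt$kind))
  if (n_drop > 0L) {
    message(n_drop, " non-simple-repeat mask interval(s) dropped")
    dt <- dt[!is.na(kind)]
  }
  if (any(dt$start < 0L) || any(dt$start >= dt$end)) {
    stop("invalid mask interval (need 0 <= start < end)", call. = FALSE)
  }
  if (!is.null(community)) {
    lens <- scaffold_length_table(community)
    m <- merge(dt, unique(lens[, list(scaffold_id, scaffold_length)]),
               by = "scaffold_id", all.x = FALSE)
    if (any(m$end > m$scaffold_length)) {
      stop("mask interval extends past scaffold end", call. = FALSE)
    }
  }
  data.table::setattr(dt, "class", c("repeat_mask", class(data.table::data.table())))
  dt
}

#' Write detection/validation results
#'
#' Writes, into `out_dir`: `survivors.bed` (BED6, 0-based half-open, score
#' = `round(1000 * min(1, -log10(p)/10))`), `report.tsv` (full table with
#' 1-based inclusive coordinates for human reading), `funnel.tsv`
#' (step-by-step survivor counts) and `run_log.txt` (parameters).
#'
#' @param candidates candidate table (see [call_candidate_hgts()]); pass the
#'   surviving candidates.
#' @param funnel a `filter_funnel` table (see [run_funnel()]), or `NULL`.
#' @param out_dir output directory.
#' @param params optional named list of run parameters echoed into the log.
#' @return invisibly, a named list of written paths.
#' @export
write_results <- function(candidates, funnel = NULL, out_dir, params = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  candidates <- data.table::as.data.table(candidates)
  paths <- list()

  bed_path <- file.path(out_dir, "survivors.bed")
  con <- file(bed_path, "w")
  writeLines("# BED6: scaffold, start (0-based), end (exclusive), candidate_id, score, strand", con)
  if (nrow(candidates) > 0L) {
    score <- round(1000 * pmin(1, -log10(candidates$p_value) / 10))
    score[!is.finite(score)] <- 1000L  # p == 0
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", candidates$scaffold_id,
                       candidates$start, candidates$end, candidates$candidate_id,
                       as.integer(score)), con)
  }
  close(con)
  paths$bed <- bed_path

  rep_path <- file.path(out_dir, "report.tsv")
  rep <- data.table::copy(candidates)
  if (nrow(rep) > 0L) {
    rep[, start_1based := start + 1L]
    rep[, end_1based := end]
    rep[, c("start", "end") := NULL]
  }
  data.table::fwrite(rep, rep_path, sep = "\t")
  paths$report <- rep_path

  if (!is.null(funnel)) {
    f <- data.table::as.data.table(funnel)
    applied <- f[is.na(note) | note != "skipped"]
    if (is.unsorted(rev(applied$survivors))) {
      stop("funnel survivor counts must be non-increasing", call. = FALSE)
    }
    funnel_path <- file.path(out_dir, "funnel.tsv")
    data.table::fwrite(f, funnel_path, sep = "\t")
    paths$funnel <- funnel_path
  }

  log_path <- file.path(out_dir, "run_log.txt")
  lines <- c(sprintf("hgtweave run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("n_candidates_written\t%d", nrow(candidates)))
  if (!is.null(params)) {
    p <- unclass(params)
    lines <- c(lines, vapply(names(p), function(nm) {
      sprintf("param\t%s\t%s", nm, paste(format(p[[nm]]), collapse = ","))
    }, ""))
  }
  writeLines(lines, log_path)
  paths$log <- log_path
  invisible(paths)
}
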