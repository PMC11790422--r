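# Internal helpers shared across modules: sequence manipulation and
# 0-based half-open interval arithmetic. All internal coordinates are
# 0-based half-open; conversion to 1-based inclusive happens only when
# writing human-readable tables.

DOMAINS <- c("Bacteria", "Archaea", "Eukaryota", "Virus")
ENVIRONMENTS <- c("soil", "creek", "endolithic", "none")

#' Reverse complement of a DNA string
#'
#' Vectorised over its input; `N` complements to `N`.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

gc_fraction <- function(seq) {
  # GC over unambiguous bases only; NA when no unambiguous base remains
  counts <- stringi::stri_count_fixed(seq, c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) return(NA_real_)
  (counts[2L] + counts[3L]) / denom
}

# union of 0-based half-open intervals given as two numeric vectors;
# returns data.table(start, end), sorted, disjoint
interval_union <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.table::data.table(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- start[1L]; ue <- end[1L]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ue) {
      ue <- max(ue, end[i])
    } else {
      outs <- c(outs, us); oute <- c(oute, ue)
      us <- start[i]; ue <- end[i]
    }
  }
  data.table::data.table(start = c(outs, us), end = c(oute, ue))
}

interval_overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# reciprocal overlap: overlap covers >= frac of BOTH intervals
reciprocal_overlap <- function(s1, e1, s2, e2, frac = 0.5) {
  ov <- interval_overlap_len(s1, e1, s2, e2)
  ov >= frac * (e1 - s1) & ov >= frac * (e2 - s2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  invisible(x)
}
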