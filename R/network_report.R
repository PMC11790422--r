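# Directed class-level transfer network: one node per taxonomic group
# involved in a validated event, one edge per ordered (donor, recipient)
# group pair carrying all its events, with per-event lengths and optional
# functional category labels as data attributes. Rendering (Cytoscape et
# al.) is left to the consumer.

#' Build the directed transfer network
#'
#' @param final_candidates validated candidate table (needs `candidate_id`,
#'   `donor_group`, `recipient_group`, `length`; an optional `category`
#'   column carries per-event functional labels).
#' @param community named list of [mag_record()] objects (supplies node
#'   domains).
#' @return object of class `hgt_network`: list with `nodes` (group,
#'   domain), `edges` (donor_group, recipient_group, n_events, min/max
#'   length, comma-joined event ids, lengths, categories) and `events`
#'   (the per-event rows).
#' @export
build_network <- function(final_candidates, community) {
  cand <- data.table::as.data.table(final_candidates)
  gd <- group_domain_map(community)
  groups_used <- unique(c(cand$donor_group, cand$recipient_group))
  unknown <- setdiff(groups_used, names(gd))
  if (length(unknown)) stop("candidate references unknown group: ", unknown[1L], call. = FALSE)
  if (nrow(cand) > 0L && any(cand$donor_group == cand$recipient_group)) {
    stop("self-edge: donor_group equals recipient_group", call. = FALSE)
  }
  if (!"category" %in% names(cand)) cand$category <- NA_character_
  nodes <- data.table::data.table(group = groups_used, domain = gd[groups_used])
  events <- cand[, list(candidate_id, donor_group, recipient_group, length, category)]
  edges <- if (nrow(events)) {
    events[, list(n_events = .N,
                  min_length = min(length), max_length = max(length),
                  event_ids = paste(candidate_id, collapse = ","),
                  lengths = paste(length, collapse = ","),
                  categories = paste(ifelse(is.na(category), ".", category),
                                     collapse = ",")),
           by = list(donor_group, recipient_group)]
  } else {
    data.table::data.table(donor_group = character(0), recipient_group = character(0),
                           n_events = integer(0), min_length = integer(0),
                           max_length = integer(0), event_ids = character(0),
                           lengths = character(0), categories = character(0))
  }
  structure(list(nodes = nodes, edges = edges, events = events),
            class = "hgt_network")
}

#' @export
print.hgt_network <- function(x, ...) {
  cat(sprintf("<hgt_network> %d node(s), %d directed edge(s), %d event(s)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$events)))
  invisible(x)
}

#' Domain-level flow matrix
#'
#' Counts validated events per ordered (donor domain, recipient domain)
#' pair; the diagonal totals within-domain transfer. The matrix sums to
#' the number of events (conservation).
#'
#' @param network an `hgt_network` from [build_network()].
#' @param community named list of [mag_record()] objects.
#' @return 4x4 integer matrix over Bacteria, Archaea, Eukaryota, Virus
#'   (rows: donor domain; columns: recipient domain).
#' @export
domain_flow_counts <- function(network, community) {
  gd <- group_domain_map(community)
  m <- matrix(0L, 4L, 4L, dimnames = list(donor = DOMAINS, recipient = DOMAINS))
  ev <- network$events
  if (nrow(ev)) {
    tab <- table(factor(gd[ev$donor_group], levels = DOMAINS),
                 factor(gd[ev$recipient_group], levels = DOMAINS))
    m[] <- as.integer(tab)
  }
  m
}

#' Export the transfer network
#'
#' `tsv`: edge list with event counts, lengths and categories. `sif`:
#' Cytoscape simple-interaction lines `donor hgt recipient`. `graphml`:
#' full graph with node `domain` and edge `weight` (= event count),
#' `min_length`, `max_length` attributes, readable by Cytoscape and igraph.
#'
#' @param network an `hgt_network`.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_network <- function(network, format = c("tsv", "sif", "graphml"), path) {
  format <- match.arg(format)
  if (format == "tsv") {
    data.table::fwrite(network$edges, path, sep = "\t")
  } else if (format == "sif") {
    lines <- if (nrow(network$edges)) {
      sprintf("%s\thgt\t%s", network$edges$donor_group, network$edges$recipient_group)
    } else character(0)
    writeLines(lines, path)
  } else {
    g <- igraph::make_empty_graph(directed = TRUE)
    if (nrow(network$nodes)) {
      g <- igraph::add_vertices(g, nrow(network$nodes),
                                name = network$nodes$group,
                                domain = network$nodes$domain)
    }
    if (nrow(network$edges)) {
      idx <- rbind(match(network$edges$donor_group, network$nodes$group),
                   match(network$edges$recipient_group, network$nodes$group))
      g <- igraph::add_edges(g, as.vector(idx),
                             weight = network$edges$n_events,
                             min_length = network$edges$min_length,
                             max_length = network$edges$max_length)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
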