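# Directly-follows process discovery. Traces (padded with START/END) yield
# a directly-follows graph; each retained pair (a,b) becomes a place
# connecting the labeled transitions a and b. The construction is
# deterministic, and any externally mined PNML net can be substituted via
# read_pnml() -- decay replay only requires a replayable net.

place_name <- function(a, b) paste0("p:", a, ">", b)

canonical_place_order <- function(places) {
  fixed <- intersect(c("p_source", "p_sink", "p:OTHER"), places)
  c(fixed, sort(setdiff(places, fixed)))
}

#' Discover a Petri net from an event log
#'
#' Builds the directly-follows graph over event names, keeps pairs seen at
#' least `frequency_threshold` times, and wires one place per retained
#' pair between the pair's labeled transitions, plus a marked source place
#' feeding START and a sink place fed by END. A transition whose every
#' incoming (outgoing) pair fell below the threshold keeps its
#' highest-count pair, so every transition always has at least one input
#' and one output place. An OTHER transition with a self-loop place
#' absorbs event names outside the training vocabulary at replay time.
#'
#' @param log a `hf_event_log` (training traces only).
#' @param frequency_threshold minimum directly-follows count (>= 1).
#' @return A `petri_net` object.
#' @export
discover_petri_net <- function(log, frequency_threshold = 1) {
  if (nrow(log$events) == 0L) stop_config("empty event log")
  if (frequency_threshold < 1) stop_config("frequency_threshold must be >= 1")
  nm_by <- split(log$events$name, log$events$case_id)
  from <- unlist(lapply(nm_by, function(x) c("START", x)))
  to <- unlist(lapply(nm_by, function(x) c(x, "END")))
  key <- paste(from, to, sep = "\r")
  tab <- table(key)
  dfg <- data.frame(
    from = sub("\r.*$", "", names(tab)),
    to = sub("^.*\r", "", names(tab)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  dfg <- dfg[order(dfg$from, dfg$to), ]
  keep <- dfg$count >= frequency_threshold
  # orphan rescue: keep each transition's strongest pair on a starved side
  vocab <- sort(unique(log$events$name))
  for (v in vocab) {
    inc <- which(dfg$to == v)
    if (!any(keep[inc])) keep[inc[which.max(dfg$count[inc])]] <- TRUE
    out <- which(dfg$from == v)
    if (!any(keep[out])) keep[out[which.max(dfg$count[out])]] <- TRUE
  }
  dfg <- dfg[keep, ]

  transitions <- c("START", "END", "OTHER", vocab)
  pair_places <- place_name(dfg$from, dfg$to)
  places <- canonical_place_order(c("p_source", "p_sink", "p:OTHER", pair_places))
  arcs <- rbind(
    data.frame(from = "p_source", to = "START", stringsAsFactors = FALSE),
    data.frame(from = "END", to = "p_sink", stringsAsFactors = FALSE),
    data.frame(from = "OTHER", to = "p:OTHER", stringsAsFactors = FALSE),
    data.frame(from = "p:OTHER", to = "OTHER", stringsAsFactors = FALSE),
    data.frame(from = dfg$from, to = pair_places, stringsAsFactors = FALSE),
    data.frame(from = pair_places, to = dfg$to, stringsAsFactors = FALSE))
  arcs <- unique(arcs)
  marking <- stats::setNames(integer(length(places)), places)
  marking["p_source"] <- 1L
  net <- new_petri_net(places, transitions, arcs, marking,
                       source_place = "p_source", sink_place = "p_sink",
                       dfg = dfg)
  net
}

# assemble + structurally validate a petri_net
new_petri_net <- function(places, transitions, arcs, initial_marking,
                          source_place, sink_place, dfg = NULL) {
  places <- canonical_place_order(unique(places))
  transitions <- unique(transitions)
  is_place_from <- arcs$from %in% places
  is_trans_from <- arcs$from %in% transitions
  ok <- (is_place_from & arcs$to %in% transitions) |
        (is_trans_from & arcs$to %in% places)
  if (!all(ok))
    stop_invariant("arc %s -> %s does not connect a place and a transition",
                   arcs$from[!ok][1L], arcs$to[!ok][1L])
  trans_in <- lapply(transitions, function(t)
    match(arcs$from[arcs$to == t], places))
  trans_out <- lapply(transitions, function(t)
    match(arcs$to[arcs$from == t], places))
  names(trans_in) <- names(trans_out) <- transitions
  starved <- transitions[lengths(trans_in) == 0L | lengths(trans_out) == 0L]
  if (length(starved))
    stop_invariant("transition '%s' lacks an input or output place", starved[1L])
  if (sum(initial_marking) < 1L)
    stop_invariant("initial marking must contain at least one token")
  structure(list(
    places = places, transitions = transitions, arcs = arcs,
    trans_in = trans_in, trans_out = trans_out,
    initial_marking = initial_marking[places],
    source_place = source_place, sink_place = sink_place, dfg = dfg),
    class = "petri_net")
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("<petri_net> %d places, %d transitions, %d arcs\n",
              length(x$places), length(x$transitions), nrow(x$arcs)))
  invisible(x)
}

#' Export a Petri net as Graphviz DOT
#'
#' @param net a `petri_net`.
#' @param path output file; `NULL` returns the DOT string.
#' @return The DOT source, invisibly when written to file.
#' @export
write_dot <- function(net, path = NULL) {
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  lines <- c("digraph petri {", "  rankdir=LR;",
    sprintf('  "%s" [shape=circle,label=""];', esc(net$places)),
    sprintf('  "%s" [shape=box];', esc(net$transitions)),
    sprintf('  "%s" -> "%s";', esc(net$arcs$from), esc(net$arcs$to)), "}")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
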