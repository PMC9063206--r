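# Independent oracles: implemented deliberately apart from the package
# internals (plain loops and data frames, no shared helpers), so each
# dual-route check compares two genuinely different computations.

# exhaustive pairwise AUROC with half credit for ties
brute_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# brute-force decay replay: mirrors the documented replay semantics with
# naive data structures. net fields (places/arcs) are treated as data; the
# token dynamics are recomputed from scratch.
oracle_replay_tss <- function(net, names, times_sec, upto, alphas, beta = 1) {
  places <- net$places
  P <- length(places)
  marking <- as.numeric(net$initial_marking[places])
  count <- rep(0, P)
  t_last <- rep(NA_real_, P)
  miss <- 0
  arcs <- net$arcs
  inputs_of <- function(tr) which(places %in% arcs$from[arcs$to == tr])
  outputs_of <- function(tr) which(places %in% arcs$to[arcs$from == tr])
  arrive <- function(p, tm) {
    count[p] <<- count[p] + 1
    t_last[p] <<- tm
  }
  fire <- function(label, prev, tm) {
    ins <- inputs_of(label)
    pref <- which(places == paste0("p:", prev, ">", label))
    if (length(pref) == 1L && marking[pref] > 0) {
      marking[pref] <<- marking[pref] - 1
    } else {
      marked <- ins[marking[ins] > 0]
      if (length(marked) > 0L) {
        marking[marked[1L]] <<- marking[marked[1L]] - 1
      } else {
        miss <<- miss + 1
        tgt <- if (length(pref) == 1L) pref else ins[1L]
        arrive(tgt, tm)
      }
    }
    for (p in outputs_of(label)) {
      arrive(p, tm)
      marking[p] <<- marking[p] + 1
    }
  }
  td <- times_sec / 86400
  fire("START", "__none__", td[1L] - 0.001 / 86400)
  prev <- "START"
  for (i in seq_len(upto)) {
    label <- if (names[i] %in% net$transitions) names[i] else "OTHER"
    fire(label, prev, td[i])
    prev <- label
  }
  tcap <- td[upto]
  decay <- rep(0, P)
  for (p in seq_len(P)) {
    if (!is.na(t_last[p]))
      decay[p] <- max(0, beta - alphas[[places[p]]] * (tcap - t_last[p]))
  }
  list(decay = decay, count = count, marking = marking, miss = miss)
}

# random toy event log over a small alphabet; returns a hf_event_log-shaped
# object built directly (no build_event_log involvement)
random_toy_log <- function(n_traces, alphabet, seed, max_len = 6) {
  set.seed(seed)
  cases <- lapply(seq_len(n_traces), function(i) {
    len <- sample(2:max_len, 1)
    nm <- sample(alphabet, len, replace = TRUE)
    ts <- sort(sample(1:500, len)) * 86400 / 10  # tenths of days, strictly inc
    list(case_id = i, names = nm, timestamps = ts)
  })
  events <- do.call(rbind, lapply(cases, function(cs)
    data.frame(case_id = cs$case_id, name = cs$names, timestamp = cs$timestamps,
               stringsAsFactors = FALSE)))
  log <- list(events = events,
              cases = data.frame(
                case_id = seq_len(n_traces),
                label = rep(c(TRUE, FALSE), length.out = n_traces),
                tss_index = vapply(cases, function(cs) length(cs$names), 1L)))
  class(log) <- "hf_event_log"
  log
}

# direct prefix-lookup severity oracle straight off the shipped CSVs
oracle_elix_groups <- function(codes) {
  map <- read.csv(system.file("extdata", "elixhauser_quan_icd9.csv",
                              package = "dreamHF"),
                  colClasses = c("integer", "character", "character"))
  codes <- gsub(".", "", toupper(codes), fixed = TRUE)
  hits <- character(0)
  for (i in seq_len(nrow(map))) {
    for (cd in codes) {
      if (substr(cd, 1, nchar(map$icd9_prefix[i])) == map$icd9_prefix[i])
        hits <- c(hits, map$group[i])
    }
  }
  unique(map$group)[unique(map$group) %in% hits]
}

oracle_charlson <- function(codes) {
  map <- read.csv(system.file("extdata", "charlson_quan_icd9.csv",
                              package = "dreamHF"),
                  colClasses = c("character", "integer", "character"))
  codes <- gsub(".", "", toupper(codes), fixed = TRUE)
  cats <- character(0)
  for (i in seq_len(nrow(map))) {
    for (cd in codes) {
      if (substr(cd, 1, nchar(map$icd9_prefix[i])) == map$icd9_prefix[i])
        cats <- c(cats, map$category[i])
    }
  }
  cats <- unique(cats)
  # canonical hierarchy rules of the index
  if ("DiabetesComplication" %in% cats) cats <- setdiff(cats, "DiabetesNoComplication")
  if ("ModerateSevereLiver" %in% cats) cats <- setdiff(cats, "MildLiver")
  if ("MetastaticTumor" %in% cats) cats <- setdiff(cats, "Malignancy")
  w <- map$weight[match(cats, map$category)]
  sum(w)
}
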