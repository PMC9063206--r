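# Decay replay: traces are replayed on the Petri net; every place carries
# a linear decay function value(t) = max(0, beta - alpha * (t - t_last))
# that is reset to beta whenever a token arrives. The Timed State Sample
# (TSS) captured at the TSS marker (the index discharge) concatenates all
# places' decay values, cumulative token-arrival counts and current
# marking. Time is measured in days, the native resolution of the source
# records, so millisecond ordering offsets contribute ~0 decay.

# hashed lookup structures reused across replays; callers replaying many
# traces build this once and pass it down
net_runtime <- function(net) {
  trans_idx <- new.env(parent = emptyenv())
  for (i in seq_along(net$transitions)) assign(net$transitions[i], i, trans_idx)
  pair_idx <- new.env(parent = emptyenv())
  for (i in seq_along(net$places)) assign(net$places[i], i, pair_idx)
  rt <- list(trans_idx = trans_idx, pair_idx = pair_idx,
             t_in = net$trans_in, t_out = net$trans_out,
             P = length(net$places),
             init = as.numeric(net$initial_marking))
  rt
}

# core token replay; times in days; fires events [1..upto]
# Consumption: the place of the directly-preceding pair when marked, else
# the first marked input place, else a missing-token insertion (counted,
# and itself a token arrival). Production: one token into every output
# place. Under this rule a log replays at threshold 1 with zero
# insertions.
replay_events <- function(net, names, times_days, upto = length(names),
                          track_gaps = FALSE, rt = net_runtime(net)) {
  P <- rt$P
  marking <- rt$init
  count <- numeric(P)
  t_last <- rep(NA_real_, P)
  miss <- 0L
  maxgap <- if (track_gaps) rep(-Inf, P) else NULL

  arrive <- function(p, tm) {
    if (track_gaps && !is.na(t_last[p])) {
      g <- tm - t_last[p]
      if (g > maxgap[p]) maxgap[p] <<- g
    }
    count[p] <<- count[p] + 1
    t_last[p] <<- tm
  }

  fire <- function(ti, tm, prev_label, label) {
    ins <- rt$t_in[[ti]]
    pp <- get0(place_name(prev_label, label), rt$pair_idx,
               ifnotfound = NA_integer_)
    if (!is.na(pp) && marking[pp] > 0) {
      marking[pp] <<- marking[pp] - 1
    } else {
      marked <- ins[marking[ins] > 0]
      if (length(marked)) {
        marking[marked[1L]] <<- marking[marked[1L]] - 1
      } else {
        miss <<- miss + 1L
        tgt <- if (!is.na(pp)) pp else ins[1L]
        arrive(tgt, tm)  # inserted token arrives and is consumed at once
      }
    }
    outs <- rt$t_out[[ti]]
    for (p in outs) arrive(p, tm)
    marking[outs] <<- marking[outs] + 1
  }

  if (upto < 1L) stop_config("nothing to replay")
  t0 <- times_days[1L] - MS / DAY_S
  start_t <- get0("START", rt$trans_idx, ifnotfound = NA_integer_)
  # externally mined nets may have no explicit START transition; the
  # initially marked place then feeds the first event directly
  if (!is.na(start_t)) fire(start_t, t0, NA_character_, "START")
  prev <- "START"
  other <- get0("OTHER", rt$trans_idx)
  for (i in seq_len(upto)) {
    ti <- get0(names[i], rt$trans_idx, ifnotfound = NA_integer_)
    label <- names[i]
    if (is.na(ti)) {
      if (is.na(other)) stop_invariant(
        "event name '%s' unknown to the net and no OTHER transition", names[i])
      ti <- other
      label <- "OTHER"
    }
    fire(ti, times_days[i], prev, label)
    prev <- label
  }
  list(marking = marking, count = count, t_last = t_last, miss = miss,
       maxgap = maxgap, taken_at = times_days[upto])
}

#' Estimate per-place decay rates from the training log
#'
#' Replays every training trace and sets `alpha_p = beta / D_p`, where
#' `D_p` is the maximum observed within-trace inter-arrival time of tokens
#' at place `p` (in days). Places never re-activated in any trace use the
#' maximum trace duration as `D_p`.
#'
#' @param net a `petri_net`.
#' @param log a `hf_event_log` (training traces).
#' @param beta decay reactivation value (default 1).
#' @return Named numeric vector of positive finite decay rates, one per
#'   place (units: `beta` per day).
#' @export
estimate_decay_rates <- function(net, log, beta = 1) {
  traces <- log_traces(log)
  P <- length(net$places)
  rt <- net_runtime(net)
  maxgap <- rep(-Inf, P)
  maxdur <- 0
  for (tr in traces) {
    td <- tr$timestamps / DAY_S
    r <- replay_events(net, tr$names, td, track_gaps = TRUE, rt = rt)
    maxgap <- pmax(maxgap, r$maxgap)
    maxdur <- max(maxdur, td[length(td)] - td[1L])
  }
  if (maxdur <= 0) stop_config("zero-duration log: cannot estimate decay rates")
  D <- ifelse(is.finite(maxgap) & maxgap > 0, maxgap, maxdur)
  alphas <- stats::setNames(beta / D, net$places)
  stopifnot(all(is.finite(alphas)), all(alphas > 0))
  alphas
}

#' Replay one trace to its Timed State Sample
#'
#' Fires the labeled transition of every event up to and including the
#' TSS marker, in timestamp order; event names outside the net vocabulary
#' route to the OTHER transition; a transition that is not enabled causes
#' a counted missing-token insertion. The sample is captured at the marker
#' timestamp, before any later event can touch the state.
#'
#' @param net a `petri_net`.
#' @param trace list with `names`, `timestamps` (seconds) and `tss_index`.
#' @param alphas named decay-rate vector from [estimate_decay_rates()].
#' @param beta decay reactivation value (default 1).
#' @param rt precomputed replay lookup structures; pass one
#'   `net_runtime(net)` when replaying many traces on the same net.
#' @return A `timed_state_sample`: `decay_values`, `token_counts`,
#'   `marking`, `taken_at` (seconds), `missing_token_insertions`.
#' @export
replay_to_tss <- function(net, trace, alphas, beta = 1, rt = net_runtime(net)) {
  k <- trace$tss_index
  if (is.null(k) || is.na(k) || k < 1L || k > length(trace$names))
    stop_config("trace lacks a valid TSS marker")
  r <- replay_events(net, trace$names, trace$timestamps / DAY_S, upto = k,
                     rt = rt)
  decay <- ifelse(is.na(r$t_last), 0,
                  pmax(0, beta - alphas[net$places] * (r$taken_at - r$t_last)))
  structure(list(
    decay_values = stats::setNames(as.numeric(decay), net$places),
    token_counts = stats::setNames(r$count, net$places),
    marking = stats::setNames(r$marking, net$places),
    taken_at = ms_round(r$taken_at * DAY_S),
    missing_token_insertions = r$miss), class = "timed_state_sample")
}

#' Timed-state-sample feature matrix for an event log
#'
#' One row per trace: `[decay values | token counts | marking]`, columns in
#' the net's canonical place order. Optional per-column min-max
#' normalization; fit the parameters on the training matrix and pass them
#' via `norm` for validation/test data (values outside `[0,1]` are allowed,
#' never `NaN`).
#'
#' @param log a `hf_event_log`.
#' @param net a `petri_net`.
#' @param alphas decay rates from [estimate_decay_rates()].
#' @param normalize logical; min-max normalize columns.
#' @param norm normalization parameters from a previous call (attribute
#'   `"norm"` of its result); `NULL` fits on this log.
#' @param components which state components to include.
#' @return Numeric matrix with attributes `"norm"` (parameters) and
#'   `"component"` (per-column component tag).
#' @export
tss_matrix <- function(log, net, alphas, normalize = FALSE, norm = NULL,
                       components = c("decay", "count", "marking")) {
  traces <- log_traces(log)
  P <- length(net$places)
  rt <- net_runtime(net)
  rows <- lapply(traces, function(tr) {
    s <- replay_to_tss(net, tr, alphas, rt = rt)
    c(if ("decay" %in% components) s$decay_values,
      if ("count" %in% components) s$token_counts,
      if ("marking" %in% components) s$marking)
  })
  X <- do.call(rbind, rows)
  tags <- c(if ("decay" %in% components) rep("decay", P),
            if ("count" %in% components) rep("count", P),
            if ("marking" %in% components) rep("marking", P))
  colnames(X) <- paste0(tags, ":", rep(net$places, length.out = ncol(X)))
  rownames(X) <- as.character(log$cases$case_id)
  if (normalize) {
    if (is.null(norm)) {
      lo <- apply(X, 2L, min)
      hi <- apply(X, 2L, max)
      rng <- ifelse(hi > lo, hi - lo, 1)
      norm <- list(lo = lo, rng = rng)
    }
    X <- sweep(sweep(X, 2L, norm$lo), 2L, norm$rng, "/")
  }
  attr(X, "norm") <- norm
  attr(X, "component") <- tags
  X
}
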