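# Decay replay: rate estimation rules, hand-checked decay values, oracle
# equivalence on toy nets, anti-leakage and the TSS matrix contract.

toy_log <- function(names, days, case = 1, tss = length(names)) {
  structure(list(
    events = data.frame(case_id = case, name = names, timestamp = days * DAY),
    cases = data.frame(case_id = case, label = FALSE, tss_index = tss)),
    class = "hf_event_log")
}

test_that("decay rates: alpha = beta / max inter-arrival, with trace-duration fallback", {
  # A fires at day 0 and day 10 -> place p:A>B sees arrivals 10 days apart
  log <- toy_log(c("A", "B", "A", "B"), c(0, 5, 10, 50))
  net <- discover_petri_net(log)
  al <- estimate_decay_rates(net, log)
  expect_equal(unname(al["p:A>B"]), 1 / 10)
  # p:START>A is hit once per trace -> fallback to max trace duration (50 d)
  expect_equal(unname(al["p:START>A"]), 1 / 50)
  expect_true(all(is.finite(al) & al > 0))

  # a zero-duration log cannot calibrate decay
  zl <- toy_log("A", 0, tss = 1)
  znet <- discover_petri_net(zl)
  expect_error(estimate_decay_rates(znet, zl), class = "dreamHF_config_error")
})

test_that("decay equals beta at the arrival instant and follows the hand computation", {
  log <- toy_log(c("A", "B"), c(0, 5))
  net <- discover_petri_net(log)
  al <- setNames(rep(0.1, length(net$places)), net$places)
  s <- replay_to_tss(net, dreamHF:::log_traces(log)[[1]], al)
  # p:A>B last refreshed when A fired at t=0; captured at t=5 d
  expect_equal(unname(s$decay_values["p:A>B"]), max(0, 1 - 0.1 * 5))
  # p:B>END refreshed by B at the capture instant
  expect_equal(unname(s$decay_values["p:B>END"]), 1)
  expect_equal(s$missing_token_insertions, 0L)
  expect_equal(s$taken_at, 5 * DAY)
})

test_that("TSS is identical whether the trace is truncated at the marker or not", {
  sp <- small_pipeline()
  traces <- dreamHF:::log_traces(sp$log)
  tr <- traces[[1]]
  rt <- dreamHF:::net_runtime(sp$net)
  base <- replay_to_tss(sp$net, tr, sp$alphas, rt = rt)
  set.seed(1)
  for (i in 1:10) {
    extra <- sample(c(sp$net$transitions, "UNSEEN_EVENT"), sample(1:4, 1),
                    replace = TRUE)
    tr2 <- list(names = c(tr$names, extra),
                timestamps = c(tr$timestamps,
                               tr$timestamps[length(tr$timestamps)] +
                                 seq_along(extra) * DAY),
                tss_index = tr$tss_index)
    s2 <- replay_to_tss(sp$net, tr2, sp$alphas, rt = rt)
    expect_identical(s2, base)
  }
})

test_that("replay matches the brute-force oracle on random toy nets", {
  n_checked <- 0
  for (seed in 1:12) {
    log <- random_toy_log(12, c("A", "B", "C"), seed = seed)
    net <- discover_petri_net(log, frequency_threshold = sample(1:2, 1))
    al <- setNames(runif(length(net$places), 0.001, 0.2), net$places)
    rt <- dreamHF:::net_runtime(net)
    for (tr in dreamHF:::log_traces(log)) {
      nm <- tr$names
      # sprinkle unseen names to exercise the OTHER route
      if (runif(1) < 0.3) nm[sample(length(nm), 1)] <- "ZZZ"
      k <- sample(seq_along(nm), 1)
      s <- replay_to_tss(net, list(names = nm, timestamps = tr$timestamps,
                                   tss_index = k), al, rt = rt)
      o <- oracle_replay_tss(net, nm, tr$timestamps, k, as.list(al))
      expect_equal(unname(s$decay_values), o$decay, tolerance = 1e-12)
      expect_equal(unname(s$token_counts), o$count)
      expect_equal(unname(s$marking), o$marking)
      expect_equal(s$missing_token_insertions, o$miss)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("decay values stay in [0, beta] and decrease monotonically between arrivals", {
  for (seed in 1:5) {
    log <- random_toy_log(8, c("A", "B", "C"), seed = seed)
    net <- discover_petri_net(log)
    al <- estimate_decay_rates(net, log)
    rt <- dreamHF:::net_runtime(net)
    for (tr in dreamHF:::log_traces(log)) {
      prev <- NULL
      for (k in seq_along(tr$names)) {
        s <- replay_to_tss(net, list(names = tr$names,
                                     timestamps = tr$timestamps,
                                     tss_index = k), al, rt = rt)
        expect_true(all(s$decay_values >= 0 & s$decay_values <= 1))
        if (!is.null(prev)) {
          # places with no token arrival since the previous capture can
          # only have decayed further
          same <- s$token_counts == prev$token_counts
          expect_true(all(s$decay_values[same] <=
                            prev$decay_values[same] + 1e-12))
        }
        prev <- s
      }
    }
  }
})

test_that("tss_matrix concatenates the state components with stable geometry", {
  sp <- small_pipeline()
  log <- build_event_log(sp$tables, sp$split$validation, sp$art)
  P <- length(sp$net$places)
  X <- tss_matrix(log, sp$net, sp$alphas)
  expect_equal(ncol(X), 3 * P)
  expect_equal(nrow(X), nrow(log$cases))
  expect_equal(attr(X, "component"),
               rep(c("decay", "count", "marking"), each = P))
  Xd <- tss_matrix(log, sp$net, sp$alphas, components = "decay")
  expect_equal(ncol(Xd), P)
  expect_true(all(Xd >= 0 & Xd <= 1))

  # normalization fit on train, applied elsewhere: finite, never NaN,
  # values outside [0,1] allowed
  Xtr <- tss_matrix(sp$log, sp$net, sp$alphas, normalize = TRUE)
  Xva <- tss_matrix(log, sp$net, sp$alphas, normalize = TRUE,
                    norm = attr(Xtr, "norm"))
  expect_true(all(is.finite(Xva)))
  expect_true(all(Xtr >= 0 & Xtr <= 1))

  # permuting traces permutes rows only
  log2 <- log
  o <- rev(seq_len(nrow(log$cases)))
  # reverse case blocks by rebuilding from traces
  trs <- dreamHF:::log_traces(log)[o]
  log2$events <- do.call(rbind, lapply(trs, function(tr)
    data.frame(case_id = tr$case_id, name = tr$names, timestamp = tr$timestamps)))
  log2$cases <- log$cases[o, ]
  X2 <- tss_matrix(log2, sp$net, sp$alphas)
  expect_equal(X2[rownames(X), ], X[, ], ignore_attr = TRUE)

  # a trace without a marker is refused
  bad <- dreamHF:::log_traces(log)[[1]]
  bad$tss_index <- NA_integer_
  expect_error(replay_to_tss(sp$net, bad, sp$alphas),
               class = "dreamHF_config_error")
})
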