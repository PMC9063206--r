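# Directly-follows discovery, structural invariants and PNML round trips.

two_step_log <- function() {
  log <- list(
    events = data.frame(case_id = 1, name = c("A", "B"),
                        timestamp = c(0, 5) * DAY),
    cases = data.frame(case_id = 1, label = TRUE, tss_index = 2L))
  class(log) <- "hf_event_log"
  log
}

test_that("a one-trace log yields the minimal source -> A -> B -> sink net", {
  net <- discover_petri_net(two_step_log())
  expect_setequal(net$places,
                  c("p_source", "p_sink", "p:OTHER", "p:START>A", "p:A>B",
                    "p:B>END"))
  expect_setequal(net$transitions, c("START", "END", "OTHER", "A", "B"))
  # replay moves the token source -> p(A,B) -> consumed by B, zero insertions
  al <- setNames(rep(1, length(net$places)), net$places)
  s <- replay_to_tss(net, list(names = c("A", "B"),
                               timestamps = c(0, 5) * DAY, tss_index = 2L), al)
  expect_equal(s$missing_token_insertions, 0L)
  expect_equal(unname(s$token_counts["p:A>B"]), 1)
  expect_equal(unname(s$marking["p:A>B"]), 0)   # consumed by B
  expect_equal(unname(s$marking["p:B>END"]), 1)
})

test_that("pairs below the frequency threshold lose their place", {
  ev <- rbind(
    data.frame(case_id = 1, name = c("A", "B", "C"), timestamp = c(1, 2, 3) * DAY),
    data.frame(case_id = 2, name = c("A", "B", "C"), timestamp = c(1, 2, 3) * DAY),
    data.frame(case_id = 3, name = c("A", "C"), timestamp = c(1, 2) * DAY))
  log <- structure(list(events = ev,
                        cases = data.frame(case_id = 1:3, label = FALSE,
                                           tss_index = c(3L, 3L, 2L))),
                   class = "hf_event_log")
  net1 <- discover_petri_net(log, frequency_threshold = 1)
  expect_true("p:A>C" %in% net1$places)
  net2 <- discover_petri_net(log, frequency_threshold = 2)
  expect_false("p:A>C" %in% net2$places)
  # every transition still has input and output places (orphan rescue)
  expect_true(all(lengths(net2$trans_in) >= 1))
  expect_true(all(lengths(net2$trans_out) >= 1))
})

test_that("discovery is deterministic and structurally sound", {
  sp <- small_pipeline()
  n1 <- discover_petri_net(sp$log)
  n2 <- discover_petri_net(sp$log)
  expect_identical(n1[c("places", "transitions", "arcs", "initial_marking")],
                   n2[c("places", "transitions", "arcs", "initial_marking")])
  # bipartite: every arc joins a place and a transition
  from_place <- n1$arcs$from %in% n1$places
  to_place <- n1$arcs$to %in% n1$places
  expect_true(all(xor(from_place, to_place)))
  expect_equal(sum(n1$initial_marking), 1L)
  expect_equal(unname(n1$initial_marking["p_source"]), 1L)
})

test_that("training traces replay with zero insertions at threshold 1", {
  for (seed in 1:3) {
    log <- random_toy_log(15, c("A", "B", "C"), seed = seed)
    net <- discover_petri_net(log, frequency_threshold = 1)
    al <- setNames(rep(0.01, length(net$places)), net$places)
    rt <- dreamHF:::net_runtime(net)
    for (i in seq_len(nrow(log$cases))) {
      tr <- dreamHF:::log_traces(log)[[i]]
      s <- replay_to_tss(net, tr, al, rt = rt)
      expect_equal(s$missing_token_insertions, 0L)
    }
  }
})

test_that("PNML round trip reproduces the net and its decay annotations", {
  sp <- small_pipeline()
  f <- withr::local_tempfile(fileext = ".pnml")
  write_pnml(sp$net, f, alphas = sp$alphas)
  back <- read_pnml(f)
  expect_identical(back$places, sp$net$places)
  expect_identical(back$transitions, sp$net$transitions)
  expect_equal(back$arcs, sp$net$arcs, ignore_attr = TRUE)
  expect_equal(unname(back$initial_marking), unname(sp$net$initial_marking))
  expect_equal(attr(back, "alphas"), sp$alphas, tolerance = 1e-12)

  # a net whose marking was stripped is refused by the writer
  bad <- sp$net
  bad$initial_marking[] <- 0L
  expect_error(write_pnml(bad, f), class = "dreamHF_invariant_error")
  # malformed PNML is a format error
  writeLines("<pnml><net>", f)
  expect_error(read_pnml(f), class = "dreamHF_format_error")
})

test_that("an externally mined PNML fixture loads and replays", {
  net <- read_pnml(test_path("fixtures", "external_miner_net.pnml"))
  expect_setequal(net$transitions, c("A", "B"))
  expect_equal(net$source_place, "start")
  al <- setNames(rep(0.1, length(net$places)), net$places)
  s <- replay_to_tss(net, list(names = c("A", "B"),
                               timestamps = c(0, 2) * DAY, tss_index = 2L), al)
  # A consumes the start token, B the between token; end holds one token
  expect_equal(unname(s$marking[net$places == "end"]), 1)
  expect_equal(s$missing_token_insertions, 0L)
  expect_equal(unname(s$decay_values[net$places == "end"]), 1)
})
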