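# PNML (ISO/IEC 15909-2) place/transition net serialization. Decay rates
# fitted by estimate_decay_rates() can ride along as a tool-specific
# annotation so a net and its replay parameters form one artifact.

#' Write a Petri net as PNML
#'
#' @param net a `petri_net`.
#' @param path output file.
#' @param alphas optional named per-place decay-rate vector (stored as a
#'   `<toolspecific>` annotation).
#' @return `path`, invisibly.
#' @export
write_pnml <- function(net, path, alphas = NULL) {
  if (is.null(net$initial_marking) || sum(net$initial_marking) < 1L)
    stop_invariant("net lacks an initial marking")
  p_id <- stats::setNames(sprintf("p%d", seq_along(net$places)), net$places)
  t_id <- stats::setNames(sprintf("t%d", seq_along(net$transitions)),
                          net$transitions)
  place_xml <- sprintf(
    '      <place id="%s"><name><text>%s</text></name>%s</place>',
    p_id, xml_escape(net$places),
    ifelse(net$initial_marking > 0,
           sprintf('<initialMarking><text>%d</text></initialMarking>',
                   net$initial_marking), ""))
  trans_xml <- sprintf(
    '      <transition id="%s"><name><text>%s</text></name></transition>',
    t_id, xml_escape(net$transitions))
  all_id <- c(p_id, t_id)
  arc_xml <- sprintf('      <arc id="a%d" source="%s" target="%s"/>',
                     seq_len(nrow(net$arcs)),
                     all_id[net$arcs$from], all_id[net$arcs$to])
  tool_xml <- character(0)
  if (!is.null(alphas)) {
    tool_xml <- c('      <toolspecific tool="dreamHF" version="1.0">',
                  sprintf('        <decay place="%s" alpha="%.17g"/>',
                          p_id[names(alphas)], as.numeric(alphas)),
                  '      </toolspecific>')
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">',
    '  <net id="net1" type="http://www.pnml.org/version-2009/grammar/ptnet">',
    '    <page id="page1">',
    place_xml, trans_xml, arc_xml, tool_xml,
    '    </page>', '  </net>', '</pnml>'), path)
  invisible(path)
}

#' Read a PNML Petri net
#'
#' Reads nets written by [write_pnml()] as well as externally mined
#' place/transition PNML; node labels are taken from `<name><text>`,
#' falling back to ids. The source place is the marked place; the sink is
#' a place without outgoing arcs.
#'
#' @param path PNML file.
#' @return A `petri_net`; any stored decay rates are attached as attribute
#'   `"alphas"`.
#' @export
read_pnml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_format("malformed PNML: %s",
                                                  conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  pl <- xml2::xml_find_all(doc, ".//place")
  tr <- xml2::xml_find_all(doc, ".//transition")
  ar <- xml2::xml_find_all(doc, ".//arc")
  if (length(pl) == 0L || length(tr) == 0L)
    stop_format("PNML contains no places or no transitions")
  node_label <- function(nodes) {
    lab <- xml2::xml_text(xml2::xml_find_first(nodes, "./name/text"))
    id <- xml2::xml_attr(nodes, "id")
    ifelse(is.na(lab) | lab == "", id, lab)
  }
  p_label <- node_label(pl)
  t_label <- node_label(tr)
  p_ids <- xml2::xml_attr(pl, "id")
  t_ids <- xml2::xml_attr(tr, "id")
  mark_txt <- xml2::xml_text(xml2::xml_find_first(pl, "./initialMarking/text"))
  marking <- stats::setNames(ifelse(is.na(mark_txt), 0L, as.integer(mark_txt)),
                             p_label)
  if (sum(marking) < 1L) stop_format("PNML net lacks an initial marking")
  id2label <- stats::setNames(c(p_label, t_label), c(p_ids, t_ids))
  arcs <- data.frame(from = unname(id2label[xml2::xml_attr(ar, "source")]),
                     to = unname(id2label[xml2::xml_attr(ar, "target")]),
                     stringsAsFactors = FALSE)
  if (anyNA(arcs$from) || anyNA(arcs$to))
    stop_format("PNML arc references an unknown node id")
  has_out <- p_label %in% arcs$from
  sink <- p_label[!has_out][1L]
  source <- p_label[marking > 0][1L]
  net <- new_petri_net(p_label, t_label, arcs, marking,
                       source_place = source, sink_place = sink)
  tool <- xml2::xml_find_all(doc, './/toolspecific[@tool="dreamHF"]/decay')
  if (length(tool)) {
    a_pid <- xml2::xml_attr(tool, "place")
    alphas <- stats::setNames(as.numeric(xml2::xml_attr(tool, "alpha")),
                              unname(id2label[a_pid]))
    attr(net, "alphas") <- alphas[net$places]
  }
  net
}
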