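# Grouped Monte-Carlo Shapley attribution. Features are partitioned into
# the six variable families (severity scores, admission events,
# demographics, artificial events, comorbidity events, lab measurement
# events); masked groups are imputed with training means. Contributions
# telescope exactly, so per-instance efficiency
# sum_g phi_g = f(x) - f(baseline) holds for every sampled permutation.

#' Grouped Monte-Carlo Shapley values
#'
#' @param predict_fun function mapping a feature matrix to a numeric score
#'   vector.
#' @param X instance matrix (rows = instances to explain).
#' @param groups named list of column-index vectors partitioning
#'   `1:ncol(X)`.
#' @param baseline per-column imputation values for masked groups
#'   (typically training means).
#' @param n_perm number of sampled group permutations.
#' @param seed RNG seed.
#' @return Data frame with one row per group: `mean_abs` (mean absolute
#'   contribution across instances), `mean_signed`, and `mc_se` (Monte
#'   Carlo standard error of `mean_abs` across permutations). The raw
#'   per-instance contribution matrix is attached as attribute `"phi"`.
#' @export
grouped_shapley <- function(predict_fun, X, groups, baseline,
                            n_perm = 50, seed = 1) {
  idx <- sort(unlist(groups))
  if (!identical(as.integer(idx), seq_len(ncol(X))))
    stop_config("groups must partition the feature columns")
  G <- length(groups)
  n <- nrow(X)
  base_mat <- matrix(baseline, n, ncol(X), byrow = TRUE)
  phi <- matrix(0, n, G, dimnames = list(NULL, names(groups)))
  per_perm <- matrix(0, n_perm, G, dimnames = list(NULL, names(groups)))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(G)
      cur <- base_mat
      f_prev <- predict_fun(cur)
      contrib <- matrix(0, n, G)
      for (g in ord) {
        cols <- groups[[g]]
        cur[, cols] <- X[, cols]
        f_new <- predict_fun(cur)
        contrib[, g] <- f_new - f_prev
        f_prev <- f_new
      }
      phi <- phi + contrib
      per_perm[r, ] <- colMeans(abs(contrib))
    }
  })
  phi <- phi / n_perm
  data.frame(
    group = names(groups),
    mean_abs = colMeans(abs(phi)),
    mean_signed = colMeans(phi),
    mc_se = apply(per_perm, 2L, stats::sd) / sqrt(n_perm),
    row.names = NULL)
}

#' Feature-family partition for the combined model input
#'
#' Maps the concatenated `[tss | demographics | severity]` columns to the
#' six variable families used for attribution. TSS columns are assigned by
#' the source event of their place (the transition whose firing refreshes
#' the place); careflow skeleton places (START/END/OTHER, the
#' source/sink, and discharge-fed pairs) count as admission events.
#'
#' @param net a `petri_net`.
#' @param tss_cols TSS column names (from [tss_matrix()]).
#' @param demo_cols,sev_cols demographics / severity column names.
#' @return Named list of column indices over the concatenated matrix, in
#'   the order tss, demographics, severity.
#' @export
feature_groups <- function(net, tss_cols, demo_cols, sev_cols) {
  src <- sub("^(decay|count|marking):", "", tss_cols)
  src <- sub("^p:", "", src)
  src <- sub(">.*$", "", src)
  fam <- function(s) {
    if (startsWith(s, "Elix_")) "comorbidity_events"
    else if (startsWith(s, "Artificial_")) "artificial_events"
    else if (grepl("_(mean|std)$", s)) "lab_events"
    else "admission_events"  # Admission_/Insurance_/Discharge + skeleton
  }
  tss_fam <- vapply(src, fam, character(1))
  n_tss <- length(tss_cols)
  groups <- list(
    severity = n_tss + length(demo_cols) + seq_along(sev_cols),
    admission_events = which(tss_fam == "admission_events"),
    demographics = n_tss + seq_along(demo_cols),
    artificial_events = which(tss_fam == "artificial_events"),
    comorbidity_events = which(tss_fam == "comorbidity_events"),
    lab_events = which(tss_fam == "lab_events"))
  groups[lengths(groups) > 0L]
}

#' Shapley attribution for a trained three-branch model
#'
#' Convenience wrapper: explains `predict.dream_nn` on a test bundle with
#' the six-family partition and training-mean imputation.
#'
#' @param model a trained `dream_nn`.
#' @param net the `petri_net` behind the TSS columns.
#' @param train,test `feature_bundle` lists.
#' @param n_perm,seed passed to [grouped_shapley()].
#' @return The [grouped_shapley()] data frame.
#' @export
model_shapley <- function(model, net, train, test, n_perm = 30, seed = 1) {
  splitx <- function(b) cbind(as.matrix(b$tss), as.matrix(b$demographics),
                              as.matrix(b$severity))
  Xtr <- splitx(train)
  Xte <- splitx(test)
  d_tss <- ncol(test$tss); d_demo <- ncol(test$demographics)
  groups <- feature_groups(net, colnames(test$tss),
                           colnames(test$demographics),
                           colnames(test$severity))
  pf <- function(M) predict(model, list(
    tss = M[, seq_len(d_tss), drop = FALSE],
    demographics = M[, d_tss + seq_len(d_demo), drop = FALSE],
    severity = M[, (d_tss + d_demo + 1):ncol(M), drop = FALSE]))
  grouped_shapley(pf, Xte, groups, baseline = colMeans(Xtr),
                  n_perm = n_perm, seed = seed)
}
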