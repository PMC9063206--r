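# Artificial event abstraction: each admission's ordered ICD-9 procedure +
# CPT code sequence is hashed into an n-gram count vector and clustered
# (k-means, k = 30). The cluster id becomes a synthetic event for that
# admission. The vectorizer/cluster strategy is deliberately replaceable:
# anything that maps a code sequence to one of k names fits the interface.

token_hash <- function(s, dim) {
  cache <- .dhf$hash_cache
  if (is.null(cache)) cache <- .dhf$hash_cache <- new.env(parent = emptyenv())
  key <- paste0(dim, "#", s)
  h <- cache[[key]]
  if (is.null(h)) {
    v <- utf8ToInt(s)
    h <- 0
    for (c in v) h <- (h * 31 + c) %% 1048576
    h <- as.integer(h %% dim) + 1L
    cache[[key]] <- h
  }
  h
}

# hashed bag of 1-grams and 2-grams
featurize_code_seqs <- function(seqs, dim = 256L) {
  X <- matrix(0, length(seqs), dim)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (length(s) == 0L) next
    toks <- s
    if (length(s) > 1L)
      toks <- c(toks, paste(s[-length(s)], s[-1L], sep = ">"))
    idx <- vapply(toks, token_hash, integer(1), dim = dim)
    X[i, ] <- tabulate(idx, nbins = dim)
  }
  X
}

# ordered concatenation of ICD-9 procedure codes (by SEQ_NUM) and CPT codes
# (by chart time) for each admission
admission_code_seqs <- function(tables, hadm_ids) {
  pr <- tables$procedures_icd
  pr <- pr[pr$HADM_ID %in% hadm_ids, ]
  pr <- pr[order(pr$HADM_ID, pr$SEQ_NUM), ]
  cp <- tables$cptevents
  cp <- cp[cp$HADM_ID %in% hadm_ids, ]
  cp <- cp[order(cp$HADM_ID, cp$CHARTTIME), ]
  pr_by <- split(as.character(pr$ICD9_CODE), pr$HADM_ID)
  cp_by <- split(as.character(cp$CPT_CD), cp$HADM_ID)
  out <- lapply(as.character(hadm_ids), function(h)
    c(pr_by[[h]], cp_by[[h]]))
  names(out) <- as.character(hadm_ids)
  out
}

#' Fit the artificial-event abstraction model
#'
#' Vectorizes each training admission's ordered procedure/CPT code sequence
#' (hashed 1-gram + 2-gram counts, dimension `dim`) and clusters the
#' vectors with k-means into `k` clusters (default 30). Must be fitted on
#' the training cohort only.
#'
#' @param tables an `ehr_tables` object.
#' @param cohort training-cohort members ([select_cohort()] /
#'   [split_cohort()]).
#' @param k number of clusters (>= 2; reduced with a warning if fewer
#'   distinct sequences exist).
#' @param seed RNG seed (k-means initialization).
#' @param dim hashing dimension.
#' @return An `artificial_event_model` (centroids + vectorizer
#'   parameters).
#' @export
fit_artificial_events <- function(tables, cohort, k = 30, seed = 1, dim = 256L) {
  if (k < 2) stop_config("k must be >= 2")
  if (nrow(cohort) == 0L) stop_config("training cohort is empty")
  hadm <- unlist(c(cohort$prior_admission_ids, cohort$index_admission_id))
  seqs <- admission_code_seqs(tables, hadm)
  seqs <- seqs[lengths(seqs) > 0L]
  if (length(seqs) == 0L) stop_config("no admission has any procedure/CPT code")
  X <- featurize_code_seqs(seqs, dim)
  Xu <- unique(X)
  k_eff <- min(k, nrow(Xu))
  if (k_eff < k)
    warning(sprintf("only %d distinct code-sequence vectors; k reduced from %d to %d",
                    nrow(Xu), k, k_eff))
  km <- if (k_eff == nrow(Xu)) {
    # every distinct vector is its own centroid
    stats::kmeans(X, centers = Xu, iter.max = 100)
  } else {
    with_seed(seed, stats::kmeans(X, centers = k_eff, nstart = 10, iter.max = 100))
  }
  structure(list(centroids = km$centers, dim = dim, k = k_eff,
                 fitted_on = length(seqs)),
            class = "artificial_event_model")
}

# nearest-centroid assignment; NA for empty sequences
predict_artificial_clusters <- function(model, seqs) {
  out <- rep(NA_integer_, length(seqs))
  keep <- lengths(seqs) > 0L
  if (!any(keep)) return(out)
  X <- featurize_code_seqs(seqs[keep], model$dim)
  C <- model$centroids
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  out[keep] <- max.col(-d2, ties.method = "first")
  out
}
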