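# shared internal helpers: time arithmetic, seeding, errors, fast AUROC

MS <- 1e-3          # one millisecond, in seconds
DAY_S <- 86400      # seconds per day

# quantize to the millisecond grid so offset arithmetic and serialization
# round-trip exactly
ms_round <- function(x) round(x * 1000) / 1000

num_to_iso <- function(x) {
  t <- as.POSIXct(round(x, 3), origin = "1970-01-01", tz = "UTC")
  format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

iso_to_num <- function(s) {
  t <- as.POSIXct(as.character(s), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  # plain "YYYY-MM-DD HH:MM:SS" also accepted
  alt <- is.na(t) & !is.na(s)
  if (any(alt)) {
    t[alt] <- as.POSIXct(as.character(s[alt]), format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  ms_round(as.numeric(t))
}

dhf_stop <- function(msg, class = "dreamHF_error", ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "dreamHF_error")))
}

stop_config <- function(msg, ...) dhf_stop(msg, "dreamHF_config_error", ...)
stop_format <- function(msg, ...) dhf_stop(msg, "dreamHF_format_error", ...)
stop_invariant <- function(msg, ...) dhf_stop(msg, "dreamHF_invariant_error", ...)

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Mann-Whitney AUROC with half credit for ties (used for per-epoch metrics
# and model selection; DeLong CIs live in auroc_delong())
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) dhf_stop("both classes required to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
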