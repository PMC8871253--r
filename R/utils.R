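# Internal helpers shared across modules.

# Moment-based sample statistics on a numeric vector (population convention;
# skewness/kurtosis defined as 0 for zero-variance input).
moment_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  }
  c(
    mean = m,
    variance = m2,
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3
  )
}

# Nearest-rank percentile: smallest x with at least p*n observations <= x.
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[pmax(1L, ceiling(p * length(s)))]
}

# Derive a bounded child seed from a parent seed and a stream index, so every
# stage consumes an independent, reproducible stream. Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483647
}

# Classification metrics from confusion counts; positive class = HTN.
confusion_metrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens,
    specificity = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    plr = if (!is.na(spec) && spec < 1) sens / (1 - spec) else Inf,
    nlr = if (!is.na(spec) && spec > 0) (1 - sens) / spec else Inf,
    accuracy = (tp + tn) / (tp + fp + tn + fn)
  )
}

# Confusion counts for score-vs-cutoff classification (score > cutoff -> HTN).
confusion_at_cutoff <- function(scores, labels, cutoff) {
  pred_htn <- scores > cutoff
  is_htn <- labels == "HTN"
  confusion_metrics(
    tp = sum(pred_htn & is_htn),
    fp = sum(pred_htn & !is_htn),
    tn = sum(!pred_htn & !is_htn),
    fn = sum(!pred_htn & is_htn)
  )
}

group_factor <- function(x) {
  factor(as.character(x), levels = c("NC", "HTN"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
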