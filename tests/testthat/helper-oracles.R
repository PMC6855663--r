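## Independent oracles and fixture builders used across the suite.

## Brute-force product-limit estimate by explicit subject bookkeeping:
## walk the distinct times in order, count events among the subjects still
## present (events leave first on ties), multiply the survival down, then
## drop the censored subjects at that time.
bruteKM <- function(time, event) {
  remaining <- data.frame(time = time, event = as.logical(event))
  s <- 1
  out <- data.frame(time = numeric(), survival = numeric())
  for (tt in sort(unique(time))) {
    atRisk <- nrow(remaining)
    d <- sum(remaining$time == tt & remaining$event)
    s <- s * (atRisk - d) / atRisk
    out <- rbind(out, data.frame(time = tt, survival = s))
    remaining <- remaining[remaining$time != tt, , drop = FALSE]
  }
  out
}

## Literal step-down definition of the Holm adjustment (double loop).
bruteHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 0
    for (j in seq_len(i)) best <- max(best, (m - j + 1) * p[o[j]])
    adj[o[i]] <- min(1, best)
  }
  adj
}

## Build a cohort whose animals have prescribed volumes on prescribed days
## (calliper triples are the volume's cube root on each axis, so the
## ellipsoid product reproduces the volume exactly).
cohortFromVolumes <- function(volumes, days, groups = NULL,
                              controlGroup = "control", fates = NULL) {
  if (is.null(groups)) groups <- rep("control", length(volumes))
  ids <- names(volumes) %||% sprintf("a%02d", seq_along(volumes))
  meas <- do.call(rbind, lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    d <- (6 * v / pi)^(1 / 3)
    data.frame(animal_id = ids[i], group = groups[i],
               day = days[seq_along(v)], length_mm = d, width_mm = d,
               height_mm = d, stringsAsFactors = FALSE)
  }))
  TumourCohort(meas, controlGroup = controlGroup, fates = fates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
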