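# Independent oracles used across the suite.  These restate the rules
# directly (brute force / closed form) and never call the implementation
# paths they check.

# brute-force points combiner: literal restatement of the combination rules
oracle_combine <- function(evid, engine = c("canvig", "auto")) {
  engine <- match.arg(engine)
  pts_of <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8,
              standalone = 8)
  benign <- c("BA1", "BS1", "BS3", "BP1", "BP3", "BP4", "BP6")
  p <- ifelse(evid$code %in% benign,
              -pts_of[evid$strength], pts_of[evid$strength])
  total <- sum(p)
  if ("BA1" %in% evid$code)
    return(list(category = "BV", total = total))
  is_path <- !(evid$code %in% benign)
  if (engine == "canvig" && sum(is_path) == 1 &&
      evid$code[is_path] == "PM2") {
    remaining <- total - p[evid$code == "PM2"]
    if (remaining <= -1) total <- remaining
  }
  cat5 <-
    if (total >= 10) "PV"
    else if (total >= 6) "LPV"
    else if (total >= 0) "VUS"
    else if (engine == "canvig" && total >= -5) "LBV"
    else if (engine == "auto" && total >= -6) "LBV"
    else "BV"
  if (engine == "canvig" && cat5 %in% c("LBV", "BV") && sum(is_path) >= 2)
    cat5 <- "VUS"
  list(category = cat5, total = total)
}

# cumulative probability-mass summation: smallest count whose Poisson CDF
# first reaches the confidence level
oracle_mtac <- function(af_threshold, allele_number, confidence = 0.95) {
  lambda <- af_threshold * allele_number
  k <- 0L
  cum <- exp(-lambda)
  while (cum < confidence) {
    k <- k + 1L
    cum <- cum + stats::dpois(k, lambda)
    if (k > 10 * lambda + 1000) stop("oracle runaway")
  }
  k
}

# closed-form Clopper-Pearson bounds via the beta quantile identity
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

# two evidence pools (6 elements each, distinct codes) for exhaustive
# subset enumeration through the combiners
oracle_pools <- function() {
  list(
    graded = evidence_table(
      evidence("PS3", "strong"), evidence("PM2", "supporting"),
      evidence("PP3", "supporting"), evidence("BS3", "strong"),
      evidence("BP4", "supporting"), evidence("BP1", "supporting")),
    extreme = evidence_table(
      evidence("PS4", "strong"), evidence("PM5", "moderate"),
      evidence("PP5", "very_strong"), evidence("BS1", "strong"),
      evidence("BP6", "strong"), evidence("BA1", "standalone"))
  )
}
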