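# Stress-response statistics: ROS reporter induction, survival fractions,
# NPN outer-membrane permeability, and the survival-permeability
# correlation.

#' log2 induction of a ROS reporter
#'
#' From size-normalized fluorescence ratios (FITC/FSC) measured at baseline
#' (t0) and after exposure (t1) in challenged (c) and non-challenged (nc)
#' cultures:
#' `log2( [(FITC/FSC)_t1,c / (FITC/FSC)_t1,nc] /
#'        [(FITC/FSC)_t0,c / (FITC/FSC)_t0,nc] )`.
#' The FSC normalization cancels any uniform rescaling of either channel.
#'
#' @param t1_challenged,t1_nonchallenged,t0_challenged,t0_nonchallenged the
#'   four FITC/FSC ratios (all > 0). Alternatively pass a single data.frame
#'   as `t1_challenged` with columns `time` (`"t0"`/`"t1"`), `condition`
#'   (`"challenged"`/`"nonchallenged"`), `fitc`, `fsc` (4 rows).
#' @return the log2 induction value.
#' @export
log2_induction <- function(t1_challenged, t1_nonchallenged = NULL,
                           t0_challenged = NULL, t0_nonchallenged = NULL) {
  if (is.data.frame(t1_challenged)) {
    d <- t1_challenged
    need <- c("time", "condition", "fitc", "fsc")
    if (length(setdiff(need, names(d))) || nrow(d) != 4L)
      stop_config("flow table needs 4 rows with columns time, condition, fitc, fsc")
    pick <- function(tm, cond) {
      i <- d$time == tm & d$condition == cond
      if (sum(i) != 1L) stop_config("flow table must hold exactly one row per (time, condition)")
      d$fitc[i] / d$fsc[i]
    }
    return(log2_induction(pick("t1", "challenged"), pick("t1", "nonchallenged"),
                          pick("t0", "challenged"), pick("t0", "nonchallenged")))
  }
  r <- c(t1_challenged, t1_nonchallenged, t0_challenged, t0_nonchallenged)
  if (length(r) != 4L || any(!is.finite(r)) || any(r <= 0))
    stop_config("all four FITC/FSC ratios must be positive and finite")
  log2((r[1L] / r[2L]) / (r[3L] / r[4L]))
}

#' Survival fractions from CFU counts
#'
#' Survival at each time point is the CFU count divided by the initial count.
#' Raw zero counts are preserved in `fraction`; `fraction_floored` replaces
#' them with a plating detection floor (`floor_cfu / cfu[1]`) so that log-scale
#' plots stay finite.
#'
#' @param times time points (h), increasing, first entry is the baseline.
#' @param cfu colony-forming-unit counts (>= 0); `cfu[1] > 0` required.
#' @param floor_cfu detection floor in CFU equivalents (default 0.5).
#' @return data.frame (class `survival_series`): `time`, `cfu`, `fraction`,
#'   `fraction_floored`.
#' @export
survival_fraction <- function(times, cfu, floor_cfu = 0.5) {
  if (length(times) != length(cfu)) stop_config("times and cfu differ in length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_config("times must be strictly increasing")
  if (any(cfu < 0)) stop_config("CFU counts must be >= 0")
  if (!length(cfu) || cfu[1L] <= 0)
    stop_config("initial CFU count must be > 0")
  fr <- cfu / cfu[1L]
  frf <- pmax(cfu, floor_cfu) / cfu[1L]
  structure(data.frame(time = times, cfu = cfu, fraction = fr,
                       fraction_floored = frf),
            class = c("survival_series", "data.frame"))
}

#' NPN uptake
#'
#' Outer-membrane permeability proxy: NPN-derived fluorescence divided by the
#' optical density (OD595) of the resuspended culture.
#'
#' @param fluorescence NPN fluorescence (a.u., >= 0).
#' @param od optical density (> 0).
#' @return uptake value(s).
#' @export
npn_uptake <- function(fluorescence, od) {
  if (any(!is.finite(od)) || any(od <= 0))
    stop_config("OD must be positive and finite")
  fluorescence / od
}

# midranks (average rank for ties)
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of midranks. The two-sided p-value is
#' computed by exact enumeration of all permutations for n <= 8 without ties,
#' and otherwise by the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_config("x and y differ in length")
  if (n < 4L) stop_config("at least 4 observations are required")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_config("Spearman rho is undefined for a constant input")
  rx <- midrank(x); ry <- midrank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 8L && !ties) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(abs(tt), df = n - 2L, lower.tail = FALSE)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as a (n!) x n matrix; n <= 8 keeps this small
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Correlation between survival and outer-membrane permeability
#'
#' Aggregates replicate measurements to strain means and runs
#' [spearman_test()] on mean survival (conventionally the 5 h fraction under
#' 5 percent ethanol) versus mean NPN uptake.
#'
#' @param survival survival fractions, one per measurement.
#' @param uptake NPN uptake values, same length.
#' @param strain strain label per measurement; at least 4 distinct strains.
#' @return list with `rho`, `p_value`, `n` (strains), `method`, and the
#'   per-strain means in `means`.
#' @export
survival_permeability_correlation <- function(survival, uptake, strain) {
  if (length(survival) != length(uptake) || length(survival) != length(strain))
    stop_config("survival, uptake and strain must have equal length")
  ms <- tapply(survival, strain, mean)
  mu <- tapply(uptake, strain, mean)
  if (length(ms) < 4L) stop_config("at least 4 strains are required")
  res <- spearman_test(as.numeric(ms), as.numeric(mu))
  res$means <- data.frame(strain = names(ms), survival = as.numeric(ms),
                          uptake = as.numeric(mu), row.names = NULL)
  res
}
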