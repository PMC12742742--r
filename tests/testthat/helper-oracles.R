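# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and textbook formulas only.

# Enumerate every mutation of every TCS and apply the three scoring formulas
# one by one; rank by (Pscore desc, fbar desc, name).
oracle_priority <- function(mut, catalog, n_pop, n_lev, aggregate = "mean") {
  systems <- sort(unique(catalog$components$tcs))
  out <- data.frame(tcs = systems, fbar_score = NA_real_, n_mt = NA_integer_,
                    pscore = NA_real_)
  for (i in seq_along(systems)) {
    nm <- systems[i]
    genes <- catalog$components$gene[catalog$components$tcs == nm]
    fs <- numeric(0)
    for (g in genes) {
      d <- mut[mut$gene == g, , drop = FALSE]
      for (m in unique(d$mutation_id)) {
        recs <- d[d$mutation_id == m, , drop = FALSE]
        n <- length(unique(recs$population))
        cp <- switch(aggregate,
                     mean = mean(recs$frequency),
                     max = max(recs$frequency),
                     sum = sum(recs$frequency))
        fs <- c(fs, cp * n / n_pop)
      }
    }
    fbar <- if (length(fs)) sum(fs) / n_lev else 0
    reg <- catalog$regulon[catalog$regulon$tcs == nm, , drop = FALSE]
    nmt <- 0L
    for (tg in unique(reg$target)) {
      rr <- reg[reg$target == tg, , drop = FALSE]
      if (any(grepl("membrane", tolower(rr$cc), fixed = TRUE) &
              grepl("transport", tolower(rr$bp), fixed = TRUE)))
        nmt <- nmt + 1L
    }
    out$fbar_score[i] <- fbar
    out$n_mt[i] <- nmt
    out$pscore[i] <- fbar * nmt
  }
  ord <- order(-out$pscore, -out$fbar_score, out$tcs)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  out[ord, ]
}

# random small mutation dataset + catalog for oracle-equivalence checks
random_small_dataset <- function(seed, max_mutations = 50, max_tcs = 8) {
  set.seed(seed)
  n_tcs <- sample(2:max_tcs, 1)
  tcs <- sprintf("S%02d", seq_len(n_tcs))
  genes <- sprintf("g%02d", seq_len(2 * n_tcs + 4))
  comp <- data.frame(tcs = rep(tcs, each = 2),
                     gene = genes[seq_len(2 * n_tcs)],
                     role = rep(c("sensor", "regulator"), n_tcs))
  reg <- do.call(rbind, lapply(tcs, function(nm) {
    k <- sample(0:4, 1)
    if (!k) return(NULL)
    data.frame(tcs = nm, target = sprintf("%s_t%d", nm, seq_len(k)),
               cc = sample(c("outer membrane", "inner Membrane", "cytosol"), k, TRUE),
               bp = sample(c("ion Transport", "transporter activity", "glycolysis"), k, TRUE))
  }))
  if (is.null(reg)) reg <- data.frame(tcs = character(), target = character(),
                                      cc = character(), bp = character())
  n_mut <- sample(5:max_mutations, 1)
  pops <- sprintf("HT%d", 1:16)
  recs <- data.frame(gene = sample(genes, n_mut, TRUE),
                     population = sample(pops, n_mut, TRUE),
                     level = sample(1:7, n_mut, TRUE),
                     mutation_id = sprintf("m%02d", sample(1:12, n_mut, TRUE)),
                     frequency = round(runif(n_mut), 3))
  recs <- recs[!duplicated(recs[c("gene", "population", "level", "mutation_id")]), ]
  list(mutations = recs, catalog = tcs_catalog(comp, reg))
}

# textbook OLS slope t-test (n - 2 df), computed from sums only
oracle_slope_test <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  t <- b / se
  list(slope = b, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}

# rank-then-Pearson Spearman rho with midranks, from the covariance formula
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
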