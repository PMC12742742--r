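make_mut <- function(gene, population, level, mutation_id, frequency) {
  data.frame(gene = gene, population = population, level = level,
             mutation_id = mutation_id, frequency = frequency)
}

small_catalog <- function() {
  tcs_catalog(
    data.frame(tcs = c("A", "A", "B", "B"),
               gene = c("sA", "rA", "sB", "rB"),
               role = c("sensor", "regulator", "sensor", "regulator")),
    data.frame(tcs = c("A", "A", "A", "B"),
               target = c("t1", "t2", "t3", "t4"),
               cc = c("integral component of Membrane", "membrane", "membrane", "cytosol"),
               bp = c("transmembrane Transport", "ion transport", "proteolysis", "transport")))
}

test_that("mutation matrices aggregate all evolved mutations per gene", {
  pops <- sprintf("HT%d", 1:16)
  d <- make_mut("gA", pops, 1L, "m1", 0.5)
  pat <- build_mutation_matrices(d, populations = pops, levels = 1:7)
  expect_equal(pat$gA$global_count, 16)
  expect_equal(dim(pat$gA$pattern), c(16L, 7L))
  expect_equal(pat$gA$mean_occurrence, 16 / 7)

  # two distinct mutations in one gene in one population both contribute
  d2 <- make_mut("gA", "HT1", 1L, c("m1", "m2"), c(0.2, 0.9))
  pat2 <- build_mutation_matrices(d2)
  expect_equal(pat2$gA$global_count, 2)

  # empty dataset gives an empty collection
  expect_length(build_mutation_matrices(d2[0, ]), 0)

  # duplicate keys are rejected
  expect_error(build_mutation_matrices(rbind(d2, d2[1, ])), "duplicate")
})

test_that("mean-occurrence filter respects threshold and denominator", {
  d <- rbind(make_mut("gA", sprintf("HT%d", 1:8), 1L, "m1", 0.5),
             make_mut("gB", "HT1", 1L, "m1", 0.5))
  pat <- build_mutation_matrices(d, levels = 1:7)
  expect_equal(filter_by_mean_occurrence(pat, 0), c("gA", "gB"))
  expect_equal(filter_by_mean_occurrence(pat, 1), "gA")   # 8/7 >= 1 > 1/7
  pat_p <- build_mutation_matrices(d, populations = sprintf("HT%d", 1:16),
                                   levels = 1:7,
                                   occurrence_denominator = "populations")
  expect_equal(pat_p$gA$mean_occurrence, 8 / 16)
  expect_equal(filter_by_mean_occurrence(pat_p, 1), character(0))
})

test_that("frequency score follows cp * n / N_p with configurable aggregation", {
  expect_equal(mutation_fscore(numeric(0), n = 0, n_populations = 16), 0)
  expect_equal(mutation_fscore(c(0.5, 0.5), n = 2, n_populations = 16), 0.0625)
  expect_equal(mutation_fscore(rep(1, 16), n = 16, n_populations = 16), 1)
  expect_equal(mutation_fscore(c(0.2, 0.8), n = 2, n_populations = 16,
                               aggregate = "max"), 0.8 * 2 / 16)
  expect_equal(mutation_fscore(c(0.2, 0.8), n = 2, n_populations = 16,
                               aggregate = "sum"), 1 * 2 / 16)
  expect_error(mutation_fscore(0.5, n = 1, n_populations = 0), "positive")
})

test_that("global score sums mutation scores over the ethanol levels", {
  expect_equal(global_fscore(numeric(0)), 0)
  expect_equal(global_fscore(0.7, n_levels = 7), 0.1)
  expect_equal(global_fscore(c(0.0625, 0.0625), n_levels = 7), 0.125 / 7)
  expect_error(global_fscore(0.5, n_levels = 0), ">= 1")
})

test_that("membrane-transporter counting requires both keywords", {
  cat <- small_catalog()
  expect_equal(count_membrane_transporters(cat, "A"), 2L)  # t3 lacks transport
  expect_equal(count_membrane_transporters(cat, "B"), 0L)  # transport, no membrane
  expect_error(count_membrane_transporters(cat, "Z"), "unknown TCS")
  empty <- tcs_catalog(data.frame(tcs = "A", gene = c("s", "r"),
                                  role = c("sensor", "regulator")),
                       data.frame(tcs = character(), target = character(),
                                  cc = character(), bp = character()))
  expect_equal(count_membrane_transporters(empty, "A"), 0L)
})

test_that("priority ranking matches the formula chain and handles ties", {
  cat <- small_catalog()
  d <- rbind(make_mut("sA", c("HT1", "HT2"), 1L, "m1", 0.5),
             make_mut("rB", c("HT1", "HT3"), 2L, "m1", 1))
  res <- priority_rank(d, cat, n_populations = 16, n_levels = 7)
  expect_s3_class(res, "tcs_priority")
  expect_equal(res$pscore, res$fbar_score * res$n_mt)
  expect_setequal(res$rank, seq_len(nrow(res)))
  a <- res[res$tcs == "A", ]
  expect_equal(a$fbar_score, (0.5 * 2 / 16) / 7)
  expect_equal(a$pscore, (0.5 * 2 / 16) / 7 * 2)
  expect_equal(res$tcs[res$rank == 1], "A")   # B has N_MT = 0, Pscore 0

  # all-zero Pscores rank by the deterministic tie-break (fbar, then name)
  cat0 <- tcs_catalog(cat$components,
                      data.frame(tcs = character(), target = character(),
                                 cc = character(), bp = character()))
  res0 <- priority_rank(d, cat0, n_populations = 16, n_levels = 7)
  expect_true(all(res0$pscore == 0))
  expect_equal(res0$tcs[res0$rank == 1], "B")  # fbar(B) = 2/16/7 > fbar(A)
})

test_that("priority ranking equals the brute-force oracle on random datasets", {
  for (seed in 1:10) {
    ds <- random_small_dataset(seed)
    res <- priority_rank(ds$mutations, ds$catalog,
                         n_populations = 16, n_levels = 7)
    orc <- oracle_priority(ds$mutations, ds$catalog, 16, 7)
    res <- res[order(res$tcs), ]
    orc <- orc[order(orc$tcs), ]
    expect_identical(res$fbar_score, orc$fbar_score)
    expect_identical(res$n_mt, orc$n_mt)
    expect_identical(res$pscore, orc$pscore)
    expect_identical(res$rank, orc$rank)
  }
})

test_that("scores scale linearly in cp and are permutation invariant", {
  ds <- random_small_dataset(42)
  res <- priority_rank(ds$mutations, ds$catalog, n_populations = 16, n_levels = 7)
  lambda <- 0.37
  scaled <- ds$mutations
  scaled$frequency <- scaled$frequency * lambda
  res_l <- priority_rank(scaled, ds$catalog, n_populations = 16, n_levels = 7)
  expect_equal(res_l$pscore, res$pscore * lambda)
  expect_equal(res_l$fbar_score, res$fbar_score * lambda)
  expect_identical(res_l$rank, res$rank)

  set.seed(7)
  shuffled <- ds$mutations[sample(nrow(ds$mutations)), ]
  res_s <- priority_rank(shuffled, ds$catalog, n_populations = 16, n_levels = 7)
  expect_identical(res_s$pscore, res$pscore)
  expect_identical(res_s$rank, res$rank)
})

test_that("adding a sensor mutation never decreases a TCS Pscore", {
  ds <- random_small_dataset(3)
  base <- priority_rank(ds$mutations, ds$catalog, n_populations = 16, n_levels = 7)
  for (nm in unique(ds$catalog$components$tcs)) {
    g <- ds$catalog$components$gene[ds$catalog$components$tcs == nm][1]
    extra <- make_mut(g, "HT9", 6L, "mX9", 0.8)
    res <- priority_rank(rbind(ds$mutations, extra), ds$catalog,
                         n_populations = 16, n_levels = 7)
    expect_gte(res$pscore[res$tcs == nm], base$pscore[base$tcs == nm])
  }
})

test_that("mutated TCS counting sees sensor and regulator hits only", {
  cat <- small_catalog()
  d <- rbind(make_mut("sA", "HT1", 1L, "m1", 0.4),
             make_mut("other", "HT2", 1L, "m1", 0.9))
  expect_equal(mutated_tcs_count(d, cat), 1L)
  expect_equal(mutated_tcs_count(d[0, ], cat), 0L)
})

test_that("mutation tables are validated", {
  expect_error(validate_mutations(data.frame(gene = "g")), "missing column")
  bad <- make_mut("g", "HT1", 1L, "m1", 1.4)
  expect_error(validate_mutations(bad), "\\[0, 1\\]")
})
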