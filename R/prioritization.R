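# TCS prioritization from population-level mutation data.
#
# The scoring chain is: per-mutation frequency score
#   fscore_m = cp_m * n_m / N_p
# (cp_m = aggregated allele frequency, n_m = number of populations carrying
# the mutation, N_p = number of parallel-evolved populations), summed per TCS
# and divided by the number of ethanol levels N_e to give the global score
# fbar, and finally weighted by the number of membrane-associated transporter
# genes in the TCS regulon:
#   Pscore = fbar * N_MT.

#' Validate a population-level mutation table
#'
#' A mutation dataset records, for every observed mutation, the gene it falls
#' in, the evolved population it was observed in, the ethanol level (ordinal
#' sampling point) and the population allele frequency (`cp`, the fraction of
#' reads supporting the variant).
#'
#' @param data data.frame with columns `gene`, `population`, `level`,
#'   `mutation_id`, `frequency`.
#' @return the validated data.frame, invisibly classed `mutation_dataset`.
#' @export
validate_mutations <- function(data) {
  need <- c("gene", "population", "level", "mutation_id", "frequency")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_config("mutation table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data)) {
    if (any(!is.finite(data$frequency)) ||
        any(data$frequency < 0) || any(data$frequency > 1))
      stop_config("mutation frequencies must lie in [0, 1]")
    key <- paste(data$gene, data$population, data$level, data$mutation_id, sep = "\r")
    if (anyDuplicated(key))
      stop_config("duplicate (gene, population, level, mutation_id) records")
  }
  class(data) <- unique(c("mutation_dataset", class(data)))
  invisible(data)
}

#' Build per-gene mutation presence matrices
#'
#' For every gene, one binary presence matrix per mutation (populations x
#' ethanol levels) is implied by the records; summing these binary matrices
#' over all mutations in the gene yields the gene's global pattern, a
#' populations x levels count matrix. `global_count` is the sum of all its
#' entries, so every evolved mutation in a gene contributes. The mean
#' occurrence divides `global_count` by an averaging denominator: the number
#' of ethanol levels (default) or of populations.
#'
#' @param data validated mutation table (see [validate_mutations()]).
#' @param populations,levels optional full sets of population / level labels
#'   (defaults: those present in `data`); supply these when some populations
#'   or levels carry no mutations so matrix dimensions reflect the design.
#' @param occurrence_denominator `"levels"` (default) or `"populations"`.
#' @return named list of `gene_pattern` objects, each with elements `gene`,
#'   `pattern` (count matrix), `global_count` and `mean_occurrence`.
#' @export
build_mutation_matrices <- function(data,
                                    populations = NULL,
                                    levels = NULL,
                                    occurrence_denominator = c("levels", "populations")) {
  data <- validate_mutations(data)
  occurrence_denominator <- match.arg(occurrence_denominator)
  if (!nrow(data)) return(structure(list(), names = character()))
  pops <- if (is.null(populations)) sort(unique(data$population)) else populations
  levs <- if (is.null(levels)) sort(unique(data$level)) else levels
  denom <- if (occurrence_denominator == "levels") length(levs) else length(pops)
  out <- lapply(split(data, data$gene), function(d) {
    m <- matrix(0L, length(pops), length(levs), dimnames = list(pops, levs))
    idx <- cbind(match(d$population, pops), match(d$level, levs))
    if (anyNA(idx))
      stop_config("records reference populations/levels outside the supplied design")
    # several mutations may hit the same cell; tabulate rather than assign
    for (k in seq_len(nrow(idx))) m[idx[k, 1L], idx[k, 2L]] <- m[idx[k, 1L], idx[k, 2L]] + 1L
    structure(list(gene = d$gene[1L], pattern = m, global_count = sum(m),
                   mean_occurrence = sum(m) / denom),
              class = "gene_pattern")
  })
  out[order(names(out))]
}

#' Filter genes by mean mutation occurrence
#'
#' Retains genes whose mean occurrence (global mutation count divided by the
#' averaging denominator chosen in [build_mutation_matrices()]) reaches the
#' threshold; the conventional cut of 1 keeps genes carrying on average one
#' mutation.
#'
#' @param patterns list of `gene_pattern` objects.
#' @param threshold nonnegative mean-occurrence cutoff (default 1).
#' @return character vector of retained gene names, sorted.
#' @export
filter_by_mean_occurrence <- function(patterns, threshold = 1) {
  assert_scalar_num(threshold, "threshold", lower = 0)
  keep <- vapply(patterns, function(p) p$mean_occurrence >= threshold, logical(1))
  sort(names(patterns)[keep])
}

#' Per-mutation frequency score
#'
#' `fscore_m = cp_m * n_m / N_p`, where `cp_m` aggregates the mutation's
#' per-population allele frequencies, `n_m` is the number of populations
#' carrying it and `N_p` the total number of parallel-evolved populations.
#'
#' @param cp_values numeric vector of per-population frequencies in `[0, 1]`.
#' @param n number of populations carrying the mutation (default:
#'   `length(cp_values)`).
#' @param n_populations total number of parallel-evolved populations (N_p).
#' @param aggregate how to collapse `cp_values` to a single `cp_m`:
#'   `"mean"` (default), `"max"` or `"sum"`.
#' @return the frequency score, 0 when `n = 0`.
#' @export
mutation_fscore <- function(cp_values, n = length(cp_values), n_populations,
                            aggregate = c("mean", "max", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!is.numeric(n_populations) || length(n_populations) != 1L || n_populations <= 0)
    stop_config("'n_populations' must be a positive number")
  if (n < 0) stop_config("'n' must be >= 0")
  if (n == 0L || !length(cp_values)) return(0)
  cp <- switch(aggregate, mean = mean(cp_values), max = max(cp_values),
               sum = sum(cp_values))
  cp * n / n_populations
}

#' Global frequency score of a TCS
#'
#' Sums the per-mutation frequency scores of all mutations in the system's
#' sensor and regulator genes and divides by the number of ethanol levels
#' considered.
#'
#' @param fscores numeric vector of per-mutation frequency scores.
#' @param n_levels number of ethanol levels (N_e, default 7).
#' @return `sum(fscores) / n_levels`; 0 for an empty vector.
#' @export
global_fscore <- function(fscores, n_levels = 7) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 1)
    stop_config("'n_levels' must be >= 1")
  if (!length(fscores)) return(0)
  sum(fscores) / n_levels
}

#' Construct a TCS catalog
#'
#' @param components data.frame with columns `tcs`, `gene`, `role`
#'   (`"sensor"` or `"regulator"`); every TCS must have at least one sensor
#'   and one regulator gene.
#' @param regulon data.frame with columns `tcs`, `target`, `cc` and `bp`
#'   (cellular-component and biological-process annotation keyword strings);
#'   may be empty for a TCS.
#' @return a `tcs_catalog` object.
#' @export
tcs_catalog <- function(components, regulon) {
  need_c <- c("tcs", "gene", "role")
  need_r <- c("tcs", "target", "cc", "bp")
  if (length(setdiff(need_c, names(components))))
    stop_config("components table needs columns: ", paste(need_c, collapse = ", "))
  if (length(setdiff(need_r, names(regulon))))
    stop_config("regulon table needs columns: ", paste(need_r, collapse = ", "))
  if (nrow(components)) {
    bad <- setdiff(unique(components$role), c("sensor", "regulator"))
    if (length(bad)) stop_config("unknown component role(s): ", paste(bad, collapse = ", "))
    for (nm in unique(components$tcs)) {
      roles <- components$role[components$tcs == nm]
      if (!all(c("sensor", "regulator") %in% roles))
        stop_config("TCS '", nm, "' lacks a sensor or regulator gene")
    }
  }
  structure(list(components = components, regulon = regulon), class = "tcs_catalog")
}

#' @export
print.tcs_catalog <- function(x, ...) {
  cat("TCS catalog:", length(unique(x$components$tcs)), "systems,",
      nrow(x$regulon), "regulon targets\n")
  invisible(x)
}

#' Count membrane-associated transporter genes in a TCS regulon
#'
#' A regulon target counts if its cellular-component annotation contains
#' "membrane" AND its biological-process annotation contains "transport"
#' (case-insensitive substring match).
#'
#' @param catalog a [tcs_catalog()].
#' @param tcs TCS name present in the catalog.
#' @return integer N_MT.
#' @export
count_membrane_transporters <- function(catalog, tcs) {
  stopifnot(inherits(catalog, "tcs_catalog"))
  if (!tcs %in% catalog$components$tcs)
    stop_config("unknown TCS: ", tcs)
  reg <- catalog$regulon[catalog$regulon$tcs == tcs, , drop = FALSE]
  if (!nrow(reg)) return(0L)
  hit <- grepl("membrane", reg$cc, ignore.case = TRUE) &
    grepl("transport", reg$bp, ignore.case = TRUE)
  # a target regulated via several entries still counts once
  length(unique(reg$target[hit]))
}

#' Rank two-component systems by priority score
#'
#' For each TCS, mutations falling in its sensor or regulator genes are
#' scored with [mutation_fscore()] (one score per distinct mutation; `n_m` =
#' number of populations carrying it, `cp_m` aggregated over its records),
#' combined into the global score by [global_fscore()], and multiplied by the
#' regulon's membrane-transporter count to give
#' `Pscore = fbar * N_MT`. Genes shared between systems contribute to each.
#' Ranking is by descending Pscore, ties broken by descending fbar, then TCS
#' name.
#'
#' @param data mutation table (see [validate_mutations()]).
#' @param catalog a [tcs_catalog()].
#' @param n_populations total populations N_p (default: distinct populations
#'   in `data`).
#' @param n_levels ethanol levels N_e (default: distinct levels in `data`).
#' @param aggregate cp aggregation passed to [mutation_fscore()].
#' @return data.frame (class `tcs_priority`) with one row per TCS: `tcs`,
#'   `n_mutations`, `fbar_score`, `n_mt`, `pscore`, `rank`; per-mutation
#'   score tables attached as attribute `"fscores"`.
#' @export
priority_rank <- function(data, catalog,
                          n_populations = NULL, n_levels = NULL,
                          aggregate = c("mean", "max", "sum")) {
  data <- validate_mutations(data)
  stopifnot(inherits(catalog, "tcs_catalog"))
  aggregate <- match.arg(aggregate)
  if (is.null(n_populations)) n_populations <- max(1L, length(unique(data$population)))
  if (is.null(n_levels)) n_levels <- max(1L, length(unique(data$level)))

  systems <- sort(unique(catalog$components$tcs))
  breakdown <- vector("list", length(systems))
  names(breakdown) <- systems
  rows <- lapply(systems, function(nm) {
    genes <- catalog$components$gene[catalog$components$tcs == nm]
    d <- data[data$gene %in% genes, , drop = FALSE]
    if (nrow(d)) {
      mut <- paste(d$gene, d$mutation_id, sep = "\r")
      fs <- vapply(split(d, mut), function(dm) {
        mutation_fscore(dm$frequency, n = length(unique(dm$population)),
                        n_populations = n_populations, aggregate = aggregate)
      }, numeric(1))
      breakdown[[nm]] <<- data.frame(
        tcs = nm,
        gene = vapply(split(d$gene, mut), `[`, character(1), 1L),
        mutation_id = vapply(split(d$mutation_id, mut), `[`, character(1), 1L),
        fscore = unname(fs), row.names = NULL)
    } else fs <- numeric(0)
    fbar <- global_fscore(fs, n_levels = n_levels)
    nmt <- count_membrane_transporters(catalog, nm)
    data.frame(tcs = nm, n_mutations = length(fs), fbar_score = fbar,
               n_mt = nmt, pscore = fbar * nmt)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(tcs = character(), n_mutations = integer(),
                                      fbar_score = numeric(), n_mt = integer(),
                                      pscore = numeric())
  ord <- order(-res$pscore, -res$fbar_score, res$tcs)
  res$rank <- rep(NA_integer_, nrow(res))
  res$rank[ord] <- seq_len(nrow(res))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "fscores") <- do.call(rbind, breakdown)
  attr(res, "n_populations") <- n_populations
  attr(res, "n_levels") <- n_levels
  class(res) <- c("tcs_priority", class(res))
  res
}

#' Number of mutated two-component systems
#'
#' Counts the systems with at least one observed mutation in a sensor or
#' regulator gene.
#'
#' @inheritParams priority_rank
#' @return integer count.
#' @export
mutated_tcs_count <- function(data, catalog) {
  data <- validate_mutations(data)
  stopifnot(inherits(catalog, "tcs_catalog"))
  systems <- unique(catalog$components$tcs)
  sum(vapply(systems, function(nm) {
    genes <- catalog$components$gene[catalog$components$tcs == nm]
    any(data$gene %in% genes)
  }, logical(1)))
}
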