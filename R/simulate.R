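# Seeded synthetic-data generators. Every generator produces one input class
# of the pipeline together with its planted ground truth, so that recovery
# tests need no external files. Each generator derives its own RNG stream
# from the master seed by a fixed offset, so adding a generator never
# perturbs the others.

SEED_OFFSETS <- c(mutation = 101L, reporter = 211L, protein = 307L,
                  spot = 401L, fermentation = 503L)

stream_seed <- function(config, stream) {
  as.integer((config$seed + SEED_OFFSETS[[stream]]) %% .Machine$integer.max)
}

#' Simulation configuration
#'
#' Bundles the study-design constants shared by the generators: 16 parallel
#' evolved populations sampled at 7 ethanol levels, with one planted
#' top-priority TCS, plus noise/missingness settings for the assay
#' generators.
#'
#' @param seed master integer seed; identical configurations give
#'   bit-identical outputs.
#' @param n_populations number of parallel-evolved populations (default 16).
#' @param n_ethanol_levels number of sequenced ethanol levels (default 7).
#' @param n_genes number of genes in the simulated genome (default 60).
#' @param n_tcs number of two-component systems (default 8).
#' @param planted_top_tcs name of the TCS planted as the top-priority target
#'   (default `"TCS01"`).
#' @param reporter_noise_sd fluorescence noise sd (a.u., default 2).
#' @param proteomics_missing_rate fraction of left-censored missing values
#'   per sample (default 0.1).
#' @param spot_grid `c(rows, cols)` of the spot-assay grid (default 4 x 7:
#'   four strains, seven 10-fold dilutions).
#' @param gompertz_truth named c(A, mu, lambda, y0) of the fermentation
#'   ground truth (default A = 20 g, mu = 0.3 g/h, lambda = 10 h, y0 = 0 g).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_populations = 16L,
                              n_ethanol_levels = 7L,
                              n_genes = 60L,
                              n_tcs = 8L,
                              planted_top_tcs = "TCS01",
                              reporter_noise_sd = 2,
                              proteomics_missing_rate = 0.1,
                              spot_grid = c(4L, 7L),
                              gompertz_truth = c(A = 20, mu = 0.3, lambda = 10, y0 = 0)) {
  gompertz_truth <- unlist(gompertz_truth)
  spot_grid <- unlist(spot_grid)
  if (n_populations < 1L) stop_config("n_populations must be >= 1")
  if (n_ethanol_levels < 1L) stop_config("n_ethanol_levels must be >= 1")
  if (n_genes < 0L) stop_config("n_genes must be >= 0")
  if (n_tcs < 0L) stop_config("n_tcs must be >= 0")
  if (proteomics_missing_rate < 0 || proteomics_missing_rate > 1)
    stop_config("proteomics_missing_rate must lie in [0, 1]")
  assert_scalar_num(reporter_noise_sd, "reporter_noise_sd", lower = 0)
  if (length(spot_grid) != 2L || any(spot_grid < 1L))
    stop_config("spot_grid must be c(rows, cols) with positive entries")
  if (length(gompertz_truth) != 4L)
    stop_config("gompertz_truth must hold four values (A, mu, lambda, y0)")
  names(gompertz_truth) <- c("A", "mu", "lambda", "y0")
  structure(list(seed = as.integer(seed), n_populations = as.integer(n_populations),
                 n_ethanol_levels = as.integer(n_ethanol_levels),
                 n_genes = as.integer(n_genes), n_tcs = as.integer(n_tcs),
                 planted_top_tcs = planted_top_tcs,
                 reporter_noise_sd = reporter_noise_sd,
                 proteomics_missing_rate = proteomics_missing_rate,
                 spot_grid = as.integer(spot_grid),
                 gompertz_truth = gompertz_truth),
            class = "sim_config")
}

#' Simulate a population mutation dataset with a planted top TCS
#'
#' Generates a gene pool, assigns each TCS one sensor and one regulator gene,
#' and draws mutation events with Beta-distributed allele frequencies. The
#' planted TCS receives many high-frequency sensor/regulator mutations spread
#' over most populations, and the regulon table gives it the largest number
#' of membrane-associated transporter targets, so its priority score is
#' strictly maximal by construction. Non-planted systems and non-TCS genes
#' receive sparse low-frequency background mutations.
#'
#' @param config a [simulation_config()].
#' @return list of class `ale_sim`: `mutations` (mutation table), `catalog`
#'   (a [tcs_catalog()]), `truth` (list with `planted_top_tcs`).
#' @export
simulate_mutation_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes == 0L || config$n_tcs == 0L) {
    empty <- data.frame(gene = character(), population = character(),
                        level = integer(), mutation_id = character(),
                        frequency = numeric())
    cat <- tcs_catalog(data.frame(tcs = character(), gene = character(),
                                  role = character()),
                       data.frame(tcs = character(), target = character(),
                                  cc = character(), bp = character()))
    return(structure(list(mutations = validate_mutations(empty), catalog = cat,
                          truth = list(planted_top_tcs = NA_character_)),
                     class = "ale_sim"))
  }
  if (config$n_genes < 2L * config$n_tcs)
    stop_config("n_genes must be at least 2 * n_tcs (one sensor + one regulator each)")
  set.seed(stream_seed(config, "mutation"))
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  tcs_names <- sprintf("TCS%02d", seq_len(config$n_tcs))
  if (!config$planted_top_tcs %in% tcs_names)
    tcs_names[1L] <- config$planted_top_tcs
  comp <- data.frame(
    tcs = rep(tcs_names, each = 2L),
    gene = genes[seq_len(2L * config$n_tcs)],
    role = rep(c("sensor", "regulator"), config$n_tcs))
  pops <- sprintf("HT%d", seq_len(config$n_populations))
  levs <- seq_len(config$n_ethanol_levels)
  planted <- config$planted_top_tcs

  # per-TCS Beta shapes: planted system has high-frequency alleles,
  # the rest sit near the detection floor
  shapes <- lapply(tcs_names, function(nm) {
    if (nm == planted) c(30, 3) else c(2, 8)
  })
  names(shapes) <- tcs_names

  recs <- list()
  for (nm in tcs_names) {
    gset <- comp$gene[comp$tcs == nm]
    if (nm == planted) {
      n_mut <- 6L
      n_pop_each <- max(1L, round(config$n_populations * 0.75))
      lev_each <- levs[levs > max(1L, config$n_ethanol_levels %/% 3L)]
    } else {
      n_mut <- sample(1:3, 1L)
      n_pop_each <- sample(1:2, 1L)
      lev_each <- NA
    }
    for (k in seq_len(n_mut)) {
      g <- sample(gset, 1L)
      mid <- sprintf("%s_m%02d", g, k)
      carrier <- sample(pops, n_pop_each)
      use_levs <- if (nm == planted) lev_each else sample(levs, sample(1:2, 1L))
      for (p in carrier) {
        cp <- rbeta(length(use_levs), shapes[[nm]][1L], shapes[[nm]][2L])
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g, population = p, level = use_levs,
          mutation_id = mid, frequency = cp)
      }
    }
  }
  # background mutations in non-TCS genes
  other <- setdiff(genes, comp$gene)
  for (g in other) {
    if (runif(1) < 0.5) next
    n_mut <- sample(1:2, 1L)
    for (k in seq_len(n_mut)) {
      p <- sample(pops, 1L)
      lv <- sample(levs, 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g, population = p, level = lv,
        mutation_id = sprintf("%s_m%02d", g, k),
        frequency = rbeta(1L, 2, 8))
    }
  }
  mut <- do.call(rbind, recs)
  mut <- mut[!duplicated(mut[c("gene", "population", "level", "mutation_id")]), ]
  mut <- mut[order(mut$gene, mut$population, mut$level, mut$mutation_id), ]
  rownames(mut) <- NULL

  # regulons: planted TCS gets the most membrane-associated transporters
  reg <- list()
  for (nm in tcs_names) {
    n_mt <- if (nm == planted) 6L else sample(0:3, 1L)
    n_other <- sample(1:3, 1L)
    tg_mt <- if (n_mt) sprintf("%s_tgt%02d", nm, seq_len(n_mt)) else character()
    tg_ot <- sprintf("%s_tgt%02d", nm, n_mt + seq_len(n_other))
    reg[[nm]] <- rbind(
      if (n_mt) data.frame(tcs = nm, target = tg_mt,
                           cc = "integral component of membrane",
                           bp = "transmembrane transport"),
      data.frame(tcs = nm, target = tg_ot,
                 cc = sample(c("cytoplasm", "periplasmic space"), n_other, TRUE),
                 bp = sample(c("metabolic process", "DNA repair"), n_other, TRUE)))
  }
  catalog <- tcs_catalog(comp, do.call(rbind, c(reg, list(make.row.names = FALSE))))
  structure(list(mutations = validate_mutations(mut), catalog = catalog,
                 truth = list(planted_top_tcs = planted)),
            class = "ale_sim")
}

#' Simulate a promoter-fusion reporter time course
#'
#' Fluorescence follows `F_s(t) = rF(t) * (OD_s(t) - OD_b) + F_b + noise`
#' with logistic sample growth, a constant medium blank, and Gaussian
#' fluorescence noise, sampled hourly up to 10 h.
#'
#' @param config a [simulation_config()]; `reporter_noise_sd` sets the noise.
#' @param true_rf the planted relative fluorescence: a constant or a
#'   function of time.
#' @param times sampling times (default `0:10` h).
#' @return list: `series` (a [reporter_series()]) and `truth` (rF values).
#' @export
simulate_reporter_series <- function(config, true_rf, times = 0:10) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config, "reporter"))
  rf <- if (is.function(true_rf)) true_rf(times) else rep(true_rf, length(times))
  od_b <- 0.04
  od_s <- od_b + 0.01 + 1.1 / (1 + exp(-(times - 5)))   # keeps OD_s > OD_b
  f_b <- 50
  f_s <- rf * (od_s - od_b) + f_b + rnorm(length(times), 0, config$reporter_noise_sd)
  list(series = reporter_series(times, f_s, rep(f_b, length(times)), od_s,
                                rep(od_b, length(times))),
       truth = setNames(rf, times))
}

#' Simulate a log2 label-free protein matrix with planted effects
#'
#' Baseline log2 intensities are drawn per protein, planted proteins receive
#' a group-B shift of `log2fc`, and missingness is left-censored: a value is
#' missing iff it falls below its sample's `missing_rate` quantile
#' (detection-limit censoring). A small fraction of proteins is marked
#' non-proteotypic or given a failing library q-value to exercise the record
#' filter.
#'
#' @param config a [simulation_config()]; `proteomics_missing_rate` sets the
#'   censoring rate.
#' @param n_proteins number of proteins (default 500).
#' @param groups sample group labels (default 4 + 4, groups "A"/"B").
#' @param planted_de protein names (or indices) shifted in group B.
#' @param log2fc planted shift (default 3).
#' @param within_sd within-group sd of log2 intensities (default 0.5).
#' @param frac_low_confidence fraction of proteins planted to fail the
#'   record filter (default 0).
#' @return list: `quant` (a [protein_quant()]) and `truth` (planted protein
#'   names).
#' @export
simulate_protein_matrix <- function(config, n_proteins = 500,
                                    groups = rep(c("A", "B"), each = 4L),
                                    planted_de = character(),
                                    log2fc = 3, within_sd = 0.5,
                                    frac_low_confidence = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(groups) || any(table(groups) < 1L))
    stop_config("every group needs at least one sample")
  set.seed(stream_seed(config, "protein"))
  prot <- sprintf("P%04d", seq_len(n_proteins))
  if (is.numeric(planted_de)) planted_de <- prot[planted_de]
  base <- rnorm(n_proteins, 25, 2)
  m <- matrix(rnorm(n_proteins * length(groups), base, within_sd),
              n_proteins, length(groups),
              dimnames = list(prot, sprintf("%s_%d", groups, seq_along(groups))))
  shift <- prot %in% planted_de
  m[shift, groups == "B"] <- m[shift, groups == "B"] + log2fc
  # left-censoring: missing iff below the per-sample quantile
  rate <- config$proteomics_missing_rate
  if (rate > 0) {
    for (j in seq_len(ncol(m))) {
      if (rate >= 1) { m[, j] <- NA_real_; next }
      m[m[, j] < quantile(m[, j], rate), j] <- NA_real_
    }
  }
  qv <- runif(n_proteins, 0, 0.009)
  pt_flag <- rep(TRUE, n_proteins)
  n_bad <- round(frac_low_confidence * n_proteins)
  if (n_bad > 0L) {
    bad <- sample(setdiff(seq_len(n_proteins), which(shift)), n_bad)
    half <- seq_len(ceiling(n_bad / 2))
    qv[bad[half]] <- runif(length(half), 0.011, 0.2)
    pt_flag[bad[-half]] <- FALSE
    if (n_bad == 1L) pt_flag[bad] <- TRUE  # single bad protein: fail on q only
  }
  list(quant = protein_quant(m, groups, proteotypic = pt_flag, qvalue = qv),
       truth = list(planted_de = prot[shift], log2fc = log2fc))
}

#' Render a synthetic spot-plate image
#'
#' Draws filled disks on a uniform dark background, one per specified grid
#' cell, and attaches the grid metadata. Every disk must lie fully inside its
#' cell.
#'
#' @param config a [simulation_config()]; `spot_grid` sets the grid.
#' @param true_spots data.frame with columns `row`, `col`, `radius`,
#'   `intensity` (gray level 0-255); optional `cx`, `cy` absolute pixel
#'   centers (default: cell center).
#' @param cell_size cell edge in pixels (default 100).
#' @param background background gray level (default 20).
#' @return list: `plate` (a [spot_plate()]) and `truth` (the spot table).
#' @export
render_spot_plate <- function(config, true_spots, cell_size = 100,
                              background = 20) {
  stopifnot(inherits(config, "sim_config"))
  nrows <- config$spot_grid[1L]; ncols <- config$spot_grid[2L]
  img <- matrix(background, nrows * cell_size, ncols * cell_size)
  if (nrow(true_spots)) {
    need <- c("row", "col", "radius", "intensity")
    if (length(setdiff(need, names(true_spots))))
      stop_config("true_spots needs columns: ", paste(need, collapse = ", "))
    for (i in seq_len(nrow(true_spots))) {
      s <- true_spots[i, ]
      if (s$row < 1L || s$row > nrows || s$col < 1L || s$col > ncols)
        stop_config("spot ", i, " references a grid cell outside the plate")
      cy <- if ("cy" %in% names(s) && !is.na(s$cy)) s$cy else (s$row - 0.5) * cell_size
      cx <- if ("cx" %in% names(s) && !is.na(s$cx)) s$cx else (s$col - 0.5) * cell_size
      if (cy - s$radius < (s$row - 1L) * cell_size || cy + s$radius > s$row * cell_size ||
          cx - s$radius < (s$col - 1L) * cell_size || cx + s$radius > s$col * cell_size)
        stop_config("spot ", i, " does not fit fully inside its grid cell")
      img <- draw_disk(img, cy, cx, s$radius, s$intensity)
    }
  }
  list(plate = spot_plate(img, nrows, ncols), truth = true_spots)
}

#' Simulate a fermentation time series
#'
#' Cumulative ethanol mass follows the four-parameter Gompertz curve at the
#' configuration's `gompertz_truth`, sampled every 24 h over the first week
#' of the run plus the 185 h endpoint, with optional Gaussian noise; glucose
#' declines in proportion to the ethanol produced.
#'
#' @param config a [simulation_config()].
#' @param times sampling times (default `c(seq(0, 168, 24), 185)` h).
#' @param noise_sd sd of additive ethanol noise in g (default 0).
#' @param glucose0 starting glucose concentration (g/L, default 90).
#' @return list: `series` (data.frame `time`, `ethanol_g`, `glucose_g_l`) and
#'   `truth` (the Gompertz parameters).
#' @export
simulate_fermentation <- function(config, times = c(seq(0, 168, by = 24), 185),
                                  noise_sd = 0, glucose0 = 90) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config, "fermentation"))
  p <- config$gompertz_truth
  eth <- if (p["mu"] == 0) rep(p["y0"], length(times))
         else gompertz4(times, p["A"], p["mu"], p["lambda"], p["y0"])
  if (noise_sd > 0) eth <- eth + rnorm(length(times), 0, noise_sd)
  eth <- pmax(eth, 0)
  frac <- if (p["A"] > p["y0"]) (eth - p["y0"]) / (p["A"] - p["y0"]) else rep(0, length(times))
  glucose <- pmax(glucose0 * (1 - pmin(pmax(frac, 0), 1)), 0)
  list(series = data.frame(time = times, ethanol_g = eth, glucose_g_l = glucose),
       truth = p)
}
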