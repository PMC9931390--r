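# Seeded generators emulating each experimental design in the pipeline:
# negative-binomial barcode counts with planted resistors, amplicon reads,
# logistic growth under Hill inhibition, degradation-coupled spheroid
# landscapes, Lea-Coulson mutant-count distributions, and biased
# mutation-position sampling.

# fixed 20-bp flanks of the synthetic amplicon; the barcode sits between
# them in every simulated read
GS_FLANK5 <- "ACGTTGCAGGTCCAGTTACG"
GS_FLANK3 <- "TGGACCATAACGGTCAGTAC"

#' Configuration for the pooled-screen count generator
#'
#' @param n_strains library size (default 3680 knockouts).
#' @param planted_resistors,planted_sensitives data.frames with columns
#'   `strain` (id within the library) and `log2fc` (true drug/control log2
#'   fold change; typically positive for resistors, negative for
#'   sensitives).
#' @param dispersion negative-binomial dispersion alpha
#'   (Var = mu + alpha mu^2); 0 gives Poisson counts.
#' @param depth expected reads per sample.
#' @param n_reps replicates per condition (default 3).
#' @param seed integer seed.
#' @return validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_strains = 3680, planted_resistors = NULL,
                              planted_sensitives = NULL, dispersion = 0.05,
                              depth = 1e6, n_reps = 3, seed = 1) {
  gs_assert(is_count(n_strains), "`n_strains` must be a positive integer")
  gs_assert(is_pos_num(depth), "`depth` must be > 0")
  gs_assert(is_scalar_num(dispersion) && dispersion >= 0,
            "`dispersion` must be >= 0")
  gs_assert(is_count(n_reps), "`n_reps` must be a positive integer")
  planted <- rbind(planted_resistors, planted_sensitives)
  if (!is.null(planted) && nrow(planted)) {
    gs_assert(all(c("strain", "log2fc") %in% names(planted)),
              "planted tables need `strain` and `log2fc` columns")
    gs_assert(!anyDuplicated(planted$strain),
              "planted strain ids must be unique")
    gs_assert(all(planted$strain >= 1 & planted$strain <= n_strains),
              "planted strain ids must lie within the library")
  }
  structure(list(n_strains = n_strains, planted = planted,
                 dispersion = dispersion, depth = depth, n_reps = n_reps,
                 seed = seed),
            class = "screen_sim_config")
}

#' Simulate pooled-screen barcode counts
#'
#' Strain abundances are log-normal (fixed by the seed), scaled to the
#' target depth; counts are negative-binomial with the configured
#' dispersion. Planted strains have their drug-condition means multiplied
#' by `2^log2fc`.
#'
#' @param config a [screen_sim_config()].
#' @return `count_table` with `n_reps` control and `n_reps` drug samples,
#'   and an attribute `truth` holding the planted table.
#' @export
simulate_screen_counts <- function(config) {
  gs_assert(inherits(config, "screen_sim_config"),
            "`config` must come from screen_sim_config()")
  set.seed(config$seed)
  ns <- config$n_strains
  abund <- exp(stats::rnorm(ns, 0, 0.8))
  abund <- abund / sum(abund)
  mu_c <- config$depth * abund
  fc <- rep(1, ns)
  if (!is.null(config$planted) && nrow(config$planted))
    fc[config$planted$strain] <- 2^config$planted$log2fc
  mu_d <- mu_c * fc
  draw <- function(mu) {
    if (config$dispersion < 1e-12) stats::rpois(ns, mu)
    else stats::rnbinom(ns, mu = mu, size = 1 / config$dispersion)
  }
  cols <- c(replicate(config$n_reps, draw(mu_c), simplify = FALSE),
            replicate(config$n_reps, draw(mu_d), simplify = FALSE))
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("strain_%04d", seq_len(ns))
  cond <- rep(c("control", "drug"), each = config$n_reps)
  out <- count_table(counts, cond)
  attr(out, "truth") <- config$planted
  out
}

#' Generate a synthetic barcode database
#'
#' Random 20-bp barcodes with pairwise Hamming distance at least
#' `min_dist`, so single-mismatch assignment is unambiguous at
#' `min_dist >= 3`.
#'
#' @param n number of barcodes.
#' @param width barcode length in bp (default 20).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed integer seed.
#' @return named `DNAStringSet` (`strain_0001`, ...).
#' @export
simulate_barcode_db <- function(n, width = 20, min_dist = 3, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  picked <- matrix(NA_integer_, nrow = 0, ncol = width)
  while (nrow(picked) < n) {
    cand <- sample.int(4, width, replace = TRUE)
    if (nrow(picked) == 0 ||
        min(rowSums(picked != matrix(cand, nrow(picked), width,
                                     byrow = TRUE))) >= min_dist) {
      picked <- rbind(picked, cand)
    }
  }
  seqs <- apply(picked, 1, function(i) paste(bases[i], collapse = ""))
  db <- Biostrings::DNAStringSet(seqs)
  names(db) <- sprintf("strain_%04d", seq_len(n))
  db
}

#' Simulate amplicon reads from a barcode count table
#'
#' Each read is the fixed 5' flank, the strain's barcode, and the fixed 3'
#' flank, with independent per-base substitution errors. Per-barcode read
#' totals equal the supplied counts.
#'
#' @param counts named integer vector (one sample), or a `count_table`
#'   (all samples, returned as a named list).
#' @param db barcode database ([simulate_barcode_db()] or FASTA path);
#'   every counted strain must be present.
#' @param error_rate per-base substitution probability in [0, 0.5).
#' @param seed integer seed.
#' @return `DNAStringSet` of reads (or a list of them per sample).
#' @export
simulate_screen_reads <- function(counts, db, error_rate = 0, seed = 1) {
  gs_assert(is_scalar_num(error_rate) && error_rate >= 0 && error_rate < 0.5,
            "`error_rate` must be in [0, 0.5)")
  db <- as_dna(db, "fasta")
  if (inherits(counts, "count_table")) {
    cols <- lapply(seq_len(ncol(counts$counts)), function(j) {
      simulate_screen_reads(counts$counts[, j], db, error_rate, seed + j)
    })
    names(cols) <- colnames(counts$counts)
    return(cols)
  }
  gs_assert(all(names(counts) %in% names(db)),
            "unknown barcode id in counts")
  set.seed(seed)
  counts <- counts[counts > 0]
  if (!length(counts))
    return(Biostrings::DNAStringSet(character(0)))
  bc <- as.character(db[names(counts)])
  reads <- rep(paste0(GS_FLANK5, bc, GS_FLANK3), times = counts)
  if (error_rate > 0) {
    mat <- do.call(rbind, strsplit(reads, ""))
    err <- matrix(stats::runif(length(mat)) < error_rate, nrow(mat))
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      # substitution to one of the three other bases
      repl <- vapply(mat[err], function(b) {
        sample(setdiff(bases, b), 1)
      }, character(1))
      mat[err] <- repl
      reads <- apply(mat, 1, paste, collapse = "")
    }
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read_%06d", seq_along(out))
  out
}

#' Write reads as FASTQ
#'
#' @param reads `DNAStringSet`.
#' @param path output path; a `.gz` suffix enables compression.
#' @param quality constant per-base quality character (default "I").
#' @export
write_fastq <- function(reads, path, quality = "I") {
  q <- Biostrings::BStringSet(strrep(quality, Biostrings::width(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    reads, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Configuration for the growth-curve generator
#'
#' @param carrying_capacity plateau OD of the uninhibited culture.
#' @param rate logistic growth rate (1/h).
#' @param lag lag time (h).
#' @param ic50_true true half-inhibitory concentration (uM).
#' @param hill Hill slope of the inhibition.
#' @param noise_sd OD measurement noise (sd).
#' @param t_grid measurement times in minutes (default every 10 min for
#'   18 h).
#' @param blank_od optical density of blank wells.
#' @param n_reps technical replicates per dose.
#' @param seed integer seed.
#' @export
growth_sim_config <- function(carrying_capacity = 1.0, rate = 0.8, lag = 2,
                              ic50_true = 10, hill = 2, noise_sd = 0,
                              t_grid = seq(0, 1080, by = 10),
                              blank_od = 0.05, n_reps = 3, seed = 1) {
  gs_assert(all(vapply(list(carrying_capacity, rate, lag, ic50_true, hill),
                       is_pos_num, logical(1))),
            "growth parameters must be positive")
  gs_assert(is_scalar_num(noise_sd) && noise_sd >= 0, "`noise_sd` >= 0")
  gs_assert(all(diff(t_grid) > 0) && all(t_grid >= 0),
            "`t_grid` must be non-negative and strictly increasing")
  structure(list(carrying_capacity = carrying_capacity, rate = rate,
                 lag = lag, ic50_true = ic50_true, hill = hill,
                 noise_sd = noise_sd, t_grid = t_grid, blank_od = blank_od,
                 n_reps = n_reps, seed = seed),
            class = "growth_sim_config")
}

#' Dose-response strain presets
#'
#' Growth configurations for characterised strains, with true IC50s of
#' 0.7 uM (F-18, the most gemcitabine-sensitive strain) and 103 uM
#' (BW25113, the most resistant), and a 12-point dose series (11 doses in
#' 1.6-fold serial dilution plus a zero-dose column) spanning each IC50.
#'
#' @param strain `"F-18"` or `"BW25113"`.
#' @param ... overrides passed on to [growth_sim_config()].
#' @return list with `config` (a `growth_sim_config`) and `doses` (uM).
#' @export
strain_preset <- function(strain = c("F-18", "BW25113"), ...) {
  strain <- match.arg(strain)
  ic50 <- c("F-18" = 0.7, "BW25113" = 103)[[strain]]
  max_dose <- c("F-18" = 8, "BW25113" = 1200)[[strain]]
  doses <- c(max_dose / 1.6^(10:0), 0)
  list(config = growth_sim_config(ic50_true = ic50, ...),
       doses = sort(doses))
}

#' Simulate plate-reader growth curves under Hill inhibition
#'
#' Logistic growth whose plateau is scaled by the Hill inhibition factor
#' \eqn{1/(1+(d/\mathrm{IC50})^h)}; at dose = IC50 the endpoint relative
#' growth is exactly 0.5. Blank wells carry only the blank OD (plus
#' noise).
#'
#' @param config a [growth_sim_config()].
#' @param doses dose series in uM (>= 0); include 0 for the reference.
#' @param strain strain label recorded in the layout.
#' @return object of class `plate_series` (see [plate_series()]).
#' @export
simulate_growth_curves <- function(config, doses, strain = "sim") {
  gs_assert(inherits(config, "growth_sim_config"),
            "`config` must come from growth_sim_config()")
  gs_assert(all(doses >= 0), "doses must be >= 0")
  set.seed(config$seed)
  tmin <- config$t_grid
  th <- tmin / 60
  tmid <- config$lag + 3 / config$rate
  shape <- stats::plogis(config$rate * (th - tmid)) -
    stats::plogis(config$rate * (0 - tmid))
  shape <- pmax(shape, 0)
  inh <- 1 / (1 + (doses / config$ic50_true)^config$hill)

  wells <- list(); layout <- list(); w <- 0L
  for (i in seq_along(doses)) {
    for (r in seq_len(config$n_reps)) {
      w <- w + 1L
      well <- sprintf("W%03d", w)
      od <- config$blank_od + config$carrying_capacity * inh[i] * shape +
        stats::rnorm(length(th), 0, config$noise_sd)
      wells[[w]] <- data.frame(well = well, time_min = tmin, od600 = od)
      layout[[w]] <- data.frame(well = well, strain = strain,
                                dose_um = doses[i], replicate = r,
                                is_blank = FALSE)
    }
  }
  for (r in seq_len(config$n_reps)) {
    w <- w + 1L
    well <- sprintf("W%03d", w)
    od <- config$blank_od + stats::rnorm(length(th), 0, config$noise_sd)
    wells[[w]] <- data.frame(well = well, time_min = tmin, od600 = od)
    layout[[w]] <- data.frame(well = well, strain = NA, dose_um = NA,
                              replicate = r, is_blank = TRUE)
  }
  plate_series(do.call(rbind, wells), do.call(rbind, layout))
}

#' Configuration for the spheroid-landscape generator
#'
#' @param n_doses,n_bacteria grid dimensions (default 12 x 8).
#' @param max_dose highest drug dose (uM); lower doses follow a 1.6-fold
#'   serial dilution, with a zero-dose column appended.
#' @param dilution_factor_drug serial dilution factor (default 1.6).
#' @param degradation_coefficient signed per-strain coefficient; positive
#'   values mean the bacteria deplete drug (effective dose
#'   `d * exp(-coef * inoculum)`), negative values mean they leave more
#'   active drug than the reference.
#' @param ec50_cell cancer-cell EC50 of the drug (uM).
#' @param hill Hill slope of the spheroid dose response.
#' @param noise_sd relative area noise (sd of a multiplicative factor).
#' @param area_t0 mean day-zero spheroid area (um^2).
#' @param seed integer seed.
#' @export
spheroid_sim_config <- function(n_doses = 12, n_bacteria = 8,
                                max_dose = 50, dilution_factor_drug = 1.6,
                                degradation_coefficient = 0,
                                ec50_cell = 2, hill = 1.5, noise_sd = 0,
                                area_t0 = 2e5, seed = 1) {
  gs_assert(is_count(n_doses) && n_doses >= 2 &&
              is_count(n_bacteria) && n_bacteria >= 2,
            "grid must be at least 2 x 2")
  gs_assert(dilution_factor_drug > 1, "`dilution_factor_drug` must be > 1")
  gs_assert(is_pos_num(ec50_cell) && is_pos_num(hill) && is_pos_num(max_dose),
            "dose-response parameters must be positive")
  structure(list(n_doses = n_doses, n_bacteria = n_bacteria,
                 max_dose = max_dose,
                 dilution_factor_drug = dilution_factor_drug,
                 degradation_coefficient = degradation_coefficient,
                 ec50_cell = ec50_cell, hill = hill, noise_sd = noise_sd,
                 area_t0 = area_t0, seed = seed),
            class = "spheroid_sim_config")
}

#' Simulate a spheroid co-culture plate
#'
#' End-point spheroid area responds to the effective drug dose
#' `d_eff = d * exp(-degradation_coefficient * inoculum)` through a Hill
#' curve; the zero-drug column is unaffected by bacteria. Rows are
#' bacteria levels (high to low inoculum), columns are doses (high to
#' low, with the zero-dose column last), matching the plate layout.
#'
#' @param config a [spheroid_sim_config()].
#' @return `spheroid_grid` (see [spheroid_grid()]) with an attribute
#'   `truth` giving the analytic per-row EC50 crossing dose.
#' @export
simulate_spheroid_plate <- function(config) {
  gs_assert(inherits(config, "spheroid_sim_config"),
            "`config` must come from spheroid_sim_config()")
  set.seed(config$seed)
  nd <- config$n_doses; nb <- config$n_bacteria
  doses <- c(config$max_dose / config$dilution_factor_drug^(0:(nd - 2)), 0)
  inoc <- 2^-(0:(nb - 1))            # relative inoculum, high -> low rows
  d_eff <- outer(inoc, doses, function(b, d) {
    d * exp(-config$degradation_coefficient * b)
  })
  resp <- 1 / (1 + (d_eff / config$ec50_cell)^config$hill)
  # growth ratio of a week of spheroid growth, scaled by drug response
  ratio <- 1.2 + 4.0 * resp
  t0 <- matrix(config$area_t0, nb, nd) *
    (1 + stats::rnorm(nb * nd, 0, config$noise_sd / 2))
  end <- t0 * ratio * (1 + stats::rnorm(nb * nd, 0, config$noise_sd))
  g <- spheroid_grid(end, t0, doses = doses, bacteria = inoc)
  attr(g, "truth") <- data.frame(
    row = seq_len(nb), inoculum = inoc,
    ec50_dose = config$ec50_cell *
      exp(config$degradation_coefficient * inoc))
  g
}

#' Configuration for the fluctuation-assay generator
#'
#' @param mu mutation rate per cell division (>= 0).
#' @param N0 initial cells per culture.
#' @param Nt final cells per culture (> N0).
#' @param epsilon plating efficiency in (0, 1].
#' @param n_cultures number of parallel cultures (default 10).
#' @param seed integer seed.
#' @export
fluctuation_sim_config <- function(mu, N0 = 730, Nt = 1e8, epsilon = 1,
                                   n_cultures = 10, seed = 1) {
  gs_assert(is_scalar_num(mu) && mu >= 0, "`mu` must be >= 0")
  gs_assert(is_pos_num(N0) && is_pos_num(Nt) && N0 < Nt,
            "need 0 < N0 < Nt")
  gs_assert(is_scalar_num(epsilon) && epsilon > 0 && epsilon <= 1,
            "`epsilon` must be in (0, 1]")
  gs_assert(is_count(n_cultures), "`n_cultures` must be a positive integer")
  structure(list(mu = mu, N0 = N0, Nt = Nt, epsilon = epsilon,
                 n_cultures = n_cultures, seed = seed),
            class = "fluctuation_sim_config")
}

#' Simulate mutant-colony counts under the Lea--Coulson model
#'
#' Per culture, the number of mutational events is Poisson with mean
#' `m = mu * (Nt - N0)`; each event's clone size is drawn from the
#' Lea--Coulson law \eqn{P(j) = 1/(j(j+1))} by the exact inverse-CDF
#' `j = floor(1/U)` (since \eqn{P(j \ge k) = 1/k}), truncated at `Nt`; the
#' observed colonies per clone are binomially thinned by the plating
#' efficiency.
#'
#' @param config a [fluctuation_sim_config()].
#' @return integer vector of observed colony counts, one per culture,
#'   with attribute `m` (the true expected mutations per culture).
#' @export
simulate_fluctuation <- function(config) {
  gs_assert(inherits(config, "fluctuation_sim_config"),
            "`config` must come from fluctuation_sim_config()")
  set.seed(config$seed)
  m <- config$mu * (config$Nt - config$N0)
  n <- config$n_cultures
  M <- stats::rpois(n, m)
  counts <- integer(n)
  tot <- sum(M)
  if (tot > 0) {
    j <- pmin(floor(1 / stats::runif(tot)), config$Nt)
    obs <- stats::rbinom(tot, j, config$epsilon)
    agg <- rowsum(obs, rep.int(seq_len(n), M))
    counts[as.integer(rownames(agg))] <- as.integer(agg)
  }
  attr(counts, "m") <- m
  counts
}

#' Simulate a conservation profile with biased mutation positions
#'
#' Per-position conservation scores on the 1-9 scale (9 = most conserved)
#' are sampled uniformly; `n_mut` mutated positions are then drawn without
#' replacement with probability proportional to
#' `bias^((score - 1) / 8)`, so `bias = 1` is the unbiased null and large
#' `bias` concentrates mutations on conserved residues.
#'
#' @param length number of residues.
#' @param bias odds multiplier for fully conserved positions (> 0).
#' @param n_mut number of mutated positions (1 <= n_mut <= length).
#' @param seed integer seed.
#' @return list with `scores` (integer vector) and `positions` (sorted
#'   mutated indices).
#' @export
simulate_conservation <- function(length, bias, n_mut, seed = 1) {
  gs_assert(is_count(length) && is_count(n_mut) && n_mut <= length,
            "need 1 <= n_mut <= length")
  gs_assert(is_pos_num(bias), "`bias` must be > 0")
  set.seed(seed)
  scores <- sample.int(9, length, replace = TRUE)
  w <- bias^((scores - 1) / 8)
  positions <- sort(sample.int(length, n_mut, prob = w))
  list(scores = scores, positions = positions)
}

# default mobile element used by transposon mutation specs: a 300-bp
# sequence with inverted 20-bp terminal repeats
gs_transposon_element <- function() {
  set.seed(90125)
  core <- paste(sample(c("A", "C", "G", "T"), 260, replace = TRUE),
                collapse = "")
  ir <- "TGACTGATTCAGCCAACGGT"
  paste0(ir, core, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ir))))
}

#' Apply a mutation descriptor to a reference coding sequence
#'
#' Supported descriptors: `substitution(pos, base)`,
#' `deletion(pos, len)`, `insertion(pos, seq)` (inserted after `pos`),
#' and `transposon(pos, element)` (a mobile-element insertion after
#' `pos`; default element is a bundled 300-bp sequence). Classification of
#' the mutant by [align_and_classify()] round-trips to the descriptor's
#' expected class.
#'
#' @param ref_cds reference CDS (character or DNAString); length must be
#'   a multiple of 3.
#' @param spec list with `type` and type-specific fields (see above).
#' @return mutated sequence as a character string.
#' @export
mutate_sequence <- function(ref_cds, spec) {
  ref <- as.character(ref_cds)
  n <- nchar(ref)
  gs_assert(n %% 3 == 0, "`ref_cds` length must be divisible by 3")
  gs_assert(is.list(spec) && !is.null(spec$type), "`spec` needs a `type`")
  pos <- spec$pos
  gs_assert(is_count(pos) && pos <= n, "mutation position out of range")
  switch(
    spec$type,
    substitution = {
      gs_assert(spec$base %in% c("A", "C", "G", "T"),
                "`base` must be one of A/C/G/T")
      paste0(substr(ref, 1, pos - 1), spec$base,
             substr(ref, pos + 1, n))
    },
    deletion = {
      gs_assert(is_count(spec$len) && pos + spec$len - 1 <= n,
                "deletion runs off the sequence")
      paste0(substr(ref, 1, pos - 1), substr(ref, pos + spec$len, n))
    },
    insertion = {
      gs_assert(grepl("^[ACGT]+$", spec$seq), "`seq` must be A/C/G/T")
      paste0(substr(ref, 1, pos), spec$seq, substr(ref, pos + 1, n))
    },
    transposon = {
      el <- if (is.null(spec$element)) gs_transposon_element()
            else spec$element
      paste0(substr(ref, 1, pos), el, substr(ref, pos + 1, n))
    },
    gs_assert(FALSE, sprintf("unknown mutation type '%s'", spec$type))
  )
}

#' Simulate a drug-breakdown assay cohort
#'
#' Generates per-replicate growth-curve AUCs of the reporter strain in
#' conditioned buffer for a cohort of knockouts plus the wild-type
#' control, mirroring the assay design: 3 knockout replicates and 18
#' wild-type replicates at each of the 15- and 45-min collection times.
#' Fast degraders deplete drug early, so their 15-min buffer supports
#' higher reporter AUC (+`effect_sd` standard deviations); slow degraders
#' leave drug at 45 min, lowering the 45-min AUC.
#'
#' @param n_fast,n_slow,n_null planted class sizes (defaults 10/23/55,
#'   the composition of the 88-strain resistor panel where a third of
#'   knockouts modulated degradation).
#' @param effect_sd planted shift in units of the replicate sd.
#' @param auc_mean,auc_sd baseline AUC mean and sd (OD h).
#' @param n_ko,n_wt replicates per knockout and for wild type.
#' @param seed integer seed.
#' @return data.frame (strain, timepoint, replicate, auc) with an
#'   attribute `truth` giving each strain's planted class; wild type is
#'   strain `"WT"`.
#' @export
simulate_breakdown_cohort <- function(n_fast = 10, n_slow = 23, n_null = 55,
                                      effect_sd = 3, auc_mean = 2.5,
                                      auc_sd = 0.15, n_ko = 3, n_wt = 18,
                                      seed = 1) {
  set.seed(seed)
  classes <- c(rep("fast", n_fast), rep("slow", n_slow), rep("none", n_null))
  strains <- sprintf("ko_%03d", seq_along(classes))
  shift15 <- ifelse(classes == "fast", effect_sd * auc_sd, 0)
  shift45 <- ifelse(classes == "slow", -effect_sd * auc_sd, 0)
  rows <- list(
    data.frame(strain = "WT", timepoint = "15",
               replicate = seq_len(n_wt),
               auc = stats::rnorm(n_wt, auc_mean, auc_sd)),
    data.frame(strain = "WT", timepoint = "45",
               replicate = seq_len(n_wt),
               auc = stats::rnorm(n_wt, auc_mean, auc_sd))
  )
  for (i in seq_along(strains)) {
    rows[[length(rows) + 1L]] <- data.frame(
      strain = strains[i], timepoint = "15", replicate = seq_len(n_ko),
      auc = stats::rnorm(n_ko, auc_mean + shift15[i], auc_sd))
    rows[[length(rows) + 1L]] <- data.frame(
      strain = strains[i], timepoint = "45", replicate = seq_len(n_ko),
      auc = stats::rnorm(n_ko, auc_mean + shift45[i], auc_sd))
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- stats::setNames(classes, strains)
  out
}
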