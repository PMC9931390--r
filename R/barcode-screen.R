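#' Construct a barcode count table
#'
#' Container for strain-by-sample barcode counts from a pooled knockout
#' screen, with per-sample condition labels (drug vs control) and
#' replicate ids. Size factors are `NULL` until
#' [estimate_size_factors()] is run.
#'
#' @param counts non-negative integer matrix, strains in rows (rownames =
#'   strain ids), samples in columns.
#' @param condition character vector per sample, values `"drug"` or
#'   `"control"`.
#' @param replicate replicate identifier per sample (defaults to 1..n
#'   within condition).
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  gs_assert(is.numeric(counts) && all(counts >= 0) &&
              all(counts == floor(counts)),
            "`counts` must be a non-negative integer matrix")
  gs_assert(length(condition) == ncol(counts),
            "`condition` must have one entry per sample")
  gs_assert(all(condition %in% c("drug", "control")),
            "`condition` values must be 'drug' or 'control'")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("strain_", seq_len(nrow(counts)))
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(condition, "_", replicate)
  structure(list(
    counts = counts,
    sample_meta = data.frame(sample = colnames(counts),
                             condition = condition,
                             replicate = replicate),
    size_factors = NULL
  ), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "strains x", ncol(x$counts),
      "samples (", sum(x$sample_meta$condition == "drug"), "drug /",
      sum(x$sample_meta$condition == "control"), "control )\n")
  invisible(x)
}

# coerce FASTA/FASTQ paths or XStringSet inputs
as_dna <- function(x, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(Biostrings::readDNAStringSet(x, format = format))
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    if (!is.null(names(x))) names(out) <- names(x)
    return(out)
  }
  gs_assert(FALSE, "expected a DNAStringSet, a file path, or a character vector")
}

#' Count barcode occurrences in sequencing reads
#'
#' Assigns each read to at most one barcode from the database by exact
#' substring matching, with optional single-mismatch rescue for reads
#' without an exact hit. Reverse complements of the reads are also
#' searched, since library orientation can vary. A read matching more than
#' one barcode (possible only with mismatch rescue on closely spaced
#' barcodes) is left unassigned, so `sum(counts) + unassigned` always
#' equals the number of input reads.
#'
#' @param reads FASTQ path (optionally gzipped), DNAStringSet, or
#'   character vector of read sequences.
#' @param db barcode FASTA path or named DNAStringSet/character vector;
#'   barcodes must be unique and of equal length.
#' @param max_mismatch 0 (exact only) or 1 (single-mismatch rescue).
#' @param search_revcomp also search reverse-complemented reads.
#' @return list with `counts` (named integer vector per barcode) and
#'   `unassigned` (number of reads matching no barcode unambiguously).
#' @export
count_barcodes <- function(reads, db, max_mismatch = 0,
                           search_revcomp = TRUE) {
  gs_assert(max_mismatch %in% c(0, 1), "`max_mismatch` must be 0 or 1")
  reads <- as_dna(reads, "fastq")
  db <- as_dna(db, "fasta")
  gs_assert(!is.null(names(db)) && !anyDuplicated(names(db)),
            "barcode database must carry unique names")
  gs_assert(!anyDuplicated(as.character(db)),
            "barcode database contains duplicate sequences")
  widths <- Biostrings::width(db)
  gs_assert(length(unique(widths)) == 1,
            "barcodes must all have the same length")

  nb <- length(db)
  n_reads <- length(reads)
  counts <- stats::setNames(integer(nb), names(db))
  if (n_reads == 0) return(list(counts = counts, unassigned = 0L))

  assign_of <- rep(NA_integer_, n_reads)
  match_round <- function(idx, subject, mm) {
    # returns matrix-free assignment for reads `idx` against `subject[idx]`
    hits <- matrix(0L, nrow = nb, ncol = length(idx))
    if (mm == 0) {
      pd <- Biostrings::PDict(db)
      hits <- Biostrings::vcountPDict(pd, subject)
    } else {
      for (b in seq_len(nb)) {
        hits[b, ] <- Biostrings::vcountPattern(db[[b]], subject,
                                               max.mismatch = 1)
      }
    }
    nhit <- colSums(hits > 0)
    one <- which(nhit == 1)
    list(one = one, which = apply(hits[, one, drop = FALSE] > 0, 2, which))
  }

  todo <- seq_len(n_reads)
  rounds <- list(list(mm = 0, rc = FALSE))
  if (search_revcomp) rounds <- c(rounds, list(list(mm = 0, rc = TRUE)))
  if (max_mismatch == 1) {
    rounds <- c(rounds, list(list(mm = 1, rc = FALSE)))
    if (search_revcomp) rounds <- c(rounds, list(list(mm = 1, rc = TRUE)))
  }
  for (r in rounds) {
    if (!length(todo)) break
    subject <- reads[todo]
    if (r$rc) subject <- Biostrings::reverseComplement(subject)
    res <- match_round(todo, subject, r$mm)
    if (length(res$one)) {
      assign_of[todo[res$one]] <- res$which
      todo <- todo[-res$one]
    }
  }
  tab <- tabulate(assign_of[!is.na(assign_of)], nbins = nb)
  counts[] <- tab
  list(counts = counts, unassigned = n_reads - sum(tab))
}

#' Discard strains with uniformly low counts
#'
#' Removes strains whose maximum count across all samples falls below
#' `min_count`; a strain detectable in either condition is kept. Row order
#' is preserved.
#'
#' @param table a `count_table`.
#' @param min_count threshold (default 10, i.e. "< 10 in every sample"
#'   drops the strain).
#' @return filtered `count_table`.
#' @export
filter_low_counts <- function(table, min_count = 10) {
  gs_assert(inherits(table, "count_table"), "`table` must be a count_table")
  keep <- apply(table$counts, 1, max) >= min_count
  table$counts <- table$counts[keep, , drop = FALSE]
  if (!is.null(table$size_factors)) table$size_factors <- table$size_factors
  table
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median across strains
#' of the ratio of each sample's count to the per-strain geometric mean
#' over samples (the standard count-screen normalisation). Only strains
#' with nonzero counts in every sample inform the medians.
#'
#' @param table a `count_table` (or bare count matrix).
#' @return the `count_table` with `size_factors` filled in (or, for a
#'   matrix input, the factor vector).
#' @export
estimate_size_factors <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  loggm <- rowMeans(log(counts))
  use <- is.finite(loggm)
  gs_assert(any(use),
            "no strain has nonzero counts in all samples",
            "gemscreen_estimation_error")
  sf <- apply(counts, 2, function(cnts) {
    exp(stats::median(log(cnts[use]) - loggm[use]))
  })
  if (inherits(table, "count_table")) {
    table$size_factors <- sf
    table
  } else sf
}

# row variances of a matrix
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Per-strain negative-binomial Wald enrichment test
#'
#' For each strain the drug/control log2 fold change of normalised mean
#' counts (pseudocount 0.5) is tested against zero with a Wald statistic
#' whose standard error comes from a negative-binomial model
#' (Var = mu + alpha mu^2). Dispersions are method-of-moments estimates
#' shrunk on the log scale toward a fitted mean-dispersion trend
#' (alpha_tr(mu) = a0 + a1/mu), which stabilises the few-replicate
#' estimates; the final dispersion is never allowed below half the trend.
#' P-values are two-sided normal and BH-adjusted across tested strains.
#'
#' @param table `count_table` with at least two replicates per condition;
#'   size factors are estimated if absent.
#' @param shrink_weight weight of the per-strain moment estimate in the
#'   log-scale shrinkage (remainder on the trend).
#' @return data.frame of class `strain_stats`: strain, base_mean, log2fc,
#'   dispersion, se_lfc, wald_z, p, q. All-zero strains are excluded with
#'   a warning.
#' @export
wald_enrichment <- function(table, shrink_weight = 0.3) {
  gs_assert(inherits(table, "count_table"), "`table` must be a count_table")
  cond <- table$sample_meta$condition
  gs_assert(sum(cond == "drug") >= 2 && sum(cond == "control") >= 2,
            "need >= 2 replicates per condition")
  if (is.null(table$size_factors)) table <- estimate_size_factors(table)
  sf <- table$size_factors
  norm <- sweep(table$counts, 2, sf, "/")

  allzero <- rowSums(table$counts) == 0
  if (any(allzero)) {
    gs_warn(sprintf("%d all-zero strains excluded from testing",
                    sum(allzero)))
    norm <- norm[!allzero, , drop = FALSE]
  }
  drug <- cond == "drug"; ctrl <- !drug
  n_d <- sum(drug); n_c <- sum(ctrl)
  mu_d <- rowMeans(norm[, drug, drop = FALSE])
  mu_c <- rowMeans(norm[, ctrl, drop = FALSE])
  v_d <- row_vars(norm[, drug, drop = FALSE])
  v_c <- row_vars(norm[, ctrl, drop = FALSE])
  base_mean <- rowMeans(norm)

  # moment dispersion pooled over conditions: alpha = (var - mu) / mu^2
  num <- (n_d - 1) * (v_d - mu_d) + (n_c - 1) * (v_c - mu_c)
  den <- (n_d - 1) * mu_d^2 + (n_c - 1) * mu_c^2
  alpha_mom <- pmax(num / pmax(den, 1e-12), 1e-8)

  # parametric trend alpha = a0 + a1/mu on informative strains, then a
  # trimmed refit to resist moment-estimate outliers
  fit_trend <- function(w) {
    mu <- base_mean[w]
    co <- stats::coef(stats::lm(alpha_mom[w] ~ I(1 / mu)))
    c(max(co[1], 1e-8), max(co[2], 0))
  }
  use <- base_mean > 0 & is.finite(alpha_mom)
  ab <- fit_trend(use)
  pred <- ab[1] + ab[2] / pmax(base_mean, 1e-12)
  resid_ratio <- alpha_mom / pmax(pred, 1e-12)
  keep <- use & resid_ratio < stats::quantile(resid_ratio[use], 0.95)
  if (sum(keep) > 10) ab <- fit_trend(keep)
  alpha_tr <- pmax(ab[1] + ab[2] / pmax(base_mean, 1e-12), 1e-8)

  alpha <- exp(shrink_weight * log(alpha_mom) +
                 (1 - shrink_weight) * log(alpha_tr))
  alpha <- pmax(alpha, alpha_tr / 2)

  # Wald statistic on log2 of pseudocounted normalised means
  inv_sf_d <- mean(1 / sf[drug]); inv_sf_c <- mean(1 / sf[ctrl])
  var_mean_d <- (mu_d * inv_sf_d + alpha * mu_d^2) / n_d
  var_mean_c <- (mu_c * inv_sf_c + alpha * mu_c^2) / n_c
  pc <- 0.5
  lfc <- log2((mu_d + pc) / (mu_c + pc))
  se <- sqrt(var_mean_d / ((mu_d + pc)^2) + var_mean_c / ((mu_c + pc)^2)) /
    log(2)
  z <- lfc / pmax(se, 1e-12)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    strain = rownames(norm), base_mean = base_mean, log2fc = lfc,
    dispersion = alpha, se_lfc = se, wald_z = z, p = p,
    q = stats::p.adjust(p, "BH"), row.names = NULL
  )
  class(out) <- c("strain_stats", "data.frame")
  out
}

#' Call resistant and sensitive hits
#'
#' Applies the screen's strict thresholds: resistant strains have
#' `log2fc >= log2(fc_cutoff)` and `q < q_cutoff`; sensitive strains
#' `log2fc <= -log2(fc_cutoff)` and `q < q_cutoff`.
#'
#' @param stats `strain_stats` from [wald_enrichment()].
#' @param fc_cutoff fold-change threshold (default 16).
#' @param q_cutoff BH-adjusted p-value threshold (default 0.05).
#' @return object of class `hit_call`: list with `resistant`, `sensitive`,
#'   `thresholds`.
#' @export
call_hits <- function(stats, fc_cutoff = 16, q_cutoff = 0.05) {
  lcut <- log2(fc_cutoff)
  res <- stats$strain[stats$log2fc >= lcut & stats$q < q_cutoff]
  sen <- stats$strain[stats$log2fc <= -lcut & stats$q < q_cutoff]
  structure(list(resistant = res, sensitive = sen,
                 thresholds = c(fold_change = fc_cutoff, q = q_cutoff)),
            class = "hit_call")
}

#' @export
print.hit_call <- function(x, ...) {
  cat("hit_call:", length(x$resistant), "resistant,", length(x$sensitive),
      "sensitive (fold change >=", x$thresholds[["fold_change"]],
      ", q <", x$thresholds[["q"]], ")\n")
  invisible(x)
}

#' One-tailed Fisher overlap test between a hit set and an annotation set
#'
#' Exact hypergeometric tail probability of observing at least the seen
#' overlap between two strain sets drawn from a common universe (used to
#' ask e.g. whether resistant hits are enriched for slow-growing
#' knockouts).
#'
#' @param hits,annotated strain id vectors, both subsets of `universe`.
#' @param universe vector of all strains under consideration.
#' @return list with `table` (2x2 hit x annotated contingency matrix) and
#'   `p` (one-tailed, enrichment direction).
#' @export
fisher_overlap <- function(hits, annotated, universe) {
  gs_assert(length(universe) > 0, "`universe` must be non-empty")
  universe <- unique(universe)
  hits <- unique(hits); annotated <- unique(annotated)
  gs_assert(all(hits %in% universe) && all(annotated %in% universe),
            "`hits` and `annotated` must be subsets of `universe`")
  N <- length(universe); K <- length(annotated); n <- length(hits)
  x <- length(intersect(hits, annotated))
  tab <- matrix(c(x, n - x, K - x, N - K - (n - x)), nrow = 2,
                dimnames = list(hit = c("yes", "no"),
                                annotated = c("yes", "no")))
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(table = tab, p = p)
}

#' Flag slow-growing knockouts by endpoint optical density
#'
#' @param growth_od24 named numeric vector of OD values (24 h growth on
#'   minimal medium) per strain.
#' @param cutoff strains with OD strictly below this are flagged
#'   (default 0.11, the antimode of the bimodal density distribution of
#'   the knockout collection).
#' @return character vector of slow-grower strain ids.
#' @export
classify_slow_growers <- function(growth_od24, cutoff = 0.11) {
  gs_assert(is.numeric(growth_od24) && all(growth_od24 >= 0),
            "`growth_od24` must be non-negative")
  gs_assert(!is.null(names(growth_od24)), "`growth_od24` must be named")
  names(growth_od24)[growth_od24 < cutoff]
}

#' Gene-set enrichment on screen fold changes
#'
#' A light-weight set-level test in the spirit of count-screen set
#' enrichment: for each named strain set, the member log2 fold changes are
#' compared with the non-member fold changes by a Welch two-sample t-test,
#' one-sided in each direction; q-values are BH-adjusted per direction
#' across sets. Sets with fewer than `min_size` scored members, or with an
#' empty complement, are skipped with a warning.
#'
#' @param stats `strain_stats` from [wald_enrichment()].
#' @param sets named list of strain-id vectors.
#' @param q_cutoff significance threshold on the per-direction q (default
#'   0.1), used for the `direction` call.
#' @param min_size minimum scored members per set (default 3).
#' @return data.frame: set, size, t, p_up, p_down, q_up, q_down, direction.
#' @export
set_enrichment <- function(stats, sets, q_cutoff = 0.1, min_size = 3) {
  gs_assert(is.list(sets) && !is.null(names(sets)), "`sets` must be named")
  lfc <- stats::setNames(stats$log2fc, stats$strain)
  rows <- lapply(names(sets), function(nm) {
    member <- names(lfc) %in% sets[[nm]]
    if (sum(member) < min_size || all(member)) {
      gs_warn(sprintf("set '%s' skipped (size %d of %d strains)",
                      nm, sum(member), length(lfc)))
      return(NULL)
    }
    tt <- stats::t.test(lfc[member], lfc[!member])
    up <- stats::t.test(lfc[member], lfc[!member], alternative = "greater")
    dn <- stats::t.test(lfc[member], lfc[!member], alternative = "less")
    data.frame(set = nm, size = sum(member), t = unname(tt$statistic),
               p_up = up$p.value, p_down = dn$p.value)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(rows)
  rows$q_up <- stats::p.adjust(rows$p_up, "BH")
  rows$q_down <- stats::p.adjust(rows$p_down, "BH")
  rows$direction <- ifelse(rows$q_up < q_cutoff, "up",
                           ifelse(rows$q_down < q_cutoff, "down", "none"))
  rows
}
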