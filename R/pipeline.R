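# Configuration-driven orchestration: each stage reads plain CSV/FASTA
# inputs, runs the corresponding module, writes CSV/JSON outputs plus a
# manifest with input/output hashes. Re-running a stage with an identical
# config reproduces byte-identical outputs.

GS_STAGES <- c("screen", "dose_response", "breakdown", "spheroid",
               "fluctuation", "annotation")

# write a data.frame as RFC-4180 CSV with 12-significant-digit floats
gs_write_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 12, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

gs_write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate a stage configuration
#'
#' A configuration (list or YAML file) must name a known `stage`, an
#' existing input file for every entry of `inputs`, and an `outdir`.
#' Validation happens before any computation; nothing is written on
#' failure.
#'
#' @param config list or path to a YAML file.
#' @return the validated config (invisibly usable by [run_stage()]).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    gs_assert(file.exists(config), sprintf("config file '%s' not found",
                                           config),
              "gemscreen_validation_error")
    config <- yaml::read_yaml(config)
  }
  gs_assert(is.list(config), "config must be a list or YAML path",
            "gemscreen_validation_error")
  gs_assert(!is.null(config$stage) && config$stage %in% GS_STAGES,
            sprintf("`stage` must be one of: %s",
                    paste(GS_STAGES, collapse = ", ")),
            "gemscreen_validation_error")
  gs_assert(is.list(config$inputs) && length(config$inputs) > 0 &&
              !is.null(names(config$inputs)),
            "`inputs` must be a named list of paths",
            "gemscreen_validation_error")
  for (nm in names(config$inputs)) {
    gs_assert(file.exists(config$inputs[[nm]]),
              sprintf("input '%s' not found: %s", nm, config$inputs[[nm]]),
              "gemscreen_validation_error")
  }
  gs_assert(!is.null(config$outdir), "`outdir` is required",
            "gemscreen_validation_error")
  if (is.null(config$params)) config$params <- list()
  config
}

# default, overridable stage parameters
gs_param <- function(config, name, default) {
  if (!is.null(config$params[[name]])) config$params[[name]] else default
}

#' Run one pipeline stage from a configuration
#'
#' Validates the configuration ([validate_config()]), executes the stage
#' on its inputs, writes the stage outputs into `outdir`, and writes a
#' manifest (`manifest_<stage>.json`) recording package version,
#' parameters, and MD5 hashes of all inputs and outputs. All stages are
#' deterministic: re-running with the same config gives byte-identical
#' outputs.
#'
#' @param config list or YAML path; fields `stage`, `inputs` (named
#'   paths), `params`, `outdir`.
#' @return invisibly, the manifest as a list.
#' @export
run_stage <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(config$stage,
                screen = stage_screen(config),
                dose_response = stage_dose_response(config),
                breakdown = stage_breakdown(config),
                spheroid = stage_spheroid(config),
                fluctuation = stage_fluctuation(config),
                annotation = stage_annotation(config))
  manifest <- list(
    stage = config$stage,
    package_version = as.character(utils::packageVersion("gemscreen")),
    params = config$params,
    inputs = lapply(config$inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(out, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  mpath <- file.path(config$outdir,
                     sprintf("manifest_%s.json", config$stage))
  gs_write_json(manifest, mpath)
  invisible(manifest)
}

stage_screen <- function(config) {
  counts <- utils::read.csv(config$inputs$counts, row.names = 1,
                            check.names = FALSE)
  meta <- utils::read.csv(config$inputs$meta)
  tab <- count_table(as.matrix(counts), meta$condition, meta$replicate)
  tab <- filter_low_counts(tab, gs_param(config, "min_count", 10))
  stats_df <- wald_enrichment(tab)
  hits <- call_hits(stats_df, gs_param(config, "fc", 16),
                    gs_param(config, "q", 0.05))
  p1 <- file.path(config$outdir, "stats.csv")
  p2 <- file.path(config$outdir, "hits.json")
  gs_write_csv(stats_df, p1)
  gs_write_json(list(resistant = hits$resistant,
                     sensitive = hits$sensitive,
                     thresholds = as.list(hits$thresholds)), p2)
  list(stats = p1, hits = p2)
}

stage_dose_response <- function(config) {
  plate <- utils::read.csv(config$inputs$plate)
  layout <- utils::read.csv(config$inputs$layout)
  series <- plate_series(plate, layout)
  resp <- relative_growth(series, gs_param(config, "t_eval", 720))
  fits <- do.call(rbind, lapply(split(resp, resp$strain), function(d) {
    f <- fit_4pl(d$dose_um, d$response)
    data.frame(strain = d$strain[1], ic50 = f$ic50, x50 = f$x50,
               hill = f$hill, top = f$top, bottom = f$bottom,
               censored = f$censored, max_dose = f$max_dose)
  }))
  p1 <- file.path(config$outdir, "responses.csv")
  p2 <- file.path(config$outdir, "fits.csv")
  gs_write_csv(resp, p1)
  gs_write_csv(fits, p2)
  list(responses = p1, fits = p2)
}

stage_breakdown <- function(config) {
  aucs <- utils::read.csv(config$inputs$aucs,
                          colClasses = c(timepoint = "character"))
  calls <- classify_degraders(aucs,
                              wt_strain = gs_param(config, "wt_strain", "WT"),
                              q_cutoff = gs_param(config, "q", 0.1))
  p1 <- file.path(config$outdir, "calls.csv")
  gs_write_csv(as.data.frame(calls), p1)
  list(calls = p1)
}

stage_spheroid <- function(config) {
  end <- as.matrix(utils::read.csv(config$inputs$end, header = FALSE))
  t0 <- as.matrix(utils::read.csv(config$inputs$t0, header = FALSE))
  grid <- normalize_spheroids(spheroid_grid(end, t0))
  fit <- fit_poly44(grid)
  front <- extract_front(fit, gs_param(config, "level", 0.5))
  p1 <- file.path(config$outdir, "surface.json")
  p2 <- file.path(config$outdir, "front.csv")
  gs_write_json(list(coefficients = as.list(fit$coefficients),
                     rss = fit$rss, level = front$level), p1)
  gs_write_csv(front$crossings, p2)
  list(surface = p1, front = p2)
}

stage_fluctuation <- function(config) {
  counts <- utils::read.csv(config$inputs$counts)
  gs_assert("count" %in% names(counts), "counts.csv needs a `count` column",
            "gemscreen_validation_error")
  eps <- gs_param(config, "epsilon", 1)
  fit <- profile_ci(mle_m(counts$count, eps))
  design <- list(N0 = gs_param(config, "n0", 730),
                 Nt = gs_param(config, "nt", 1e8),
                 gene_length = gs_param(config, "gene_length", 1000))
  rate <- mutation_rate(fit, design,
                        divisor = gs_param(config, "divisor", "divisions"))
  p1 <- file.path(config$outdir, "fit.json")
  gs_write_json(list(m = fit$m, ci = as.list(fit$ci),
                     epsilon = eps, mu = rate$mu,
                     mu_per_kb = rate$mu_per_kb,
                     mu_ci = as.list(rate$mu_ci),
                     iterations = fit$iterations,
                     converged = fit$converged), p1)
  list(fit = p1)
}

stage_annotation <- function(config) {
  queries <- Biostrings::readDNAStringSet(config$inputs$queries)
  ref <- as.character(Biostrings::readDNAStringSet(config$inputs$ref)[[1]])
  calls <- lapply(seq_along(queries), function(i)
    align_and_classify(as.character(queries[[i]]), ref))
  df <- data.frame(
    query = names(queries),
    type = vapply(calls, `[[`, "", "type"),
    nt_pos = vapply(calls, function(x) as.numeric(x$nt_pos), 0),
    protein_pos = vapply(calls, function(x) as.numeric(x$protein_pos), 0))
  sp <- spectrum(calls)
  p1 <- file.path(config$outdir, "calls.csv")
  p2 <- file.path(config$outdir, "spectrum.json")
  gs_write_csv(df, p1)
  gs_write_json(list(tally = as.list(sp$tally),
                     fraction_mutated = sp$fraction_mutated), p2)
  out <- list(calls = p1, spectrum = p2)
  if (!is.null(config$inputs$profile)) {
    prof <- utils::read.csv(config$inputs$profile)
    mis <- df$protein_pos[df$type == "missense"]
    if (length(mis) >= 3) {
      ct <- conservation_bias_test(prof$score, mis)
      p3 <- file.path(config$outdir, "conservation_test.json")
      gs_write_json(list(W = ct$W, p = ct$p, method = ct$method), p3)
      out$conservation_test <- p3
    }
  }
  out
}

#' Generate a human-readable summary report from stage manifests
#'
#' One section per manifest, in the fixed stage order, echoing the
#' stage's parameters and outputs. Regeneration from the same manifests
#' is deterministic.
#'
#' @param manifests list of manifest objects (as returned by
#'   [run_stage()]) or paths to manifest JSON files.
#' @param path optional output path for the markdown report.
#' @return character vector of report lines (invisibly when `path` is
#'   given).
#' @export
write_report <- function(manifests, path = NULL) {
  gs_assert(length(manifests) >= 1, "need at least one manifest")
  ms <- lapply(manifests, function(m) {
    if (is.character(m)) jsonlite::read_json(m) else m
  })
  ord <- order(match(vapply(ms, `[[`, "", "stage"), GS_STAGES))
  ms <- ms[ord]
  lines <- c("# gemscreen pipeline report", "")
  for (m in ms) {
    lines <- c(lines, sprintf("## Stage: %s", m$stage),
               sprintf("- package version: %s", m$package_version))
    if (length(m$params)) {
      for (nm in sort(names(m$params)))
        lines <- c(lines, sprintf("- param %s: %s", nm,
                                  paste(m$params[[nm]], collapse = ", ")))
    } else lines <- c(lines, "- params: defaults")
    for (nm in names(m$outputs))
      lines <- c(lines, sprintf("- output %s: %s (md5 %s)", nm,
                                m$outputs[[nm]]$path, m$outputs[[nm]]$md5))
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
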