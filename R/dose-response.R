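#' Construct a plate-reader time series
#'
#' @param readings data.frame with columns `well`, `time_min`, `od600`.
#' @param layout data.frame with columns `well`, `strain`, `dose_um`,
#'   `replicate`, `is_blank`.
#' @return object of class `plate_series`.
#' @export
plate_series <- function(readings, layout) {
  gs_assert(all(c("well", "time_min", "od600") %in% names(readings)),
            "`readings` needs well, time_min, od600")
  gs_assert(all(c("well", "strain", "dose_um", "replicate", "is_blank")
                %in% names(layout)),
            "`layout` needs well, strain, dose_um, replicate, is_blank")
  gs_assert(all(readings$time_min >= 0), "times must be non-negative")
  gs_assert(all(readings$well %in% layout$well),
            "every read well must appear in the layout")
  nb <- layout[!layout$is_blank, ]
  gs_assert(!any(is.na(nb$dose_um)), "every non-blank well needs a dose")
  structure(list(readings = readings, layout = layout),
            class = "plate_series")
}

#' @export
print.plate_series <- function(x, ...) {
  cat("plate_series:", length(unique(x$readings$well)), "wells,",
      length(unique(x$readings$time_min)), "timepoints\n")
  invisible(x)
}

#' Relative growth per dose at a fixed read time
#'
#' Blank-subtracted OD at the read time (nearest grid point within 5
#' minutes), averaged over replicates and divided by the zero-dose mean,
#' clipped at zero from below.
#'
#' @param series a `plate_series`.
#' @param t_eval read time in minutes (default 720, i.e. 12 h).
#' @return data.frame with columns `strain`, `dose_um`, `response`.
#' @export
relative_growth <- function(series, t_eval = 720) {
  gs_assert(inherits(series, "plate_series"), "`series` must be a plate_series")
  tg <- sort(unique(series$readings$time_min))
  i <- which.min(abs(tg - t_eval))
  gs_assert(abs(tg[i] - t_eval) <= 5,
            sprintf("no timepoint within 5 min of t_eval = %g", t_eval))
  at <- series$readings[series$readings$time_min == tg[i], ]
  od <- stats::setNames(at$od600, at$well)

  lay <- series$layout
  blank_wells <- lay$well[lay$is_blank]
  blank <- if (length(blank_wells)) mean(od[blank_wells]) else 0
  nb <- lay[!lay$is_blank, ]
  nb$net <- pmax(od[nb$well] - blank, 0)
  agg <- stats::aggregate(net ~ strain + dose_um, data = nb, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$strain), function(d) {
    z <- d$net[d$dose_um == 0]
    gs_assert(length(z) == 1, "zero-dose wells missing for a strain")
    resp <- if (z > 0) d$net / z else {
      gs_assert(all(d$net == 0),
                "zero-dose wells show no growth but dosed wells do")
      rep(0, nrow(d))   # fully blank plate: no growth anywhere
    }
    data.frame(strain = d$strain, dose_um = d$dose_um, response = resp)
  }))
  rownames(out) <- NULL
  out[order(out$strain, out$dose_um), ]
}

# 4PL mean function; d = 0 maps to `top` for hill > 0
four_pl <- function(d, bottom, top, x50, hill) {
  bottom + (top - bottom) / (1 + (d / x50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{r(d) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom}) /
#' (1 + (d/x_{50})^{h})} over a multi-start grid (Hill slope in
#' \{0.5, 1, 2, 4\}, midpoint at each interior dose; best residual sum of
#' squares wins, earlier start winning ties). The reported `ic50` is the
#' absolute IC50: the dose at which the fitted curve equals half its
#' zero-dose value (i.e. top/2), solved in closed form from the fitted
#' parameters. Curves whose response range is below `min_range` never
#' cross the half-maximal level reliably and are flagged not converged
#' with a "> max dose" censoring sentinel.
#'
#' @param doses dose vector in uM; at least 4 distinct values including 0.
#' @param responses relative growth values (same length as `doses`).
#' @param min_range minimum dynamic range required to report a finite
#'   IC50 (default 0.2).
#' @return object of class `dose_response_fit`: bottom, top, x50 (relative
#'   midpoint), hill, ic50 (absolute; `Inf` when censored), censored,
#'   converged, rss, max_dose.
#' @export
fit_4pl <- function(doses, responses, min_range = 0.2) {
  gs_assert(length(doses) == length(responses), "length mismatch")
  gs_assert(length(unique(doses)) >= 4 && any(doses == 0),
            ">= 4 distinct doses including 0 are required")
  gs_assert(all(is.finite(responses)), "responses must be finite")
  max_dose <- max(doses)

  censored_fit <- function() {
    structure(list(bottom = min(responses), top = max(responses),
                   x50 = NA_real_, hill = NA_real_, ic50 = Inf,
                   censored = TRUE, converged = FALSE, rss = NA_real_,
                   max_dose = max_dose),
              class = "dose_response_fit")
  }
  if (diff(range(responses)) < min_range) return(censored_fit())

  interior <- sort(unique(doses[doses > 0]))
  interior <- interior[interior < max_dose]
  if (!length(interior)) interior <- max_dose / 2
  starts <- expand.grid(hill = c(0.5, 1, 2, 4), x50 = interior,
                        KEEP.OUT.ATTRS = FALSE)
  b0 <- min(responses); t0 <- max(responses)
  df <- data.frame(d = doses, r = responses)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ bottom + (top - bottom) / (1 + (d / x50)^hill),
        data = df,
        start = list(bottom = b0, top = t0,
                     x50 = starts$x50[s], hill = starts$hill[s]),
        lower = c(bottom = -0.5, top = 1e-6, x50 = 1e-9, hill = 0.05),
        upper = c(bottom = Inf, top = Inf, x50 = max_dose * 100, hill = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) return(censored_fit())
  co <- as.list(best$coef)
  if (co$bottom > co$top) {  # canonicalise a decreasing parameterisation
    tmp <- co$bottom; co$bottom <- co$top; co$top <- tmp
    co$hill <- -co$hill
  }
  # absolute IC50: fitted curve equals half the fitted zero-dose response
  half <- co$top / 2
  ic50 <- if (half <= co$bottom) Inf else {
    u <- (co$top / 2) / (co$top / 2 - co$bottom)
    co$x50 * u^(1 / co$hill)
  }
  censored <- !is.finite(ic50) || ic50 > max_dose
  structure(list(bottom = co$bottom, top = co$top, x50 = co$x50,
                 hill = co$hill, ic50 = ic50, censored = censored,
                 converged = TRUE, rss = best$rss, max_dose = max_dose),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("dose_response_fit: IC50 > %g (censored)\n", x$max_dose))
  } else {
    cat(sprintf(
      "dose_response_fit: IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g\n",
      x$ic50, x$hill, x$top, x$bottom))
  }
  invisible(x)
}

#' Assemble a population-by-day IC50 heatmap matrix
#'
#' @param fits data.frame with columns `population`, `day`, `ic50`
#'   (uM; `Inf` for censored fits), or a named list of
#'   `dose_response_fit`s keyed "population.day".
#' @param log10 log-transform the values (default TRUE).
#' @return list with `matrix` (populations x days, `NA` for missing
#'   cells, `Inf` carried through for censored fits) and `censored`
#'   (logical mask).
#' @export
ic50_timecourse <- function(fits, log10 = TRUE) {
  if (is.list(fits) && !is.data.frame(fits)) {
    keys <- strsplit(names(fits), ".", fixed = TRUE)
    fits <- data.frame(
      population = vapply(keys, `[`, "", 1),
      day = as.numeric(vapply(keys, `[`, "", 2)),
      ic50 = vapply(fits, function(f) f$ic50, numeric(1)))
  }
  gs_assert(all(c("population", "day", "ic50") %in% names(fits)),
            "`fits` needs population, day, ic50")
  pops <- unique(fits$population); days <- sort(unique(fits$day))
  m <- matrix(NA_real_, length(pops), length(days),
              dimnames = list(pops, days))
  for (i in seq_len(nrow(fits))) {
    m[fits$population[i], as.character(fits$day[i])] <- fits$ic50[i]
  }
  cens <- is.infinite(m)
  if (log10) m <- log10(m)
  list(matrix = m, censored = cens)
}

#' Generations elapsed in a serial-transfer design
#'
#' A 1:`dilution` daily transfer requires `log2(dilution)` doublings to
#' regrow, so `days` transfers give `days * log2(dilution)` doublings;
#' 7 days at 1:200 gives 53.507, i.e. ~53 completed generations.
#'
#' @param days number of daily transfers (>= 1).
#' @param dilution fold dilution per transfer (> 1).
#' @return list with `exact` (real) and `completed` (floor).
#' @export
generations <- function(days, dilution) {
  if (is.list(days)) { dilution <- days$dilution; days <- days$days }
  gs_assert(is_count(days), "`days` must be a positive integer")
  gs_assert(is_pos_num(dilution) && dilution > 1, "`dilution` must be > 1")
  exact <- days * log2(dilution)
  list(exact = exact, completed = floor(exact))
}
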