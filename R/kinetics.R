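## ---------------------------------------------------------------------------
## Containers
## ---------------------------------------------------------------------------

#' Microtubule length-vs-time trace
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param length Microtubule lengths in micrometres, `>= 0`.
#' @param addition_time Time (s) at which motor protein was added; must lie
#'   within the record span.
#' @param interval Imaging interval (s).
#' @param id Optional microtubule identifier.
#' @return An object of class `length_trace`.
#' @export
length_trace <- function(time, length, addition_time = min(time),
                         interval = stats::median(diff(time)), id = NA) {
  stopifnot(length(time) == base::length(length))
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(length < 0)) stop("lengths must be >= 0")
  if (addition_time < min(time) || addition_time > max(time))
    stop("addition time outside the record span")
  structure(list(time = time, length = length,
                 addition_time = addition_time, interval = interval, id = id),
            class = "length_trace")
}

#' Single-molecule dwell-time event set
#'
#' @param duration Observed event durations (s), each at least one frame
#'   interval.
#' @param location `"end"` or `"lattice"` per event.
#' @param censored Logical per event: `TRUE` if the event was cut off by the
#'   movie boundary.
#' @param movie_length Movie duration (s).
#' @param frame_interval Frame interval (s), i.e. 1 / frame rate.
#' @param mt_length Microtubule length (µm).
#' @param concentration Motor concentration (nM).
#' @param observation_time Total observation time (s); defaults to
#'   `movie_length`.
#' @return An object of class `dwell_set`.
#' @export
dwell_set <- function(duration, location, censored = rep(FALSE, length(duration)),
                      movie_length, frame_interval, mt_length = NA,
                      concentration = NA, observation_time = movie_length) {
  stopifnot(length(duration) == length(location),
            length(duration) == length(censored))
  if (length(duration) && any(duration < frame_interval - 1e-9))
    stop("durations must be at least one frame interval")
  if (!all(location %in% c("end", "lattice")))
    stop("location must be 'end' or 'lattice'")
  structure(list(duration = duration, location = location,
                 censored = as.logical(censored),
                 movie_length = movie_length, frame_interval = frame_interval,
                 mt_length = mt_length, concentration = concentration,
                 observation_time = observation_time),
            class = "dwell_set")
}

#' ATPase progress assay
#'
#' @param time Time points (s), at least 3.
#' @param signal `[ADP]` in µM (`mode = "hplc_adp"`) or absorbance
#'   (`mode = "nadh_coupled"`).
#' @param motor Motor active-site concentration (µM), `> 0`.
#' @param mode `"hplc_adp"` or `"nadh_coupled"`.
#' @param extinction NADH extinction coefficient (M^-1 cm^-1), coupled mode;
#'   default 6220.
#' @param path_length Cuvette path length (cm), coupled mode.
#' @return An object of class `atpase_assay`.
#' @export
atpase_assay <- function(time, signal, motor,
                         mode = c("hplc_adp", "nadh_coupled"),
                         extinction = 6220, path_length = 1) {
  mode <- match.arg(mode)
  stopifnot(length(time) == length(signal))
  if (length(time) < 3) stop("need at least 3 time points")
  if (motor <= 0) stop("motor concentration must be > 0")
  structure(list(time = time, signal = signal, motor = motor, mode = mode,
                 extinction = extinction, path_length = path_length),
            class = "atpase_assay")
}

#' Named kinetic rate table
#'
#' The surface for comparative analyses: one row per condition/quantity with
#' the measured mean, sample s.d., replicate count and units.
#'
#' @param label Condition label (e.g. `"Anc13"`).
#' @param quantity Measured quantity (e.g. `"depolymerization"`).
#' @param value Mean rate, `>= 0`.
#' @param sd Sample standard deviation.
#' @param n Replicate count (`NA` when unreported).
#' @param units Unit string.
#' @return A data.frame of class `rate_table`.
#' @export
rate_table <- function(label, quantity, value, sd = NA_real_, n = NA_integer_,
                       units = NA_character_) {
  if (any(value < 0)) stop("rates must be >= 0")
  if (any(!is.na(n) & n < 1)) stop("n must be >= 1")
  structure(data.frame(label = label, quantity = quantity, value = value,
                       sd = sd, n = n, units = units,
                       stringsAsFactors = FALSE),
            class = c("rate_table", "data.frame"))
}

#' Microtubule lattice geometry constants
#'
#' @param rise_nm Tubulin dimer rise along a protofilament (nm), default 8.
#' @param protofilaments Protofilament number, default 13.
#' @return List with `rise_nm`, `protofilaments` and the derived
#'   `dimers_per_um` (default 1625).
#' @export
geometry_constants <- function(rise_nm = 8, protofilaments = 13) {
  list(rise_nm = rise_nm, protofilaments = protofilaments,
       dimers_per_um = 1000 / rise_nm * protofilaments)
}

## ---------------------------------------------------------------------------
## Estimators
## ---------------------------------------------------------------------------

#' Depolymerization rate from a length trace
#'
#' Ordinary least-squares line on length vs time from the protein-addition
#' time to the end of shrinkage. The end of shrinkage is found iteratively:
#' the fit window is cut where the fitted line crosses the resolution floor,
#' so the truncation is in time and does not select on measurement noise.
#' The rate is reported as total length loss per minute (both ends
#' combined); growing microtubules give a signed negative rate.
#'
#' @param trace A [length_trace()].
#' @param window Optional `c(t0, t1)` overriding the fit window (s).
#' @param floor Resolution floor (µm), default 0.5.
#' @param method `"ols"` (default) or `"theil_sen"` for traces with pauses.
#' @return List: `rate` (µm/min), `se` (µm/min), `n_points`, `slope`
#'   (µm/s), `r_squared`.
#' @export
depolymerization_rate <- function(trace, window = NULL, floor = 0.5,
                                  method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "length_trace"))
  t0 <- if (is.null(window)) trace$addition_time else window[1]
  t1 <- if (is.null(window)) max(trace$time) else window[2]
  sel <- trace$time >= t0 & trace$time <= t1
  tt <- trace$time[sel]; ll <- trace$length[sel]
  slope_of <- function(t, l) {
    if (method == "ols") unname(stats::coef(stats::lm(l ~ t))[2])
    else {
      ij <- utils::combn(length(t), 2)
      stats::median((l[ij[2, ]] - l[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
    }
  }
  ## seed the window from the observed values, then refine it in time
  keep <- ll >= floor
  if (sum(keep) < 3) stop("too few points after addition time (", sum(keep), ")")
  win <- tt <= max(tt[keep])
  for (iter in 1:5) {
    if (stats::sd(tt[win]) == 0) stop("zero variance in time")
    b <- slope_of(tt[win], ll[win])
    a <- mean(ll[win]) - b * mean(tt[win])
    t_cut <- if (b < 0) (floor - a) / b else Inf        # line hits the floor
    new_win <- tt <= max(t_cut, sort(tt)[3])            # keep >= 3 points
    if (identical(new_win, win)) break
    win <- new_win
  }
  tt <- tt[win]; ll <- ll[win]
  if (length(tt) < 3) stop("too few points after addition time (", length(tt), ")")
  if (stats::sd(tt) == 0) stop("zero variance in time")
  if (method == "ols") {
    fit <- stats::lm(ll ~ tt)
    sm <- suppressWarnings(summary(fit))   # exact lines warn harmlessly
    slope <- unname(stats::coef(fit)[2])
    se <- sm$coefficients[2, 2]
    r2 <- sm$r.squared
  } else {
    slope <- slope_of(tt, ll)
    se <- NA_real_
    r2 <- NA_real_
  }
  list(rate = -slope * 60, se = se * 60, n_points = length(tt),
       slope = slope, r_squared = r2)
}

#' Aggregate replicate rates
#'
#' @param rates Numeric vector of per-microtubule (or per-assay) rates.
#' @return List: `mean`, `sd` (sample s.d., 0 with `single = TRUE` flag for
#'   one value), `n`.
#' @export
aggregate_rates <- function(rates) {
  if (length(rates) == 0L) stop("no rates to aggregate")
  single <- length(rates) == 1L
  list(mean = mean(rates), sd = if (single) 0 else stats::sd(rates),
       n = length(rates), single = single)
}

#' Censored-exponential MLE of the detachment rate k_off
#'
#' `k = U / sum(d_i - d_min)` where `U` counts uncensored events and
#' `d_min` is the minimum observable duration (one frame interval),
#' subtracted from every event to correct the acquisition bias of
#' frame-overlap duration measurement. Right-censored events contribute
#' exposure but no event count. The confidence interval is from the profile
#' likelihood.
#'
#' @param dwells A [dwell_set()].
#' @param location `"end"`, `"lattice"` or `"all"`.
#' @param conf Confidence level for the profile-likelihood interval.
#' @return List: `k_off` (s^-1), `se`, `ci` (length 2), `n_events`,
#'   `n_censored`.
#' @export
koff_mle <- function(dwells, location = c("all", "end", "lattice"),
                     conf = 0.95) {
  location <- match.arg(location)
  sel <- if (location == "all") rep(TRUE, length(dwells$duration))
         else dwells$location == location
  d <- dwells$duration[sel]
  cen <- dwells$censored[sel]
  if (!any(!cen)) stop("rate unidentifiable: all events censored")
  U <- sum(!cen)
  S <- sum(pmax(d - dwells$frame_interval, 0))
  if (S <= 0) stop("no exposure after frame-interval correction")
  k <- U / S
  se <- k / sqrt(U)
  ll <- function(x) U * log(x) - x * S
  drop <- stats::qchisq(conf, 1) / 2
  target <- ll(k) - drop
  lo <- stats::uniroot(function(x) ll(x) - target, c(k * 1e-3, k))$root
  hi <- stats::uniroot(function(x) ll(x) - target, c(k, k * 1e3))$root
  list(k_off = k, se = se, ci = c(lo, hi), n_events = U, n_censored = sum(cen))
}

#' Attachment rate k_on per concentration per microtubule length
#'
#' `k_on = N / (T * L * c)` for `N` binding events over observation time `T`
#' (s), microtubule length `L` (µm) and motor concentration `c` (nM).
#'
#' @param dwells A [dwell_set()] with `mt_length`, `concentration` and
#'   `observation_time` set.
#' @return List: `k_on` (nM^-1 s^-1 µm^-1), `se` (Poisson), `n_events`.
#' @export
kon_rate <- function(dwells) {
  denom <- dwells$observation_time * dwells$mt_length * dwells$concentration
  if (!isTRUE(denom > 0)) stop("observation time, length and concentration must be > 0")
  n <- length(dwells$duration)
  if (n == 0L) warning("no binding events observed: k_on estimate is 0")
  list(k_on = n / denom, se = sqrt(n) / denom, n_events = n)
}

#' Proportion of long binding events
#'
#' Uncensored events are compared with the threshold directly; censored
#' events already longer than the threshold count as long, while censored
#' events shorter than it are uninformative and excluded.
#'
#' @param dwells A [dwell_set()].
#' @param threshold Duration threshold (s), default 2.
#' @param location `"all"`, `"end"` or `"lattice"`.
#' @return Proportion of events with duration greater than `threshold`.
#' @export
fraction_long_events <- function(dwells, threshold = 2,
                                 location = c("all", "end", "lattice")) {
  location <- match.arg(location)
  sel <- if (location == "all") rep(TRUE, length(dwells$duration))
         else dwells$location == location
  d <- dwells$duration[sel]; cen <- dwells$censored[sel]
  if (length(d) == 0L) stop("no events")
  long <- sum(d[!cen] > threshold) + sum(d[cen] > threshold)
  denom <- sum(!cen) + sum(cen & d > threshold)
  long / denom
}

#' ATPase turnover per active site
#'
#' HPLC mode fits a line to `[ADP]` vs time and divides the slope by the
#' motor concentration. Coupled mode converts the absorbance slope through
#' the NADH extinction coefficient (`-dA/dt / (eps * path)`, in M/s, then
#' µM/s) before dividing.
#'
#' @param assay An [atpase_assay()].
#' @return List: `rate` (s^-1 per active site), `se`, `slope`.
#' @export
atpase_rate <- function(assay) {
  stopifnot(inherits(assay, "atpase_assay"))
  fit <- stats::lm(assay$signal ~ assay$time)
  sm <- suppressWarnings(summary(fit))     # exact lines warn harmlessly
  slope <- unname(stats::coef(fit)[2])
  slope_se <- sm$coefficients[2, 2]
  if (assay$mode == "hplc_adp") {
    if (slope < -3 * slope_se)
      stop("decreasing [ADP] is inconsistent with hplc_adp mode")
    adp_per_s <- slope                       # µM/s
    adp_se <- slope_se
  } else {
    if (slope > 3 * slope_se)
      stop("increasing absorbance is inconsistent with nadh_coupled mode")
    noise <- max(stats::sd(stats::residuals(fit)), 1e-8)
    if (any(diff(assay$signal) > 6 * noise))
      warning("non-monotone coupled-assay signal beyond noise floor")
    adp_per_s <- -slope / (assay$extinction * assay$path_length) * 1e6  # µM/s
    adp_se <- slope_se / (assay$extinction * assay$path_length) * 1e6
  }
  list(rate = adp_per_s / assay$motor, se = adp_se / assay$motor,
       slope = slope)
}

## ---------------------------------------------------------------------------
## Comparative layer
## ---------------------------------------------------------------------------

rt_row <- function(rates, label, quantity = NULL) {
  sel <- rates$label == label
  if (!is.null(quantity)) sel <- sel & rates$quantity == quantity
  i <- which(sel)
  if (length(i) != 1L)
    stop("rate table must contain exactly one row for label '", label,
         "', quantity '", quantity, "' (found ", length(i), ")")
  rates[i, ]
}

#' Fold change between two rate-table entries
#'
#' Ratio of mean rates; the uncertainty of the log ratio combines the two
#' standard errors (`sd/sqrt(n)`) in quadrature. Entries without a reported
#' `n` use `sd` directly as the standard error.
#'
#' @param rates A [rate_table()].
#' @param numerator,denominator Condition labels.
#' @param quantity Quantity to compare (must match both rows).
#' @return List: `ratio`, `se` (of the ratio, delta method), `log_se`.
#' @export
fold_change <- function(rates, numerator, denominator, quantity = NULL) {
  a <- rt_row(rates, numerator, quantity)
  b <- rt_row(rates, denominator, quantity)
  if (b$value <= 0) stop("denominator rate must be > 0")
  ratio <- a$value / b$value
  se_of <- function(r) {
    if (is.na(r$sd)) return(NA_real_)
    if (is.na(r$n)) r$sd else r$sd / sqrt(r$n)
  }
  rel <- c(se_of(a) / a$value, se_of(b) / b$value)
  log_se <- if (anyNA(rel)) NA_real_ else sqrt(sum(rel^2))
  list(ratio = ratio, se = ratio * log_se, log_se = log_se)
}

#' Tubulin dimers removed per ATP hydrolyzed
#'
#' Relative coupling: `S_target = S_comp * (v_t / v_c) * (k_c / k_t)` with
#' depolymerization rates `v` and microtubule-stimulated ATPase rates `k`,
#' anchored to a comparator of known stoichiometry (MCAK removes on average
#' 1 tubulin per ATP on GMPCPP-stabilized microtubules). When `end_motors`
#' (motors acting per microtubule) is supplied, the absolute route
#' `v * dimers_per_um / 60 / (k * end_motors)` is used instead.
#'
#' @param rates A [rate_table()] containing `"depolymerization"` and
#'   `"atpase_mt"` rows for both labels.
#' @param target Target condition label.
#' @param comparator Comparator condition label.
#' @param comparator_stoichiometry Tubulins per ATP for the comparator
#'   (default 1).
#' @param geometry [geometry_constants()] for the absolute route.
#' @param end_motors Optional number of motors acting per microtubule; when
#'   given, the absolute calculation is performed for the target alone.
#' @return List: `stoichiometry` (tubulins per ATP), `se`, `route`.
#' @export
tubulins_per_atp <- function(rates, target, comparator,
                             comparator_stoichiometry = 1,
                             geometry = geometry_constants(),
                             end_motors = NULL) {
  vt <- rt_row(rates, target, "depolymerization")
  kt <- rt_row(rates, target, "atpase_mt")
  if (kt$value <= 0) stop("zero ATPase rate for target")
  if (!is.null(end_motors)) {
    dimers_per_s <- vt$value / 60 * geometry$dimers_per_um
    s <- dimers_per_s / (kt$value * end_motors)
    return(list(stoichiometry = s, se = NA_real_, route = "absolute"))
  }
  vc <- rt_row(rates, comparator, "depolymerization")
  kc <- rt_row(rates, comparator, "atpase_mt")
  if (kc$value <= 0 || vc$value <= 0) stop("zero comparator rate")
  s <- comparator_stoichiometry * (vt$value / vc$value) * (kc$value / kt$value)
  rel <- function(r) if (is.na(r$sd)) NA_real_ else
    (if (is.na(r$n)) r$sd else r$sd / sqrt(r$n)) / r$value
  rels <- c(rel(vt), rel(vc), rel(kt), rel(kc))
  se <- if (anyNA(rels)) NA_real_ else s * sqrt(sum(rels^2))
  list(stoichiometry = s, se = se, route = "relative")
}

#' Frequency of internal microtubule breaking
#'
#' @param records Data frame with columns `length` (µm) and `breaks`
#'   (internal break count per microtubule).
#' @param min_length Only microtubules longer than this (µm) are counted;
#'   default 5.
#' @return List: `proportion`, `n`.
#' @export
break_frequency <- function(records, min_length = 5) {
  stopifnot(all(c("length", "breaks") %in% names(records)))
  keep <- records$length > min_length
  if (!any(keep)) stop("no microtubules longer than ", min_length, " um")
  list(proportion = mean(records$breaks[keep] >= 1), n = sum(keep))
}

## ---------------------------------------------------------------------------
## Published comparative inputs
## ---------------------------------------------------------------------------

#' Measured kinesin-13 rates used for comparative analysis
#'
#' The published mean, s.d. and n for depolymerization rates,
#' single-molecule on/off rates and ATPase turnover of the ancestral motor
#' (Anc13), consensus motor (Con13), MCAK and derived constructs. These are
#' wet-lab measurements: they enter this package only as inputs to the
#' ratio, percentage and stoichiometry operations.
#'
#' @return A [rate_table()].
#' @export
kinesin13_rates <- function() {
  rbind(
    rate_table(c("MCAK", "MCAK-EGFP", "Con13", "Anc13", "MCAK-M",
                 "MCAK+taxol", "Anc13+taxol", "Anc13+ADP", "basal",
                 "MCAK-Anc13"),
               "depolymerization",
               c(2.12, 1.38, 0.67, 23.05, 2.11, 0.02, 1.01, 0.04, 0.02, 19.50),
               c(0.17, 0.15, 0.28, 5.23, 0.87, 0.01, 0.59, 0.01, 0.01, 4.87),
               c(18L, 6L, 13L, 12L, 18L, 6L, 12L, 6L, 12L, NA),
               "um/min"),
    rate_table(c("Anc13", "MCAK"), "kon", c(62.4, 0.52), c(21.5, 0.34),
               NA_integer_, "nM-1 s-1 um-1"),
    rate_table(c("Anc13", "MCAK"), "koff_lattice", c(1.36, 2.90),
               c(0.06, 0.16), NA_integer_, "s-1"),
    rate_table(c("Anc13", "MCAK"), "koff_end", c(1.23, 0.98),
               c(0.10, 0.06), NA_integer_, "s-1"),
    rate_table(c("Anc13", "MCAK"), "atpase_basal", c(0.44, 0.002),
               c(0.04, 0.001), c(3L, 4L), "s-1"),
    rate_table(c("Anc13", "MCAK"), "atpase_tubulin", c(3.76, 0.25),
               c(0.81, 0.10), c(8L, 7L), "s-1"),
    rate_table(c("Anc13", "MCAK"), "atpase_mt", c(8.07, 3.69),
               c(0.63, 0.38), c(3L, 4L), "s-1")
  )
}
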