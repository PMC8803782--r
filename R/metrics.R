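# Node-level performance assessment: region-node matching, sensitivity and
# FPs/patient, Cohen's kappa under the fixed 8.3-nodes-per-patient
# true-negative convention, exact Clopper-Pearson intervals, and recovery of
# integer counts from printed 2-dp rates.

#' Round half away from zero
#'
#' Printed clinical tables round half up; R's `round()` rounds half to even,
#' so comparisons against printed values use this instead.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Match predicted regions against ground-truth nodes
#'
#' A node is detected iff its centre lies inside at least one predicted
#' region; TP counts detected nodes, FN undetected nodes, and FP regions
#' containing no node centre. TP is per node and FP per region, the only
#' assignment under which `tp + fn` equals the node total while FPs/patient
#' stays region-based. Region sizes are also summarised so the requirement
#' that predictions localise (rather than blanket) the nodes is reportable.
#'
#' @param predictions named list (by patient) of `candidate_region` lists.
#' @param nodes_by_patient named list (by patient) of `node_annotations`.
#' @param geometries named list (by patient) of [volume3d] crop grids.
#' @return A `detection_counts` list: `tp`, `fp`, `fn`, `n_patients`,
#'   `n_nodes`, `per_patient` data.frame and region-size statistics.
#' @export
match_detections <- function(predictions, nodes_by_patient, geometries) {
  patients <- names(geometries)
  unknown <- setdiff(names(predictions), patients)
  if (length(unknown))
    stop("match_detections: predictions reference unknown patient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tp <- fp <- fn <- 0L
  per <- list()
  diams <- numeric()
  for (pid in patients) {
    regs <- predictions[[pid]] %||% list()
    nodes <- nodes_by_patient[[pid]]
    geom <- geometries[[pid]]
    d <- dim(geom$values)
    lab <- array(0L, d)
    for (i in seq_along(regs)) lab[regs[[i]]$voxels] <- i
    hit_regions <- integer()
    det <- 0L
    nn <- if (is.null(nodes)) 0L else nrow(nodes)
    for (r in seq_len(nn)) {
      v <- physical_to_voxel(geom, c(nodes$x_mm[r], nodes$y_mm[r],
                                     nodes$z_mm[r]))
      inside <- all(v >= 1) && all(v <= d) && lab[v] > 0L
      if (inside) {
        det <- det + 1L
        hit_regions <- c(hit_regions, lab[v])
      }
    }
    p_fp <- length(regs) - length(unique(hit_regions))
    tp <- tp + det
    fn <- fn + (nn - det)
    fp <- fp + p_fp
    diams <- c(diams, vapply(regs, function(rg)
      max((rg$bounding_box["max", ] - rg$bounding_box["min", ] + 1) *
            geom$spacing), numeric(1)))
    per[[pid]] <- data.frame(patient_id = pid, nodes = nn, tp = det,
                             fn = nn - det, fp = p_fp,
                             n_regions = length(regs))
  }
  structure(list(
    tp = tp, fp = fp, fn = fn,
    n_patients = length(patients),
    n_nodes = tp + fn,
    region_extent_mm = c(mean = if (length(diams)) mean(diams) else NA_real_,
                         max = if (length(diams)) max(diams) else NA_real_),
    per_patient = do.call(rbind, c(per, list(make.row.names = FALSE)))),
    class = "detection_counts")
}

#' Assemble detection counts directly
#'
#' For worked examples where TP/FP/FN are already known (e.g. recovered
#' from printed rates).
#'
#' @param tp,fp,fn integer counts.
#' @param n_patients number of patients.
#' @return A `detection_counts`.
#' @export
detection_counts <- function(tp, fp, fn, n_patients) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, n_patients >= 1)
  structure(list(tp = tp, fp = fp, fn = fn, n_patients = n_patients,
                 n_nodes = tp + fn,
                 region_extent_mm = c(mean = NA_real_, max = NA_real_),
                 per_patient = NULL),
            class = "detection_counts")
}

#' Sensitivity and false positives per patient
#'
#' `sensitivity = tp / (tp + fn)`; `fps_per_patient = fp / n_patients`.
#'
#' @param counts a `detection_counts`.
#' @return a fraction (sensitivity; `NaN` with a warning when there are no
#'   nodes) or a rate.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0L) {
    warning("sensitivity undefined: no ground-truth nodes")
    return(NaN)
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
fps_per_patient <- function(counts) counts$fp / counts$n_patients

#' Fractional true negatives under the nodes-per-patient convention
#'
#' `tn = rate * n_patients - (tp + fp + fn)`, with the published rate of
#' 8.3 nodes per patient; the result may be fractional and is used as-is.
#'
#' @param counts a `detection_counts`.
#' @param nodes_per_patient the convention rate (default 8.3).
#' @return numeric TN (possibly fractional).
#' @export
convention_tn <- function(counts, nodes_per_patient = 8.3) {
  tn <- nodes_per_patient * counts$n_patients -
    (counts$tp + counts$fp + counts$fn)
  if (tn < 0)
    stop("convention_tn: negative TN; counts exceed the convention total",
         call. = FALSE)
  tn
}

#' Cohen's kappa for a detection 2x2 table
#'
#' Two-rater chance-corrected agreement with
#' `N = tp + fp + fn + tn`, `p_o = (tp + tn) / N` and
#' `p_e = ((tp+fn)(tp+fp) + (fp+tn)(fn+tn)) / N^2`; TN comes from the
#' fixed nodes-per-patient convention and may be fractional. The magnitude
#' is qualified with the Landis-Koch bands.
#'
#' @param counts a `detection_counts`, or `NULL` when `tp`..`tn` are given.
#' @param tp,fp,fn,tn explicit cell values (override `counts`).
#' @param nodes_per_patient convention rate for the derived TN.
#' @return list with `kappa`, `band`, `tn`, `p_o`, `p_e`.
#' @export
cohen_kappa <- function(counts = NULL, tp = NULL, fp = NULL, fn = NULL,
                        tn = NULL, nodes_per_patient = 8.3) {
  if (!is.null(counts)) {
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
    if (is.null(tn)) tn <- convention_tn(counts, nodes_per_patient)
  }
  stopifnot(!is.null(tp), !is.null(fp), !is.null(fn), !is.null(tn))
  n <- tp + fp + fn + tn
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  if (abs(1 - p_e) < 1e-12)
    stop("cohen_kappa: degenerate table (chance agreement = 1)",
         call. = FALSE)
  k <- (p_o - p_e) / (1 - p_e)
  list(kappa = k, band = landis_koch_band(k), tn = tn, p_o = p_o, p_e = p_e)
}

#' Landis-Koch qualitative agreement band
#'
#' @param kappa kappa value in `[-1, 1]`.
#' @return character band label.
#' @export
landis_koch_band <- function(kappa) {
  if (kappa > 1 || kappa < -1) stop("kappa outside [-1, 1]", call. = FALSE)
  if (kappa > 0.80) "almost perfect"
  else if (kappa > 0.60) "substantial"
  else if (kappa > 0.40) "moderate"
  else if (kappa > 0.20) "fair"
  else if (kappa > 0) "slight"
  else "poor"
}

#' Exact Clopper-Pearson confidence interval
#'
#' The exact binomial interval by inversion of the binomial tails,
#' computed through the beta quantile form: lower = Beta(alpha/2; x, n-x+1)
#' (0 when x = 0), upper = Beta(1-alpha/2; x+1, n-x) (1 when x = n).
#'
#' @param successes,trials integer counts, `0 <= successes <= trials`.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials))
    stop("clopper_pearson: need integer 0 <= successes <= trials, trials >= 1",
         call. = FALSE)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Recover an integer count from a printed 2-dp rate
#'
#' Finds the integer `k` with `round(k / denominator, 2) = printed_rate`
#' (half-up rounding, as printed tables use). Zero or multiple candidates
#' raise an ambiguity error listing them: ambiguity is surfaced, never
#' resolved silently.
#'
#' @param printed_rate the rate as printed (2 decimal places).
#' @param denominator the known integer denominator.
#' @param digits decimal places of the printed rate.
#' @return the unique integer numerator.
#' @export
recover_count <- function(printed_rate, denominator, digits = 2) {
  if (denominator < 1) stop("recover_count: denominator must be >= 1",
                            call. = FALSE)
  k_max <- ceiling((printed_rate + 10^(-digits)) * denominator) + 1
  ks <- 0:k_max
  hits <- ks[round_half_up(ks / denominator, digits) ==
               round_half_up(printed_rate, digits)]
  if (length(hits) != 1L)
    stop("recover_count: ", if (length(hits)) "ambiguous" else "no",
         " integer count for rate ", printed_rate, " over ", denominator,
         if (length(hits)) paste0(" (candidates: ",
                                  paste(hits, collapse = ", "), ")") else "",
         call. = FALSE)
  hits
}

#' Evaluate a cohort of detections
#'
#' Assembles counts, sensitivity with its exact Clopper-Pearson CI
#' (successes = TP, trials = TP + FN), FPs/patient with a
#' convention-dependent CI (FP successes over the rounded
#' `8.3 * n_patients` convention total), and Cohen's kappa with its
#' Landis-Koch band.
#'
#' @param counts a `detection_counts` (from [match_detections()] or
#'   [detection_counts()]).
#' @param nodes_per_patient TN convention rate.
#' @param level CI level.
#' @return An `eval_summary` list; `as_report()` renders it as text and
#'   [write_eval_summary()] as JSON.
#' @export
evaluate_cohort <- function(counts, nodes_per_patient = 8.3, level = 0.95) {
  sens <- sensitivity(counts)
  fpp <- fps_per_patient(counts)
  sens_ci <- if (!is.nan(sens))
    clopper_pearson(counts$tp, counts$tp + counts$fn, level)
  else c(lower = NaN, upper = NaN)
  conv_total <- round(nodes_per_patient * counts$n_patients)
  fpp_ci <- clopper_pearson(counts$fp, conv_total, level) *
    conv_total / counts$n_patients
  kap <- cohen_kappa(counts, nodes_per_patient = nodes_per_patient)
  structure(list(
    counts = counts,
    sensitivity = sens, sensitivity_ci = sens_ci,
    fps_per_patient = fpp, fps_per_patient_ci = fpp_ci,
    fps_ci_note = "convention-dependent: exact binomial on (fp, round(8.3 x patients))",
    kappa = kap$kappa, kappa_band = kap$band, tn = kap$tn,
    level = level, nodes_per_patient = nodes_per_patient),
    class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(as_report(x), sep = "\n")
  invisible(x)
}

#' @rdname evaluate_cohort
#' @param summary an `eval_summary`.
#' @export
as_report <- function(summary) {
  s <- summary
  c(sprintf("Patients: %d   nodes: %d   TP %d  FP %d  FN %d  TN %.1f",
            s$counts$n_patients, s$counts$n_nodes, s$counts$tp, s$counts$fp,
            s$counts$fn, s$tn),
    sprintf("Sensitivity: %.2f [%.2f, %.2f]", s$sensitivity,
            s$sensitivity_ci["lower"], s$sensitivity_ci["upper"]),
    sprintf("FPs/patient: %.2f [%.2f, %.2f] (%s)", s$fps_per_patient,
            s$fps_per_patient_ci["lower"], s$fps_per_patient_ci["upper"],
            s$fps_ci_note),
    sprintf("Cohen's kappa: %.2f (%s agreement)", s$kappa, s$kappa_band))
}

#' @rdname evaluate_cohort
#' @param path JSON output path.
#' @export
write_eval_summary <- function(summary, path) {
  out <- unclass(summary)
  out$counts <- list(tp = summary$counts$tp, fp = summary$counts$fp,
                     fn = summary$counts$fn,
                     n_patients = summary$counts$n_patients,
                     n_nodes = summary$counts$n_nodes,
                     per_patient = summary$counts$per_patient)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
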