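#' Configuration for the synthetic sarcoma cohort generator
#'
#' Defaults emulate the study conditions the screening method was
#' designed for: the 88-patient subtype composition (20 UPS, 20 MLS,
#' 17 SS, 15 MFS, 6 LMS, 5 FS, 5 MPNST), subtype-ordered survival
#' (MFS best, UPS worst), administrative right-censoring at 50 months,
#' grade and metastasis covariates linked to subtype malignancy, and
#' non-negative MAS5-like signals with absent calls concentrated at low
#' signal.  Planted probes carry a subtype mean shift (diagnostic), a
#' survival association (prognostic), or both.
#'
#' @param subtype_counts Named integer vector of patients per subtype.
#' @param n_probes Total probes simulated.
#' @param n_control Probes flagged as array controls.
#' @param n_crosshyb Probes flagged as cross-hybridizing.
#' @param frac_diagnostic,frac_prognostic,frac_both Fractions of the
#'   non-flagged probes planted with each effect class (sum must be
#'   at most 1).
#' @param subtype_effect_size Planted log2-scale mean shift applied to
#'   one designated subtype for diagnostic/both probes.
#' @param hazard_log_hr Planted log hazard ratio between the high and
#'   low latent prognostic groups for prognostic/both probes.
#' @param prognostic_loading Log2-signal shift separating the high from
#'   the low latent group on prognostic/both probes.
#' @param base_hazard_by_subtype Named baseline monthly event rates.
#' @param censor_admin_months Administrative censoring horizon (months).
#' @param noise_sd Residual log2-signal standard deviation.
#' @param baseline_log2_range Range of per-probe baseline log2 means.
#' @param absent_midpoint,absent_slope Logistic absent-call model:
#'   P(A) = plogis((absent_midpoint - log2 signal) * absent_slope).
#' @param grade_probs_by_malignancy 3 x 3 matrix of grade probabilities
#'   (rows: low/intermediate/high-malignancy subtype; columns grade 1-3).
#' @param metastasis_prob_by_grade Probability of metastasis per grade.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(subtype_counts = c(UPS = 20, MLS = 20, SS = 17,
                                          MFS = 15, LMS = 6, FS = 5,
                                          MPNST = 5),
                       n_probes = 300,
                       n_control = 10,
                       n_crosshyb = 20,
                       frac_diagnostic = 0.05,
                       frac_prognostic = 0.05,
                       frac_both = 0.05,
                       subtype_effect_size = 1.5,
                       hazard_log_hr = 1.5,
                       prognostic_loading = 1.2,
                       base_hazard_by_subtype = c(MFS = 0.004, MLS = 0.010,
                                                  SS = 0.012, FS = 0.015,
                                                  LMS = 0.020, MPNST = 0.025,
                                                  UPS = 0.030),
                       censor_admin_months = 50,
                       noise_sd = 0.7,
                       baseline_log2_range = c(6, 12),
                       absent_midpoint = 6,
                       absent_slope = 1.2,
                       grade_probs_by_malignancy =
                         rbind(low = c(0.55, 0.35, 0.10),
                               mid = c(0.15, 0.45, 0.40),
                               high = c(0.03, 0.17, 0.80)),
                       metastasis_prob_by_grade = c(0.15, 0.35, 0.65),
                       seed = 1L) {
  if (any(subtype_counts < 0) || sum(subtype_counts) < 1) {
    stopf("subtype_counts must be non-negative with at least one patient")
  }
  bad <- setdiff(names(subtype_counts), sts_subtypes())
  if (length(bad)) stopf("unknown subtype(s) in config: %s", paste(bad, collapse = ", "))
  fr <- frac_diagnostic + frac_prognostic + frac_both
  if (fr > 1) stopf("effect fractions sum to %.2f > 1", fr)
  if (any(base_hazard_by_subtype <= 0)) stopf("baseline hazards must be > 0")
  if (n_probes < 1) stopf("n_probes must be >= 1")
  structure(list(subtype_counts = subtype_counts, n_probes = n_probes,
                 n_control = n_control, n_crosshyb = n_crosshyb,
                 frac_diagnostic = frac_diagnostic,
                 frac_prognostic = frac_prognostic, frac_both = frac_both,
                 subtype_effect_size = subtype_effect_size,
                 hazard_log_hr = hazard_log_hr,
                 prognostic_loading = prognostic_loading,
                 base_hazard_by_subtype = base_hazard_by_subtype,
                 censor_admin_months = censor_admin_months,
                 noise_sd = noise_sd,
                 baseline_log2_range = baseline_log2_range,
                 absent_midpoint = absent_midpoint,
                 absent_slope = absent_slope,
                 grade_probs_by_malignancy = grade_probs_by_malignancy,
                 metastasis_prob_by_grade = metastasis_prob_by_grade,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# subtype -> malignancy tier used for the grade multinomial
subtype_malignancy <- c(MLS = "low", MFS = "low", SS = "mid", FS = "mid",
                        LMS = "high", MPNST = "high", UPS = "high")

#' Generate a synthetic clinical cohort
#'
#' Patients are drawn per subtype with exponential event times at the
#' subtype's baseline monthly hazard multiplied by `exp(hazard_log_hr)`
#' when the patient's latent prognostic group is high (the same latent
#' group that shifts prognostic probe expression, so median splits of
#' those probes carry a true hazard contrast).  Follow-up beyond the
#' administrative horizon is censored.  Grade is drawn from a
#' subtype-malignancy multinomial and metastasis is Bernoulli with
#' probability increasing in grade.
#'
#' @param cfg A [sim_config].
#' @return A list with `clinical` (validated clinical data.frame) and
#'   `latent` (per-patient latent prognostic indicator and score).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  counts <- cfg$subtype_counts[cfg$subtype_counts > 0]
  if (!length(counts)) stopf("empty cohort")
  set.seed(derive_seed(cfg$seed, 1L))
  subtype <- rep(names(counts), counts)
  n <- length(subtype)
  patient_id <- sprintf("P%03d", seq_len(n))

  score <- stats::rnorm(n)             # latent prognostic score
  high <- score > 0                    # latent high-risk group
  haz <- cfg$base_hazard_by_subtype[subtype] *
    exp(cfg$hazard_log_hr * as.numeric(high))
  t_event <- stats::rexp(n, rate = haz)
  horizon <- cfg$censor_admin_months
  death_event <- t_event <= horizon
  survival_time <- pmin(t_event, horizon)
  # keep times strictly positive and finitely printable
  survival_time <- pmax(round(survival_time, 2), 0.01)

  tier <- subtype_malignancy[subtype]
  gp <- cfg$grade_probs_by_malignancy
  grade <- vapply(tier, function(tr) {
    sample.int(3L, 1L, prob = gp[tr, ])
  }, integer(1))
  metastasis <- stats::runif(n) < cfg$metastasis_prob_by_grade[grade]
  gender <- sample(c("male", "female"), n, replace = TRUE)
  age <- round(stats::rnorm(n, mean = 54, sd = 16))
  age <- pmin(pmax(age, 15), 90)

  clinical <- as_clinical(data.frame(
    patient_id = patient_id, subtype = subtype, gender = gender, age = age,
    grade = grade, metastasis = metastasis, survival_time = survival_time,
    death_event = death_event, stringsAsFactors = FALSE))
  list(clinical = clinical,
       latent = data.frame(patient_id = patient_id, prognostic_score = score,
                           prognostic_high = high))
}

#' Generate synthetic expression data with planted effects
#'
#' Log2 signals are a per-probe baseline plus planted effects plus
#' Gaussian noise; linear signals are `2^log2`.  Diagnostic and "both"
#' probes shift one designated discrimination subtype's mean by
#' `subtype_effect_size`; prognostic and "both" probes add
#' `prognostic_loading` to patients in the latent high-risk group, the
#' group whose hazard is multiplied by `exp(hazard_log_hr)` in
#' [generate_cohort].  Absent calls follow a logistic model in log2
#' signal; the first `n_control` probes are flagged control and the
#' next `n_crosshyb` cross-hybridizing (both left effect-free).
#'
#' @param cohort Result of [generate_cohort] (list with `clinical` and
#'   `latent`), or a clinical data.frame plus `latent` given separately.
#' @param cfg The same [sim_config] used for the cohort.
#' @return List with `expr` ([expr_mat]), `annotation` (probe
#'   annotation data.frame, MIM numbers assigned to every non-flagged
#'   probe so the knowledge map covers the screen), and `truth`
#'   (per-probe effect class, affected subtype, true log hazard ratio).
#' @export
generate_expression <- function(cohort, cfg = sim_config()) {
  clinical <- cohort$clinical
  latent <- cohort$latent
  n <- nrow(clinical)
  if (n < 1) stopf("cohort is empty")
  set.seed(derive_seed(cfg$seed, 2L))

  p <- cfg$n_probes
  n_flag <- cfg$n_control + cfg$n_crosshyb
  if (n_flag >= p) stopf("n_probes must exceed the flagged probe count")
  p_eff <- p - n_flag                       # candidate probes for effects
  n_diag <- round(cfg$frac_diagnostic * p_eff)
  n_prog <- round(cfg$frac_prognostic * p_eff)
  n_both <- round(cfg$frac_both * p_eff)
  if (n_diag + n_prog + n_both > p_eff) {
    stopf("planted-effect counts exceed available probes")
  }

  probe_id <- sprintf("SYN%04d_at", seq_len(p))
  is_control <- seq_len(p) <= cfg$n_control
  is_cross_hyb <- !is_control & seq_len(p) <= n_flag
  candidates <- which(!is_control & !is_cross_hyb)

  effect_class <- rep("null", p)
  planted <- sample(candidates, n_diag + n_prog + n_both)
  idx_diag <- planted[seq_len(n_diag)]
  idx_prog <- planted[n_diag + seq_len(n_prog)]
  idx_both <- planted[n_diag + n_prog + seq_len(n_both)]
  effect_class[idx_diag] <- "diagnostic"
  effect_class[idx_prog] <- "prognostic"
  effect_class[idx_both] <- "both"

  # each diagnostic/both probe shifts one discrimination subtype, cycled
  affected_subtype <- rep(NA_character_, p)
  idx_shift <- c(idx_diag, idx_both)
  if (length(idx_shift)) {
    affected_subtype[idx_shift] <-
      rep_len(discrimination_subtypes(), length(idx_shift))
  }
  true_log_hr <- ifelse(effect_class %in% c("prognostic", "both"),
                        cfg$hazard_log_hr, 0)

  baseline <- stats::runif(p, cfg$baseline_log2_range[1L],
                           cfg$baseline_log2_range[2L])
  log2sig <- matrix(baseline, nrow = p, ncol = n) +
    matrix(stats::rnorm(p * n, sd = cfg$noise_sd), p, n)
  for (i in idx_shift) {
    hit <- clinical$subtype == affected_subtype[i]
    log2sig[i, hit] <- log2sig[i, hit] + cfg$subtype_effect_size
  }
  prog_rows <- c(idx_prog, idx_both)
  if (length(prog_rows)) {
    log2sig[prog_rows, latent$prognostic_high] <-
      log2sig[prog_rows, latent$prognostic_high] + cfg$prognostic_loading
  }

  signals <- 2^log2sig
  p_absent <- stats::plogis((cfg$absent_midpoint - log2sig) * cfg$absent_slope)
  calls <- matrix(ifelse(stats::runif(p * n) < p_absent, "A", "P"), p, n)
  dimnames(signals) <- dimnames(calls) <-
    list(probe_id, clinical$patient_id)

  # every non-flagged probe gets a MIM number so the knowledge filter
  # passes the candidate set through unchanged by default
  mim <- vector("list", p)
  mim[candidates] <- as.list(sprintf("%06d", 100000L + candidates))
  annotation <- as_annotation(data.frame(
    probe_id = probe_id, is_control = is_control,
    is_cross_hyb = is_cross_hyb,
    gene_symbol = sprintf("SYNG%04d", seq_len(p)),
    accession = sprintf("NM_%06d", seq_len(p)),
    mim_numbers = "", stringsAsFactors = FALSE))
  annotation$mim_numbers <- lapply(mim, function(x) x %||% character())

  truth <- data.frame(probe_id = probe_id, effect_class = effect_class,
                      affected_subtype = affected_subtype,
                      true_log_hr = true_log_hr, stringsAsFactors = FALSE)
  list(expr = expr_mat(signals, calls), annotation = annotation,
       truth = truth)
}

#' Generate a full synthetic dataset (cohort + expression)
#' @param cfg A [sim_config].
#' @return List with `clinical`, `latent`, `expr`, `annotation`,
#'   `truth`, and `knowledge` (map derived from the annotation).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  cohort <- generate_cohort(cfg)
  ex <- generate_expression(cohort, cfg)
  c(cohort, ex, list(knowledge = knowledge_map_from_annotation(ex$annotation)))
}
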