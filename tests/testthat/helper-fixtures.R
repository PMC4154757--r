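# small in-code fixtures shared across test files

# a tiny expression matrix with known values
toy_expr <- function(values = matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE),
                     calls = NULL,
                     probes = paste0("p", seq_len(nrow(values))),
                     samples = paste0("s", seq_len(ncol(values)))) {
  dimnames(values) <- list(probes, samples)
  if (!is.null(calls)) dimnames(calls) <- list(probes, samples)
  expr_mat(values, calls)
}

# minimal valid clinical table for n patients
toy_clinical <- function(n = 6,
                         subtype = rep_len(c("UPS", "MFS", "MLS", "SS"), n),
                         time = seq_len(n) * 5,
                         event = rep_len(c(TRUE, FALSE), n),
                         grade = rep_len(1:3, n),
                         metastasis = rep_len(c(FALSE, TRUE), n)) {
  as_clinical(data.frame(
    patient_id = paste0("s", seq_len(n)), subtype = subtype,
    gender = rep_len(c("male", "female"), n), age = 50 + seq_len(n),
    grade = grade, metastasis = metastasis, survival_time = time,
    death_event = event, stringsAsFactors = FALSE))
}

# published 29-probe reference tables shipped with the package
ref_screening <- function() {
  path <- system.file("extdata", "sts29_screening.tsv",
                      package = "sarcoscreen")
  read.delim(path, stringsAsFactors = FALSE)
}

ref_pairwise <- function() {
  path <- system.file("extdata", "sts29_pairwise.tsv",
                      package = "sarcoscreen")
  read.delim(path, stringsAsFactors = FALSE)
}

# random survival dataset for property tests
random_surv <- function(n, event_prob = 0.7, tie_prob = 0.3) {
  t <- round(rexp(n, 0.05), ifelse(runif(n) < tie_prob, 0, 2))
  t <- pmax(t, 0.5)
  surv_data(t, runif(n) < event_prob)
}
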