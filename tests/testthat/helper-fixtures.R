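# Shared fixture builders.  All fixtures are generated in code.

# subject table from plain vectors (bypasses the simulator)
make_subjects <- function(event_month, last_observed_month,
                          weight = rep(1, length(event_month)),
                          cluster_id = rep(1L, length(event_month)),
                          static_score = rep(0, length(event_month)),
                          scores = NULL) {
  n <- length(event_month)
  out <- data.frame(
    subject_id = seq_len(n),
    cluster_id = cluster_id,
    weight = weight,
    latent_risk = rep(NA_real_, n),
    static_score = static_score,
    event_month = event_month,
    last_observed_month = last_observed_month,
    censor_reason = ifelse(is.na(event_month), "admin_cutoff", "event"),
    stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  if (!is.null(scores)) attr(out, "scores") <- scores
  out
}

# person-month array from plain vectors
make_array <- function(subject_id, month, score_A, score_S, event,
                       weight = rep(1, length(month)),
                       cluster_id = subject_id) {
  out <- data.frame(subject_id = subject_id, month = month,
                    score_A = score_A, score_S = score_S, event = event,
                    weight = weight, cluster_id = cluster_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("person_month", "data.frame")
  out
}

# standard moderate-sized test configuration (~45 clusters, ~400 events)
test_cfg <- function(seed, n_subjects = 2000, beta_A = 0.5, beta_S = 0.4,
                     beta_S_decay = 0, alpha_base = -4.8, weight_sd = 0.3,
                     ...) {
  sim_config(n_subjects = n_subjects, cluster_size_range = c(40, 60),
             weight_sd = weight_sd, lambda_S = 0.6, lambda_A_start = 0.5,
             lambda_A_end = 0.3, ar_phi = 0.6, alpha_base = alpha_base,
             training_offset = -1.5, training_months = 4,
             beta_A = beta_A, beta_S = beta_S,
             beta_S_decay = beta_S_decay, attrition_monthly = 0.011,
             seed = seed, ...)
}

# simulate and expand to a standardized person-month array
sim_array <- function(cfg) {
  standardize_scores(expand_person_months(simulate_study(cfg)))
}

# dense small event-rich fixture for likelihood/variance oracles; longer
# cutoffs (spanning the 13-24 / 25+ interaction bins) suit interaction specs
oracle_fixture <- function(seed, n_subjects = 60, n_clusters = 10,
                           cutoff = c(8, 12), alpha_base = -2.2) {
  cfg <- sim_config(n_subjects = n_subjects,
                    cluster_size_range = c(ceiling(n_subjects / n_clusters),
                                           ceiling(n_subjects / n_clusters)),
                    n_clusters = n_clusters, weight_sd = 0.4,
                    lambda_S = 0.6, lambda_A_start = 0.5,
                    lambda_A_end = 0.3, alpha_base = alpha_base,
                    training_offset = 0, training_months = 0,
                    beta_A = 0.5, beta_S = 0.5,
                    attrition_monthly = 0.02,
                    admin_cutoff_range = cutoff, seed = seed)
  sim_array(cfg)
}
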