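# Shared fixtures: small synthetic cohorts and toy matrices, all built in
# code at test time.

# Cohort with no class-dependent structure at all (null hypothesis).
null_design <- function(seed, n_a = 15, n_b = 15) {
  cohort_design(n_np = n_a, n_nc = 0, n_c = n_b,
                effect_sizes = c(choline = 1),
                mannitol_in_pain = FALSE, seed = seed)
}

# Cohort where only choline separates NP from C, at the given fold.
choline_design <- function(seed, fold = 2, n_a = 25, n_b = 25) {
  cohort_design(n_np = n_a, n_nc = 0, n_c = n_b,
                effect_sizes = c(choline = fold),
                mannitol_in_pain = FALSE, seed = seed)
}

binned_null <- function(seed, n_a = 15, n_b = 15) {
  bin_cohort(generate_cohort(null_design(seed, n_a, n_b)))
}

binned_choline <- function(seed, fold = 2, n_a = 25, n_b = 25) {
  bin_cohort(generate_cohort(choline_design(seed, fold, n_a, n_b)))
}

np_vs_c_xy <- function(m) {
  lab <- as.character(m$labels)
  keep <- lab %in% c("NP", "C")
  list(X = m$values[keep, , drop = FALSE],
       coding = class_coding(lab[keep], "NP", "C"))
}

# Fixed 4-sample, 2-variable toy with one clearly class-separating variable.
toy_xy <- function() {
  X <- rbind(c(1, 0.1), c(1.2, -0.1), c(-1, 0.05), c(-1.1, -0.05))
  coding <- class_coding(c("A", "A", "B", "B"), "A", "B")
  list(X = X, coding = coding)
}

random_contingency <- function() {
  structure(list(TP = sample(0:12, 1), FP = sample(0:12, 1),
                 TN = sample(0:12, 1), FN = sample(0:12, 1),
                 borderline_affected = 0L, borderline_unaffected = 0L,
                 n = NA, gold_standard = "simulated", conservative = TRUE),
            class = "contingency_table")
}
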