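# Independent oracles and small fixture builders shared across tests.

# Brute-force maximiser of the stratified Breslow partial likelihood with
# delayed entry, on a beta grid. Deliberately independent of any Cox
# fitting code: risk sets and tied-event terms are enumerated directly.
coxGridOracle <- function(entry, exit, event, x, stratum = rep(1, length(x)),
                          grid = seq(-3, 3, by = 1e-4)) {
  loglik <- numeric(length(grid))
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    for (t in sort(unique(exit[i][event[i] == 1]))) {
      tied <- i[event[i] == 1 & exit[i] == t]
      risk <- i[entry[i] < t & exit[i] >= t]
      loglik <- loglik + sum(x[tied]) * grid -
        length(tied) * log(colSums(exp(outer(x[risk], grid))))
    }
  }
  grid[which.max(loglik)]
}

# A deterministic 6-patient delayed-entry toy with distinct event times.
toyCohort <- function() {
  d <- data.frame(
    patient_id = paste0("p", 1:6),
    entry = c(0, 0.5, 0, 1.0, 0.2, 0),
    exit = c(2.0, 3.0, 4.5, 5.0, 6.0, 7.0),
    event = c(1, 1, 0, 1, 1, 0),
    stratum = "c1", study = "s1", er_status = "positive",
    stringsAsFactors = FALSE
  )
  list(cohort = SurvivalCohort(d), dosage = c(0, 1, 2, 0, 2, 1))
}

# Hand-rolled mean/SD Monte Carlo standard error for a proportion.
mcSe <- function(p, n) sqrt(p * (1 - p) / n)

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
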