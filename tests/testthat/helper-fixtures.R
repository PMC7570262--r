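# Fixture builders and independent oracles shared across the test files.

# A single valid packet row with overridable fields.
packetRow <- function(packet_id = "p001", species = "E. mohavense",
                      cohort = "2015", site = "site_1", plot = "plot_01",
                      microhabitat = "control", burial_seasons = 1L,
                      collection_year = "2017", seeds_sown = 18L,
                      n_expended = 6L, n_retained = 12L, n_assayed = 6L,
                      n_stained = 3L) {
  data.frame(packet_id = packet_id, species = species, cohort = cohort,
             site = site, plot = plot, microhabitat = microhabitat,
             burial_seasons = burial_seasons,
             collection_year = collection_year, seeds_sown = seeds_sown,
             n_expended = n_expended, n_retained = n_retained,
             n_assayed = n_assayed, n_stained = n_stained,
             stringsAsFactors = FALSE)
}

# Brute-force Mann-Whitney oracle: enumerate every assignment of the pooled
# observed values to the two samples and count assignments whose U is at
# least as far from the null mean as the observed one. Independent of the
# package's dynamic-programming exact path.
bruteForceMWU <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  ustat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- ustat(seq_len(na))
  mu <- na * nb / 2
  splits <- combn(na + nb, na)
  us <- apply(splits, 2, ustat)
  list(W = obs,
       p = mean(abs(us - mu) >= abs(obs - mu) - 1e-9))
}

# Random valid pool-summary rows in the summarizePools() layout, for
# conservation property tests.
randomPoolSummary <- function(n, seed) {
  set.seed(seed)
  n_total <- sample(5:200, n, replace = TRUE)
  n_expended <- rbinom(n, n_total, runif(n))
  n_retained <- rbinom(n, n_total - n_expended, runif(n, 0.5, 1))
  n_assayed <- rbinom(n, n_retained, runif(n, 0, 1))
  n_stained <- rbinom(n, n_assayed, runif(n))
  out <- data.frame(
    group = sprintf("g%04d", seq_len(n)),
    n_total = n_total, n_expended = n_expended, n_retained = n_retained,
    n_unrecovered = n_total - n_expended - n_retained,
    n_assayed = n_assayed, n_stained = n_stained,
    n_unstained = n_assayed - n_stained,
    prop_expended = n_expended / n_total,
    prop_retained = n_retained / n_total,
    prop_unrecovered = (n_total - n_expended - n_retained) / n_total,
    staining_rate = ifelse(n_assayed > 0, n_stained / n_assayed, NA_real_),
    stringsAsFactors = FALSE)
  out
}

# A small two-stratum scenario for fast simulator tests.
smallScenario <- function(p_expend1 = 0.3, p_die1 = 0.2,
                          p_expend2 = 0.4, p_die2 = 0.1,
                          n_packets = 12L, seeds_per_packet = 10L,
                          assay_fraction = 1, rng_seed = 1L, ...) {
  design <- data.frame(species = "sp", cohort = "c1",
                       n_packets = n_packets,
                       seeds_per_packet = seeds_per_packet,
                       stringsAsFactors = FALSE)
  hz <- expand.grid(microhabitat = c("control", "runoff", "shade"),
                    season = 1:2, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  hz$species <- "sp"; hz$cohort <- "c1"
  hz$p_expend <- ifelse(hz$season == 1, p_expend1, p_expend2)
  hz$p_die <- ifelse(hz$season == 1, p_die1, p_die2)
  FateScenario(design, hz, assay_fraction = assay_fraction,
               rng_seed = rng_seed, ...)
}
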