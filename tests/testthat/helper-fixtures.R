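# Shared fixture builders: everything is generated in code at test time.

# Replicate panel with exact target mean and RSD: a fixed symmetric base
# vector with unit sample SD is scaled to the requested dispersion.
make_replicates <- function(mean, rsd_percent, n = 7) {
  base <- seq_len(n) - (n + 1) / 2
  base <- base / stats::sd(base)
  mean + (rsd_percent / 100 * mean) * base
}

# Tilapia-style QC panel: target RSDs mirror the replicate trial (bile
# acids 9%, creatine kinase 6%, potassium 4%, the rest at or below 3%).
qc_panel_targets <- function() {
  c(AST = 3, BA = 9, CK = 6, GLU = 2, PHOS = 2, Ca = 1.5,
    TP = 2, ALB = 2.5, GLOB = 3, K = 4, Na = 1)
}

make_qc_panel <- function() {
  targets <- qc_panel_targets()
  means <- c(AST = 80, BA = 90, CK = 1800, GLU = 40, PHOS = 7,
             Ca = 14.5, TP = 3.6, ALB = 2.0, GLOB = 1.6, K = 4.2,
             Na = 168)
  do.call(rbind, lapply(names(targets), function(a)
    data.frame(analyte = a, value = make_replicates(means[[a]],
                                                    targets[[a]]))))
}

# Two separable Gaussian blobs (the linearly separable training toy).
make_blobs <- function(n_per = 20, shift = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n_per, 0), n_per, 2),
             matrix(stats::rnorm(2 * n_per, shift), n_per, 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(0, 1), each = n_per))
}

# Small deterministic cohort for structural tests.
make_mini_cohort <- function(seed = 42) {
  inject_study_artifacts(
    generate_cohort(default_generator_config(), seed = seed), seed = seed)
}

# Brute-force AUC oracle: concordant-pair counting with ties at half.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# Exhaustive two-sided Mann-Whitney p-value for tiny samples: enumerate
# every assignment of the pooled values to the two groups.
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(xa, xb) {
    sum(vapply(xa, function(v) sum(v > xb) + 0.5 * sum(v == xb),
               numeric(1)))
  }
  obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combs <- utils::combn(seq_along(pooled), na)
  us <- apply(combs, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
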