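# Brute-force reference computations, kept deliberately naive and independent
# of the package's implementations.

# Bray-Curtis by explicit double loop over sample pairs.
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- 1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ]))
    }
  }
  d
}

# eta squared by direct group-mean arithmetic.
oracle_eta2 <- function(values, groups) {
  groups <- as.character(groups)
  mu <- mean(values)
  sst <- sum((values - mu)^2)
  if (sst == 0) {
    return(0)
  }
  ssb <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    ssb <- ssb + sum(idx) * (mean(values[idx]) - mu)^2
  }
  ssb / sst
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of which
# observations belong to the first group (no ties assumed).
oracle_wilcox_exact_p <- function(a, b) {
  x <- c(a, b)
  stopifnot(!anyDuplicated(x))
  na <- length(a)
  r <- rank(x)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  subsets <- utils::combn(length(x), na)
  u_all <- apply(subsets, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# AUC by explicit counting over positive-negative pairs.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Area under an empirical ROC curve by the trapezoidal rule.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Small deterministic feature table used across IO / transform tests.
toy_table <- function() {
  m <- matrix(
    c(
      3, 0, 5,
      1, 2, 0,
      4, 4, 4
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("t1", "t2", "t3"))
  )
  feature_table(m, c(
    "k__Bacteria;p__Proteobacteria;c__;o__;f__;g__Halomonas",
    "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Clostridium_XlVa",
    "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__Bacteroides"
  ))
}

# One modest synthetic run shared by several test files (planted signal,
# mild batch, all four groups) to avoid regenerating repeatedly.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohorts(synthetic_spec(
        n_cohorts = 3,
        samples_per_cohort_per_group = c(
          normal = 12, benign = 6, cancer = 12, cancer_adjacent = 6
        ),
        n_taxa = 80, n_planted = 8, disease_log2fc = 2,
        batch_sd = 0.3, seed = 424242
      ))
    }
    cache
  }
})

shared_clr <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_sim()
      genus <- aggregate_to_genus(drop_unmapped_samples(filter_taxa(sim$table)))
      cache <<- list(genus = genus, clr = clr_transform(genus), meta = sim$metadata,
        truth = sim$truth)
    }
    cache
  }
})
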