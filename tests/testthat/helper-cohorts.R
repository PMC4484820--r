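# Deterministic planted cohorts built in code (no fixtures on disk).

# Depth-2 separable cohort: feature f1 >= t1 is a pure-remitter leaf;
# within f1 < t1, f2 >= t2 is a pure-remitter leaf and f2 < t2 pure
# non-remitter.  Both thresholds are observed values (the smallest value
# on each ">=" side) and the below-threshold ranks of each feature
# interleave the two outcome classes, so the planted cut is the unique
# kappa maximizer and exact recovery of (feature, threshold, direction)
# is well defined.  Noise features are label-independent uniforms.
make_separable_cohort <- function(n1 = 60, n2 = 20, n3 = 20,
                                  t1 = 14.82, t2 = 6.25,
                                  n_noise = 8, seed = 99) {
  n <- n1 + n2 + n3
  leaf <- rep(c(1L, 2L, 3L), c(n1, n2, n3))
  f1 <- f2 <- numeric(n)
  # leaf 1: f1 on and above its threshold
  f1[leaf == 1L] <- t1 + 0.01 * (seq_len(n1) - 1L)
  # below t1, alternate leaf-2 (non-remitter) and leaf-3 (remitter)
  # ranks so every interior f1 cut splits the classes evenly; the value
  # adjacent to the cut is a non-remitter, so no interior cut can beat
  # the planted one
  lo <- c(which(leaf == 2L), which(leaf == 3L))
  lo <- lo[order(rep(seq_len(max(n2, n3)), 2)[seq_along(lo)])]
  f1[lo] <- t1 - 0.5 - 0.01 * seq_along(lo)
  # leaf 3: f2 on and above its threshold; leaf 2 below it
  f2[leaf == 3L] <- t2 + 0.01 * (seq_len(n3) - 1L)
  f2[leaf == 2L] <- t2 - 0.2 - 0.02 * seq_len(n2)
  # leaf 1 (unconstrained in f2): interleave half with the leaf-2 range
  # so no pure-class f2 prefix exists at the root
  i1 <- which(leaf == 1L)
  odd <- i1[seq_along(i1) %% 2 == 1L]
  even <- i1[seq_along(i1) %% 2 == 0L]
  f2[odd] <- t2 - 0.21 - 0.02 * seq_along(odd)
  f2[even] <- t2 + 0.5 + 0.01 * seq_along(even)
  d <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    remitted = leaf != 2L, # leaves 1 and 3 remit, leaf 2 does not
    f1 = f1, f2 = f2
  )
  withr::with_seed(seed, {
    for (j in seq_len(n_noise)) {
      d[[paste0("noise", j)]] <- runif(n, 5, 25)
    }
  })
  d
}

# Melancholia fixture emulating the characterization table: 6/57
# melancholics among selected non-remitters vs 12/46 among non-selected.
make_melancholia_fixture <- function() {
  tibble::tibble(
    group = rep(c("S-NR", "N-NR"), c(57, 46)),
    melancholic = c(rep(c(TRUE, FALSE), c(6, 51)),
                    rep(c(TRUE, FALSE), c(12, 34)))
  )
}

# Depth-2 recovery configuration: the volumetric tree's leaf remission
# rates scaled to a cohort of 150 for repeated-seed recovery runs.
recovery_config <- function(seed = NULL) {
  cohort_config(
    cohorts = list(
      test = cohort_spec(
        "test", n = 150L,
        planted = list(volumetric = planted_tree(
          tibble::tibble(
            feature = c("Frontal_Mid_L", "Angular_R"),
            threshold = c(14.82, 6.25),
            leaf_side = c("ge", "lt"),
            leaf_p = c(25 / 33, 7 / 14),
            leaf_n = c(65L, 28L)
          ),
          final_p = 3 / 29, final_n = 57L
        ))
      )
    ),
    feature_means = c(Frontal_Mid_L = 14.8, Angular_R = 6.3),
    feature_sds = c(Frontal_Mid_L = 2.2, Angular_R = 1.0),
    seed = seed
  )
}

# Candidate set for recovery runs: the two planted regions plus a
# modest number of noise regions.
recovery_features <- function() {
  unique(c("Frontal_Mid_L", "Angular_R", atlas_labels("aal116")[1:20]))[1:20]
}
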