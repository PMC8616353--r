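# Shared fixtures and independent oracles for the test suite.

# A small in-code glycan library exercising every trait.
tiny_library <- function() {
  recs <- list(
    glycan_record("H9N2", "N"),
    glycan_record("H5N2P1", "N"),
    glycan_record("H3N2F1", "N", core_fucose = 1),
    glycan_record("H4N3", "N", antennae = 1),
    glycan_record("H5N4S2a", "N", glycan_type = "complex", antennae = 2,
                  sia_a23 = 1, sia_a26_gal = 1),
    glycan_record("H5N5", "N", glycan_type = "complex", antennae = 2,
                  bisecting = TRUE),
    glycan_record("H5N4F2S2", "N", glycan_type = "complex", antennae = 2,
                  core_fucose = 1, antennary_fucose = 1, sia_a23 = 2,
                  has_sLex_a = TRUE),
    glycan_record("H7N6S4", "N", glycan_type = "complex", antennae = 4,
                  sia_a23 = 2, sia_unknown = 2),
    glycan_record("H1N1", "O", has_T_antigen = TRUE),
    glycan_record("H1N1S1a", "O", sia_a23 = 1),
    glycan_record("H1N1S2a", "O", sia_a23 = 1, sia_a26_core = 1),
    glycan_record("H2N2S2", "O", glycan_type = "core2", sia_a23 = 1,
                  sia_a26_core = 1),
    glycan_record("H2N2F1S1", "O", glycan_type = "core2",
                  antennary_fucose = 1, sia_a23 = 1, has_sLex_a = TRUE),
    glycan_record("H3N3S1", "O", glycan_type = "core2", sia_a23 = 1,
                  lacnac_repeats = 1),
    glycan_record("H2N2S3", "O", glycan_type = "core2", sia_a23 = 1,
                  sia_a26_core = 1, sia_a28 = 1)
  )
  names(recs) <- vapply(recs, `[[`, character(1), "name")
  recs
}

# Brute-force trait recomputation: explicit loops over samples, traits and
# glycans, independent of the matrix algebra in derive_traits().
brute_force_traits <- function(abundances, library, traits) {
  out <- matrix(NA_real_, nrow(abundances), length(traits),
                dimnames = list(rownames(abundances),
                                vapply(traits, `[[`, character(1),
                                       "trait_name")))
  for (i in seq_len(nrow(abundances))) {
    for (td in traits) {
      num <- 0; den <- 0
      for (g in colnames(abundances)) {
        rec <- library[[g]]
        a <- abundances[i, g]
        if (is.na(a)) a <- 0
        if (rec$glycan_class != td$glycan_class) next
        carrier <- isTRUE(td$predicate(rec))
        w <- if (carrier) {
          if (td$weight == "count") td$count_fn(rec) else 1
        } else 0
        num <- num + a * w
        in_den <- if (td$output == "ratio") {
          isTRUE(td$ratio_predicate(rec))
        } else {
          switch(td$denominator,
                 total_class = TRUE,
                 complex_only = rec$glycan_type == "complex",
                 complex_hybrid = rec$glycan_type %in% c("complex", "hybrid"))
        }
        if (in_den) den <- den + a
      }
      val <- if (den > 0) {
        if (td$output == "ratio") num / den else num / den * 100
      } else NA_real_
      out[i, td$trait_name] <- val
    }
  }
  out
}

# Random fractional-abundance cohort over a subset of library glycans,
# closed to 100% within each glycan class.
random_cohort <- function(library, n_samples = 4, seed = 1) {
  set.seed(seed)
  glycans <- names(library)
  cls <- vapply(library, `[[`, character(1), "glycan_class")
  keep_n <- sample(which(cls == "N"), max(3, rbinom(1, sum(cls == "N"), 0.8)))
  keep_o <- sample(which(cls == "O"), max(2, rbinom(1, sum(cls == "O"), 0.8)))
  keep <- sort(c(keep_n, keep_o))
  m <- matrix(0, n_samples, length(keep),
              dimnames = list(paste0("s", seq_len(n_samples)),
                              glycans[keep]))
  kcls <- cls[keep]
  for (i in seq_len(n_samples)) for (k in unique(kcls)) {
    cols <- which(kcls == k)
    x <- stats::rgamma(length(cols), shape = 1)
    m[i, cols] <- x / sum(x) * 100
  }
  m
}

# Independent Hotelling T2: scores x inverse score covariance.
t2_oracle <- function(scores) {
  S <- stats::cov(scores)
  Sinv <- solve(S)
  vapply(seq_len(nrow(scores)), function(i) {
    drop(t(scores[i, ]) %*% Sinv %*% scores[i, ])
  }, numeric(1))
}

# Classical CCA correlations via the QR-based routine in stats::cancor.
cancor_oracle <- function(X, Y) {
  stats::cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))$cor
}

demo_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config(seed = 20))
    cache
  }
})

big_classes <- c(M2 = 33, M3 = 33, M4 = 34, M5 = 34, M6 = 33, M7 = 33)
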