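make_records <- function(idotp, snr, rt = TRUE, glycan = NULL) {
  n <- max(length(idotp), length(snr), length(rt))
  data.frame(sample = "s1", replicate = "r1",
             glycan = if (is.null(glycan)) paste0("g", seq_len(n)) else glycan,
             area = 100, rt_match = rt, idotp = idotp, snr = snr,
             stringsAsFactors = FALSE)
}

test_that("QC thresholds are inclusive at the stated boundaries", {
  at <- make_records(idotp = 0.85, snr = 6)
  expect_equal(nrow(qc_filter(at)$kept), 1)

  below_idotp <- make_records(idotp = 0.84, snr = 50)
  res <- qc_filter(below_idotp)
  expect_equal(nrow(res$kept), 0)
  expect_identical(res$rejected$reason, "idotp")

  below_snr <- make_records(idotp = 0.99, snr = 5.999)
  expect_identical(qc_filter(below_snr)$rejected$reason, "snr")

  no_rt <- make_records(idotp = 0.99, snr = 50, rt = FALSE)
  expect_identical(qc_filter(no_rt)$rejected$reason, "rt")
  expect_equal(nrow(qc_filter(no_rt, require_rt = FALSE)$kept), 1)
})

test_that("QC filtering keeps exactly the passing subset and is idempotent", {
  set.seed(5)
  rec <- make_records(idotp = c(runif(7, 0.9, 1), 0.5, 0.7, 0.84),
                      snr = c(runif(9, 10, 100), 50))
  res <- qc_filter(rec)
  expect_equal(nrow(res$kept), 7)
  expect_equal(nrow(res$rejected), 3)
  again <- qc_filter(res$kept)
  expect_identical(again$kept, res$kept)
  expect_equal(nrow(again$rejected), 0)
})

test_that("total-area normalization yields within-class percentages", {
  lib <- tiny_library()
  rec <- rbind(make_records(idotp = 1, snr = 99,
                            glycan = c("H9N2", "H4N3", "H5N5")),
               make_records(idotp = 1, snr = 99,
                            glycan = c("H1N1", "H1N1S1a")))
  rec$area <- c(2, 3, 5, 40, 60)
  m <- areas_from_records(rec, lib)
  f <- to_fractional(m)
  expect_equal(unname(f["s1", c("H9N2", "H4N3", "H5N5")]), c(20, 30, 50))
  expect_equal(unname(f["s1", c("H1N1", "H1N1S1a")]), c(40, 60))

  # single-glycan class normalizes to 100
  one <- make_records(idotp = 1, snr = 99, glycan = "H9N2")
  expect_equal(unname(to_fractional(areas_from_records(one, lib))[1, 1]), 100)
})

test_that("normalization is invariant to per-sample area rescaling", {
  lib <- tiny_library()
  rec <- make_records(idotp = 1, snr = 99,
                      glycan = c("H9N2", "H4N3", "H5N5"))
  rec$area <- c(7, 11, 13)
  rec2 <- rec; rec2$area <- rec$area * 1e4
  f1 <- to_fractional(areas_from_records(rec, lib))
  f2 <- to_fractional(areas_from_records(rec2, lib))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("an all-zero sample-class fails normalization by name", {
  lib <- tiny_library()
  rec <- make_records(idotp = 1, snr = 99, glycan = c("H9N2", "H1N1"))
  rec$area <- c(0, 10)
  expect_error(to_fractional(areas_from_records(rec, lib)), "s1")
})

test_that("imputation touches only missing cells and flags them", {
  m <- matrix(c(1, NA, 3, NA, 5, 0.123456789), 2, 3,
              dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  out <- impute_missing(m)
  expect_equal(out["b", "g1"], 0.01)
  expect_equal(out["b", "g2"], 0.01)
  expect_identical(out["a", "g2"], m["a", "g2"])
  expect_identical(out["b", "g3"], m["b", "g3"])  # bit-for-bit
  expect_equal(sum(attr(out, "imputed")), 2)

  complete <- matrix(1:4, 2)
  out2 <- impute_missing(complete)
  expect_equal(unclass(out2), unclass(complete), ignore_attr = TRUE)
  expect_equal(sum(attr(out2, "imputed")), 0)
})

test_that("replicate RSD matches the textbook sd/mean computation", {
  m <- matrix(c(10, 10, 10, 9, 10, 11, 0.4, 0.5, 0.6), 3, 3,
              dimnames = list(paste0("r", 1:3), c("g1", "g2", "g3")))
  res <- replicate_rsd(m)
  expect_equal(res$per_glycan$rsd[1], 0)
  expect_equal(res$per_glycan$rsd[2], 1 / 10 * 100)   # sd(9,10,11) = 1
  # g3 mean 0.5 < 1.0 is excluded from the average
  expect_false(res$per_glycan$included[3])
  expect_equal(res$average_rsd, mean(c(0, 10)))
  expect_error(replicate_rsd(m[1, , drop = FALSE]), "2 replicates")
})

test_that("z-transformation standardizes every non-constant feature", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(NULL, c("v", "const")))
  expect_warning(z <- zscore_features(m), "constant")
  expect_equal(unname(z[, "v"]), c(-1, 0, 1))
  expect_equal(unname(z[, "const"]), c(0, 0, 0))

  set.seed(8)
  r <- matrix(rnorm(200), 20, 10)
  colnames(r) <- paste0("f", 1:10)
  z <- zscore_features(r)
  expect_equal(colMeans(z), rep(0, 10), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(1, 10), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("filter-then-normalize equals normalizing the kept subset", {
  lib <- tiny_library()
  rec <- make_records(idotp = c(1, 0.5, 1), snr = 99,
                      glycan = c("H9N2", "H4N3", "H5N5"))
  rec$area <- c(5, 4, 5)
  kept <- qc_filter(rec)$kept
  f1 <- to_fractional(areas_from_records(kept, lib))
  f2 <- to_fractional(areas_from_records(rec[c(1, 3), ], lib))
  expect_equal(f1, f2)
})

test_that("replicate rows collapse to per-sample means", {
  lib <- tiny_library()
  rec <- rbind(make_records(idotp = 1, snr = 9, glycan = c("H9N2", "H5N5")),
               make_records(idotp = 1, snr = 9, glycan = c("H9N2", "H5N5")))
  rec$replicate <- rep(c("r1", "r2"), each = 2)
  rec$area <- c(60, 40, 80, 20)
  m <- areas_from_records(rec, lib)
  expect_identical(rownames(m), c("s1.r1", "s1.r2"))
  f <- collapse_replicates(to_fractional(m))
  expect_identical(rownames(f), "s1")
  expect_equal(unname(f[1, ]), c(70, 30))
})
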