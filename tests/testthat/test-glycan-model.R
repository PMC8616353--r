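test_that("composition names parse into counts and isomer letters", {
  p <- parse_glycan_name("H5N4S2a")
  expect_equal(as.integer(p$composition),
               c(5L, 4L, 0L, 2L, 0L, 0L), ignore_attr = TRUE)
  expect_identical(p$isomer, "a")

  p <- parse_glycan_name("H9N2")
  expect_equal(p$composition[["hex"]], 9L)
  expect_equal(p$composition[["hexnac"]], 2L)
  expect_true(is.na(p$isomer))

  p <- parse_glycan_name("H1N1S2")
  expect_equal(as.integer(p$composition),
               c(1L, 1L, 0L, 2L, 0L, 0L), ignore_attr = TRUE)

  # Su must win over S, and token order is free
  p <- parse_glycan_name("Su1S2N2H2")
  expect_equal(p$composition[["sulfo"]], 1L)
  expect_equal(p$composition[["neuac"]], 2L)
})

test_that("malformed names are rejected with the offending token named", {
  expect_error(parse_glycan_name("X5N2"), "unknown token 'X5'")
  expect_error(parse_glycan_name("H5N4H3"), "duplicated token 'H'")
  expect_error(parse_glycan_name("H0N2"), "non-positive count")
  expect_error(parse_glycan_name("H5N4ab"), "unknown token")
  expect_error(parse_glycan_name(""), "non-empty")
  expect_error(parse_glycan_name("a"), "no composition tokens")
})

test_that("formatting then parsing is the identity on canonical names", {
  set.seed(7)
  for (i in 1:200) {
    comp <- glycan_composition(hex = sample(0:9, 1), hexnac = sample(1:7, 1),
                               fuc = sample(0:3, 1), neuac = sample(0:4, 1),
                               phospho = sample(0:2, 1),
                               sulfo = sample(0:2, 1))
    iso <- if (runif(1) < 0.5) sample(letters[1:4], 1) else NA_character_
    nm <- format_glycan_name(comp, iso)
    p <- parse_glycan_name(nm)
    expect_identical(format_glycan_name(p$composition, p$isomer), nm)
    expect_equal(as.integer(p$composition), as.integer(comp),
                 ignore_attr = TRUE)
  }
})

test_that("alditol masses match independently summed reference values", {
  # frozen from an independent sum over standard monoisotopic residue masses
  expect_equal(alditol_mass(glycan_composition()), 20.026215,
               tolerance = 1e-6)
  expect_equal(alditol_mass(glycan_composition(hex = 1, hexnac = 1,
                                               neuac = 1)),
               676.253827, tolerance = 1e-6)
  expect_equal(alditol_mass(glycan_composition(hex = 9, hexnac = 2)),
               1884.660371, tolerance = 1e-6)
})

test_that("alditol mass is additive over compositions", {
  set.seed(11)
  term <- alditol_mass(glycan_composition())
  for (i in 1:50) {
    a <- glycan_composition(sample(0:5, 1), sample(0:5, 1), sample(0:2, 1),
                            sample(0:3, 1), sample(0:1, 1), sample(0:1, 1))
    b <- glycan_composition(sample(0:5, 1), sample(0:5, 1), sample(0:2, 1),
                            sample(0:3, 1), sample(0:1, 1), sample(0:1, 1))
    ab <- do.call(glycan_composition,
                  as.list(as.integer(a) + as.integer(b)))
    expect_equal(alditol_mass(ab) - term,
                 (alditol_mass(a) - term) + (alditol_mass(b) - term),
                 tolerance = 1e-9)
  }
})

test_that("composition-based classification reproduces the type rules", {
  cls <- function(h, n, f = 0, s = 0, class = "N")
    classify_by_composition(glycan_composition(h, n, f, s), class)
  expect_identical(cls(9, 2), "oligomannose")
  expect_identical(cls(3, 2, f = 1), "paucimannose")
  expect_identical(cls(4, 2), "oligomannose")  # Man4 boundary convention
  expect_identical(cls(3, 2), "paucimannose")
  expect_identical(cls(5, 3, s = 1), "hybrid")
  expect_identical(cls(3, 3), "complex")       # HexNAc 3, hex < 4
  expect_identical(cls(5, 4, s = 2), "complex")
  expect_identical(cls(1, 1, s = 1, class = "O"), "core1")
  expect_identical(cls(2, 2, s = 2, class = "O"), "core2")
})

test_that("classification is total and single-valued over the composition grid", {
  n_types <- c("oligomannose", "paucimannose", "hybrid", "complex")
  for (hexnac in 1:8) for (hex in 0:12) for (fuc in 0:2) for (neuac in 0:2) {
    comp <- glycan_composition(hex, hexnac, fuc, neuac)
    if (hexnac >= 2) {
      t_n <- classify_by_composition(comp, "N")
      expect_length(t_n, 1)
      expect_true(t_n %in% n_types)
    }
    t_o <- classify_by_composition(comp, "O")
    expect_true(t_o %in% c("core1", "core2"))
  }
})

test_that("annotation validation reports all inconsistencies", {
  ok <- glycan_record("H5N4S2", "N", glycan_type = "complex", antennae = 2,
                      sia_a23 = 1, sia_a26_gal = 1)
  expect_length(validate_annotation(ok), 0)

  bad_sia <- glycan_record("H5N4S2", "N", glycan_type = "complex",
                           antennae = 2, sia_a23 = 1)
  v <- validate_annotation(bad_sia)
  expect_length(v, 1)
  expect_match(v, "sialic linkage")

  bad_o <- glycan_record("H1N1S1", "O", sia_a23 = 1, bisecting = TRUE)
  expect_match(validate_annotation(bad_o), "bisected", all = FALSE)

  # several violations at once are all returned
  multi <- glycan_record("H2N2F1S1", "O", glycan_type = "core2",
                         bisecting = TRUE, has_sLex_a = TRUE)
  v <- validate_annotation(multi)
  expect_gte(length(v), 3)  # sia sum, fuc sum, bisection, sLex support

  # curated type differing from a decisive composition is warning-level
  weird <- glycan_record("H1N1", "O", glycan_type = "core2",
                         has_T_antigen = FALSE)
  v <- validate_annotation(weird)
  expect_match(v, "^warning:", all = FALSE)
})

test_that("the packaged library is complete and internally consistent", {
  lib <- builtin_glycan_library()
  cls <- vapply(lib, `[[`, character(1), "glycan_class")
  expect_gte(sum(cls == "N"), 30)
  expect_gte(sum(cls == "O"), 15)
  types <- vapply(lib, `[[`, character(1), "glycan_type")
  expect_setequal(unique(types[cls == "N"]),
                  c("oligomannose", "paucimannose", "hybrid", "complex"))
  expect_setequal(unique(types[cls == "O"]), c("core1", "core2"))
  for (rec in lib) {
    v <- validate_annotation(rec)
    expect_length(v[!startsWith(v, "warning:")], 0)
  }
  # isomer letters unique within a (composition, class) group
  key <- vapply(lib, function(r)
    paste(r$glycan_class, format_glycan_name(r$composition)), character(1))
  iso <- vapply(lib, function(r) ifelse(is.na(r$isomer), "", r$isomer),
                character(1))
  expect_false(any(duplicated(paste(key, iso))))
})

test_that("annotation tables round-trip through write and read", {
  lib <- tiny_library()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(lib, path)
  back <- read_annotation_table(path)
  expect_identical(names(back), names(lib))
  for (nm in names(lib)) {
    expect_identical(library_as_data_frame(back[nm]),
                     library_as_data_frame(lib[nm]))
  }
  suppressWarnings(
    expect_error(read_annotation_table(withr::local_tempfile(fileext = ".x")),
                 "cannot open|No such file"))
})
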