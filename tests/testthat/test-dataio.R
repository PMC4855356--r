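test_that("descriptor tables round-trip through CSV with schema checks", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,class,dft_nci,nve,ref_nci",
    "a,h_bonded,-12.1,20,-10.3",
    "b,Mixed,-4.0,30,-3.7",
    "c,dispersion,-5.5,44,-4.2"
  ), path)
  ds <- read_descriptor_table(path)
  expect_equal(n_records(ds), 3)
  expect_equal(ds$descriptor_names, c("dft_nci", "nve"))
  expect_equal(ds$records$id, c("a", "b", "c"))
  expect_equal(ds$records$class, c("h_bonded", "mixed", "dispersion"))
  expect_equal(unname(reference_nci(ds)), c(-10.3, -3.7, -4.2))

  # blank reference cell while the reference is required
  writeLines(c("id,class,dft_nci,ref_nci", "a,mixed,-4.0,-3.7",
               "b,mixed,-4.1,"), path)
  expect_error(read_descriptor_table(path), "row 2",
               class = "grnncorr_integrity_error")
  ds2 <- read_descriptor_table(path, ref_required = FALSE)
  expect_true(is.na(reference_nci(ds2)[["b"]]))

  # missing mandatory column is named in the error
  writeLines(c("id,class,nve", "a,mixed,20"), path)
  expect_error(read_descriptor_table(path), "dft_nci",
               class = "grnncorr_schema_error")

  # non-numeric descriptor cell reports row and column
  writeLines(c("id,class,dft_nci,ref_nci", "a,mixed,oops,-3.7"), path)
  expect_error(read_descriptor_table(path), "'dft_nci', row 1",
               class = "grnncorr_parse_error")

  # duplicate id
  writeLines(c("id,class,dft_nci,ref_nci", "a,mixed,-4.0,-3.7",
               "a,mixed,-4.1,-3.8"), path)
  expect_error(read_descriptor_table(path), "duplicate",
               class = "grnncorr_integrity_error")
})

test_that("generator export re-reads field-by-field identical", {
  bench <- generate_benchmark(synthetic_config(seed = 3))
  path <- tempfile(fileext = ".csv")
  export_fixture(bench$dataset, path)
  back <- read_descriptor_table(path)
  expect_equal(back$descriptor_names, bench$dataset$descriptor_names)
  expect_equal(back$records$id, bench$dataset$records$id)
  expect_equal(back$records$class, bench$dataset$records$class)
  expect_equal(descriptor_matrix(back), descriptor_matrix(bench$dataset),
               tolerance = 1e-12)
  expect_equal(reference_nci(back), reference_nci(bench$dataset),
               tolerance = 1e-12)
})

test_that("constitutional descriptors count atoms and valence electrons", {
  water <- write_xyz(c("3", "water", "O 0 0 0.12", "H 0 0.76 -0.47",
                       "H 0 -0.76 -0.47"))
  expect_equal(constitutional_descriptors(water),
               list(n_atoms = 3L, n_valence_electrons = 8L))

  methane <- write_xyz(c("5", "methane", "C 0 0 0", "H 1 1 1", "H -1 -1 1",
                         "H 1 -1 -1", "H -1 1 -1"))
  expect_equal(constitutional_descriptors(methane)$n_valence_electrons, 8L)

  # benzene dimer: 12 C + 12 H -> 24 atoms, 12*4 + 12*1 = 60 per... summed
  set.seed(1)
  atoms <- c(rep("C", 12), rep("H", 12))
  coords <- matrix(round(rnorm(72), 3), ncol = 3)
  dimer_lines <- c("24", "benzene dimer",
                   paste(atoms, coords[, 1], coords[, 2], coords[, 3]))
  dimer <- write_xyz(dimer_lines)
  expect_equal(constitutional_descriptors(dimer),
               list(n_atoms = 24L, n_valence_electrons = 60L))

  # permutation invariance in atom order
  shuffled <- write_xyz(c("24", "benzene dimer shuffled",
                          sample(dimer_lines[-(1:2)])))
  expect_equal(constitutional_descriptors(shuffled),
               constitutional_descriptors(dimer))

  # count-line mismatch and unknown element
  bad_n <- write_xyz(c("4", "broken", "O 0 0 0", "H 0 0 1"))
  expect_error(constitutional_descriptors(bad_n), "4 atoms",
               class = "grnncorr_format_error")
  bad_el <- write_xyz(c("1", "mystery", "Xq 0 0 0"))
  expect_error(constitutional_descriptors(bad_el), "Xq",
               class = "grnncorr_lookup_error")
})

test_that("halogen valence counts follow the main-group table", {
  hal <- write_xyz(c("4", "halogens", "F 0 0 0", "Cl 1 0 0", "Br 2 0 0",
                     "I 3 0 0"))
  expect_equal(constitutional_descriptors(hal)$n_valence_electrons, 28L)
})

test_that("[-1,1] normalization maps endpoints, flags constants, inverts", {
  df <- data.frame(id = c("a", "b", "c"), class = "unknown",
                   dft_nci = c(2, 4, 6), flat = c(5, 5, 5),
                   ref_nci = c(-1.5, -2.5, -4.5))
  ds <- nci_dataset(df, c("dft_nci", "flat"))
  map <- fit_normalization(ds, include_target = TRUE)
  expect_equal(map$constant_variables, "flat")
  nrm <- apply_normalization(map, ds)
  expect_equal(unname(descriptor_matrix(nrm, "dft_nci")[, 1]), c(-1, 0, 1))
  expect_equal(unname(descriptor_matrix(nrm, "flat")[, 1]), c(0, 0, 0))

  # values outside the fitted range map outside [-1, 1]; no clipping
  query <- nci_dataset(
    data.frame(id = "q", class = "unknown", dft_nci = 10, flat = 5),
    c("dft_nci", "flat"))
  expect_gt(descriptor_matrix(apply_normalization(map, query))[1, 1], 1)

  # apply-then-invert reproduces a random table to 1e-12
  ds_big <- random_dataset(10, p = 4, seed = 7)
  map_big <- fit_normalization(ds_big, include_target = TRUE)
  X <- descriptor_matrix(ds_big)
  Xn <- grnncorr:::norm_apply_matrix(map_big, X)
  expect_true(all(Xn >= -1 - 1e-12 & Xn <= 1 + 1e-12))
  expect_equal(grnncorr:::norm_invert_matrix(map_big, Xn), X,
               tolerance = 1e-12)

  set.seed(5)
  y <- rnorm(100)
  expect_equal(invert_target(map_big, grnncorr:::norm_target(map_big, y)),
               y, tolerance = 1e-12)
})

test_that("model serialization round-trips predictions bit-identically", {
  train <- random_dataset(15, p = 3, seed = 2)
  model <- grnn_fit(train, c("dft_nci", "x1", "x2"), sigma = 0.3)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$descriptor_names, model$descriptor_names)
  set.seed(9)
  q <- matrix(rnorm(60), ncol = 3,
              dimnames = list(NULL, c("dft_nci", "x1", "x2")))
  expect_identical(grnn_predict(back, q, denormalize = TRUE),
                   grnn_predict(model, q, denormalize = TRUE))

  # missing sigma and wrong version are compatibility errors
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sigma <- NULL
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path2), "sigma", class = "grnncorr_compat_error")

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$version <- 99
  jsonlite::write_json(obj, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path2), class = "grnncorr_compat_error")

  writeLines("{\"foo\": 1}", path2)
  expect_error(load_model(path2), class = "grnncorr_compat_error")
})
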