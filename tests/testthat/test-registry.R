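test_that("the bundled current registry enumerates the full taxonomy", {
  reg <- registry_2025()
  cc <- registry_counts(reg)
  expect_equal(cc$n_classes, 2L)
  expect_equal(cc$n_types, 7L)
  expect_equal(cc$n_subtypes, 46L)
  # partition identities, not just totals
  expect_equal(cc$per_type,
               c(I = 8L, II = 4L, III = 9L, IV = 3L, V = 15L, VI = 6L,
                 VII = 1L))
  expect_equal(sum(cc$per_type), cc$n_subtypes)
  expect_equal(unname(cc$per_class["1"]), 21L)
  expect_equal(sum(cc$per_class), cc$n_subtypes)
})

test_that("the previous registry version has six types and 33 subtypes", {
  cc <- registry_counts(load_registry("2020"))
  expect_equal(cc$n_types, 6L)
  expect_equal(cc$n_subtypes, 33L)
})

test_that("registry diff finds the thirteen new subtypes, antisymmetrically", {
  new <- registry_2025()
  old <- load_registry("2020")
  d <- diff_registries(new, old)
  expect_length(d$added, 13L)
  expect_length(d$removed, 0L)
  rev <- diff_registries(old, new)
  expect_equal(d$added, rev$removed)
  expect_equal(d$removed, rev$added)
  same <- diff_registries(new, new)
  expect_length(same$added, 0L)
  expect_length(same$removed, 0L)
})

test_that("sensor and ring-nuclease family nomenclature is complete", {
  fam <- registry_families(registry_2025())
  expect_equal(sum(grepl("^crf", fam$name) & fam$role == "sensor"), 11L)
  expect_equal(sum(grepl("^crn", fam$name) &
                     fam$role == "ring-nuclease"), 5L)
})

test_that("registries round-trip through their JSON serialization", {
  reg <- registry_2025()
  path <- withr::local_tempfile(fileext = ".json")
  save_registry(reg, path)
  expect_equal(load_registry(path), reg)
})

test_that("a minimal registry is constructible and countable", {
  fam <- tibble::tibble(name = c("cas1", "cas2", "cas9"),
                        role = c("adaptation", "adaptation",
                                 "signature-effector"),
                        legacy_names = list(character(0), character(0),
                                            "csn1"))
  reg <- new_registry("demo", fam,
                      list(subtype_def("II-A", 2, "II", "cas9")))
  cc <- registry_counts(reg)
  expect_equal(c(cc$n_classes, cc$n_types, cc$n_subtypes), c(1L, 1L, 1L))
})

test_that("invariant violations are reported as data, not errors", {
  fam <- tibble::tibble(name = "cas9", role = "signature-effector",
                        legacy_names = list(character(0)))
  broken <- structure(
    list(version = "demo", families = fam,
         subtypes = list(
           subtype_def("II-A", 2, "II", c("cas9", "ghost")),
           subtype_def("II-B", 2, "II", "cas9", forbidden = "cas9"),
           subtype_def("V-A", 2, "III", "cas9")
         ),
         legacy_subtype_map = character(0)),
    class = "cas_registry")
  v <- validate_registry(broken)
  expect_length(v, 3L)
  expect_match(v[1], "ghost")
  expect_match(v[2], "required and")
  expect_match(v[3], "inconsistent")
  expect_error(registry_counts(broken), "invalid")
})

test_that("malformed registry files are rejected with a parse error", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  expect_error(load_registry(empty), "parse|lacks")
  expect_error(load_registry(tempfile()), "not found")
})

test_that("core cas family recognition covers the lettered and fused names", {
  expect_true(all(is_core_family(c("cas1", "cas14", "cas8a", "cas10d",
                                   "cas12f", "cas9d", "cas7-11e",
                                   "cas7-11i"))))
  expect_false(any(is_core_family(c("csf1", "csn2", "csx26", "crf1",
                                    "crn3", "dinG", "corA", "pfam0001"))))
})
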