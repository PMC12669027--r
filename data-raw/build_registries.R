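# Builds the bundled classification registries (inst/extdata/registry_*.json).
# Subtype gene inventories are transcribed from the published subtype figures;
# run from the package root: Rscript data-raw/build_registries.R

fam <- function(name, role, legacy = character(0)) {
  list(name = name, role = role, legacy_names = as.list(legacy))
}

sub <- function(id, cas_class, cas_type, required_all,
                required_any = list(), forbidden = character(0),
                adaptation_optional = FALSE, array_optional = FALSE,
                variants = character(0), notes = "") {
  list(id = id, cas_class = cas_class, cas_type = cas_type,
       required_all = as.list(required_all),
       required_any = lapply(required_any, as.list),
       forbidden = as.list(forbidden),
       adaptation_optional = adaptation_optional,
       array_optional = array_optional,
       variants = as.list(variants), notes = notes)
}

core_families <- list(
  fam("cas1",  "adaptation"),
  fam("cas2",  "adaptation"),
  fam("cas3",  "effector-core"),
  fam("cas4",  "adaptation"),
  fam("cas5",  "effector-core"),
  fam("cas6",  "effector-core"),
  fam("cas7",  "effector-core"),
  fam("cas10", "effector-core"),
  fam("cas11", "effector-core"),
  fam("csm2",  "effector-core"),
  fam("cmr5",  "effector-core")
)

ls_families <- list(
  fam("cas8a",  "signature-effector"),
  fam("cas8b",  "signature-effector"),
  fam("cas8c",  "signature-effector"),
  fam("cas8e",  "signature-effector", "cse1"),
  fam("cas8f",  "signature-effector", "csy1"),
  fam("cas8u",  "signature-effector", "gsu0054"),
  fam("cas10d", "signature-effector"),
  fam("cas9",   "signature-effector", "csn1"),
  fam("csf1",   "signature-effector", "cas8-like"),
  fam("dinG",   "signature-effector", "casDinG")
)

class2_2020 <- list(
  fam("cas12a", "signature-effector", "cpf1"),
  fam("cas12b", "signature-effector", "c2c1"),
  fam("cas12c", "signature-effector", "c2c3"),
  fam("cas12d", "signature-effector", "casY"),
  fam("cas12e", "signature-effector", "casX"),
  fam("cas12f", "signature-effector", c("cas14a", "c2c10")),
  fam("cas12g", "signature-effector"),
  fam("cas12h", "signature-effector"),
  fam("cas12i", "signature-effector"),
  fam("cas12k", "signature-effector", "c2c5"),
  fam("cas13a", "signature-effector", "c2c2"),
  fam("cas13b", "signature-effector"),
  fam("cas13c", "signature-effector"),
  fam("cas13d", "signature-effector", "casRx")
)

misc_2020 <- list(
  fam("csn2",     "ancillary"),
  fam("csx19",    "ancillary"),
  fam("csx22",    "ancillary"),
  fam("csx24",    "ancillary"),
  fam("csx25",    "ancillary"),
  fam("cas7-11e", "signature-effector", "gramp")
)

new_2025 <- list(
  fam("cas8h",    "signature-effector"),
  fam("cas9d",    "signature-effector"),
  fam("cas14",    "signature-effector"),
  fam("cas7-11i", "signature-effector"),
  fam("csx26",    "signature-effector"),
  fam("cas12l",   "signature-effector", "casLambda"),
  fam("cas12n",   "signature-effector"),
  fam("cas12o",   "signature-effector"),
  fam("cas12p",   "signature-effector"),
  fam("cas12q",   "signature-effector"),
  fam("cas13e",   "signature-effector"),
  fam("cas13f",   "signature-effector"),
  # CARF-domain sensor / ring-nuclease nomenclature (Crf1-11, Crn1-5)
  fam("crf1",  "sensor", "csm6"),
  fam("crf2",  "sensor", "csx1"),
  fam("crf3",  "sensor"),
  fam("crf4",  "sensor"),
  fam("crf5",  "sensor"),
  fam("crf6",  "sensor"),
  fam("crf7",  "sensor"),
  fam("crf8",  "sensor"),
  fam("crf9",  "sensor"),
  fam("crf10", "sensor"),
  fam("crf11", "sensor"),
  fam("crn1",  "ring-nuclease"),
  fam("crn2",  "ring-nuclease"),
  fam("crn3",  "ring-nuclease", "csx3"),
  fam("crn4",  "ring-nuclease"),
  fam("crn5",  "ring-nuclease"),
  fam("corA",  "signalling-effector"),
  fam("nucC",  "signalling-effector"),
  fam("tnsB",  "transposon"),
  fam("tnsC",  "transposon"),
  fam("tniQ",  "transposon")
)

families_2020 <- c(core_families, ls_families, class2_2020, misc_2020)
families_2025 <- c(families_2020, new_2025)

type_i <- function(letter, sig, variants = character(0), notes = "") {
  sub(paste0("I-", letter), 1, "I", c(sig, "cas7", "cas5", "cas3"),
      variants = variants, notes = notes)
}

subtypes_2020 <- list(
  type_i("A", "cas8a"),
  type_i("B", "cas8b"),
  type_i("C", "cas8c"),
  type_i("D", "cas10d"),
  type_i("E", "cas8e"),
  type_i("F", "cas8f", variants = c("I-F1", "I-F2", "I-F3")),
  type_i("G", "cas8u", notes = "Formerly subtype I-U."),
  sub("II-A", 2, "II", c("cas9", "csn2")),
  sub("II-B", 2, "II", c("cas9", "cas4")),
  sub("II-C", 2, "II", "cas9", forbidden = "csn2",
      variants = "II-C2"),
  sub("III-A", 1, "III", c("cas10", "cas7", "cas5", "csm2"),
      adaptation_optional = TRUE),
  sub("III-B", 1, "III", c("cas10", "cas7", "cas5", "cmr5"),
      adaptation_optional = TRUE),
  sub("III-C", 1, "III", c("cas10", "cas7", "cas5", "cas11"),
      adaptation_optional = TRUE,
      notes = "Cyclase domain of Cas10 inactivated."),
  sub("III-D", 1, "III", c("cas10", "cas7", "cas5", "csx19"),
      adaptation_optional = TRUE, variants = c("III-D1", "III-D2")),
  sub("III-E", 1, "III", "cas7-11e", forbidden = "cas10",
      adaptation_optional = TRUE,
      notes = "Single multidomain effector; no cas10 gene."),
  sub("III-F", 1, "III", c("cas10", "cas7", "cas5", "csx24"),
      adaptation_optional = TRUE,
      notes = "Csx24 used as the subtype marker in this registry."),
  sub("IV-A", 1, "IV", c("csf1", "cas7", "cas5", "dinG"),
      adaptation_optional = TRUE, array_optional = TRUE),
  sub("IV-B", 1, "IV", c("csf1", "cas7", "cas5"), forbidden = "dinG",
      adaptation_optional = TRUE, array_optional = TRUE),
  sub("IV-C", 1, "IV", c("csf1", "cas7", "cas5"),
      adaptation_optional = TRUE, array_optional = TRUE,
      notes = paste("HD-fused large subunit; separable from IV-B only by",
                    "subtype-specific large-subunit profiles.")),
  sub("V-A", 2, "V", "cas12a", variants = "V-A2"),
  sub("V-B", 2, "V", "cas12b"),
  sub("V-C", 2, "V", "cas12c", adaptation_optional = TRUE),
  sub("V-D", 2, "V", "cas12d", adaptation_optional = TRUE),
  sub("V-E", 2, "V", "cas12e", adaptation_optional = TRUE),
  sub("V-F", 2, "V", "cas12f", adaptation_optional = TRUE,
      variants = c("V-F1", "V-F2", "V-F3")),
  sub("V-G", 2, "V", "cas12g", adaptation_optional = TRUE),
  sub("V-H", 2, "V", "cas12h", adaptation_optional = TRUE),
  sub("V-I", 2, "V", "cas12i", adaptation_optional = TRUE),
  sub("V-K", 2, "V", "cas12k", adaptation_optional = TRUE,
      notes = "Tn7-associated (CAST); nuclease-dead effector."),
  sub("VI-A", 2, "VI", "cas13a", adaptation_optional = TRUE),
  sub("VI-B", 2, "VI", "cas13b", adaptation_optional = TRUE,
      variants = c("VI-B1", "VI-B2")),
  sub("VI-C", 2, "VI", "cas13c", adaptation_optional = TRUE),
  sub("VI-D", 2, "VI", "cas13d", adaptation_optional = TRUE)
)

amend <- function(subtypes, id, field, value) {
  i <- which(vapply(subtypes, `[[`, "", "id") == id)
  subtypes[[i]][[field]] <- value
  subtypes
}

subtypes_2025 <- subtypes_2020
subtypes_2025 <- amend(subtypes_2025, "I-A", "variants", list("I-A-Mu"))
subtypes_2025 <- amend(subtypes_2025, "I-B", "variants", list("I-B2"))
subtypes_2025 <- amend(subtypes_2025, "I-C", "variants", list("I-C-CAST"))
subtypes_2025 <- amend(subtypes_2025, "I-D", "variants", list("I-D-CAST"))
subtypes_2025 <- amend(subtypes_2025, "I-E", "variants",
                       list("I-E2", "I-E3", "I-E5"))
subtypes_2025 <- amend(subtypes_2025, "I-F", "variants",
                       list("I-F1", "I-F2", "I-F3", "I-F4"))
subtypes_2025 <- amend(subtypes_2025, "IV-A", "variants",
                       list("IV-A2", "IV-A-CAST"))
subtypes_2025 <- amend(subtypes_2025, "III-A", "variants", list("III-A2"))
subtypes_2025 <- amend(subtypes_2025, "V-B", "variants", list("V-B3"))
subtypes_2025 <- amend(subtypes_2025, "V-C", "variants", list("V-M"))
subtypes_2025 <- amend(subtypes_2025, "V-F", "variants",
                       list("V-F1", "V-F2", "V-F3", "V-J"))
subtypes_2025 <- amend(subtypes_2025, "VI-B", "variants",
                       list("VI-B1", "VI-B2", "VI-B3"))

subtypes_2025 <- c(subtypes_2025, list(
  type_i("H", "cas8h",
         notes = paste("Eighth type I subtype of the current inventory;",
                       "transcribed from the extended subtype figures.")),
  sub("II-D", 2, "II", c("cas9d", "cas4"),
      notes = "Compact Cas9; absorbs the former II-C2 variant."),
  sub("III-G", 1, "III", c("cas10", "cas7", "cas5", "csx26"),
      adaptation_optional = TRUE, array_optional = TRUE,
      notes = paste("Sulfolobales-specific; inactivated cyclase; no CRISPR",
                    "array found so far, crRNA presumably recruited in",
                    "trans.")),
  sub("III-H", 1, "III", c("cas10", "cas7", "cas5", "cas11"),
      adaptation_optional = TRUE,
      notes = paste("Highly diverged small subunit replacing the Cas10",
                    "C-terminal domain; inactivated cyclase. Separable from",
                    "III-C only by subtype-specific profiles.")),
  sub("III-I", 1, "III", c("cas7-11i", "cas10"),
      adaptation_optional = TRUE,
      notes = paste("Cas7-11i multidomain effector with an extremely",
                    "diverged Cas10 derivative.")),
  sub("V-L", 2, "V", "cas12l", adaptation_optional = TRUE),
  sub("V-N", 2, "V", "cas12n", adaptation_optional = TRUE),
  sub("V-O", 2, "V", "cas12o", adaptation_optional = TRUE,
      notes = "RuvC inactivated; interference by transcription blocking."),
  sub("V-P", 2, "V", "cas12p", adaptation_optional = TRUE,
      notes = "RuvC inactivated; interference by transcription blocking."),
  sub("V-Q", 2, "V", "cas12q", adaptation_optional = TRUE),
  sub("VI-E", 2, "VI", "cas13e", adaptation_optional = TRUE,
      notes = "Smallest, most compact Cas13."),
  sub("VI-F", 2, "VI", "cas13f", adaptation_optional = TRUE,
      notes = "Restricted to Brachyspira."),
  sub("VII", 1, "VII", c("cas14", "cas7", "cas5"),
      required_any = list(),
      adaptation_optional = TRUE,
      notes = paste("Cas14 beta-CASP effector in an operon with Cas7 and",
                    "Cas5, sometimes Cas6; no adaptation module; degenerate",
                    "arrays."))
))

legacy_map <- list("I-U" = "I-G", "II-C2" = "II-D", "V-U5" = "V-K")

registry_2020 <- list(version = "2020", families = families_2020,
                      subtypes = subtypes_2020,
                      legacy_subtype_map = list())
registry_2025 <- list(version = "2025", families = families_2025,
                      subtypes = subtypes_2025,
                      legacy_subtype_map = legacy_map)

jsonlite::write_json(registry_2020, "inst/extdata/registry_2020.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
jsonlite::write_json(registry_2025, "inst/extdata/registry_2025.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("subtypes 2020:", length(subtypes_2020),
    " 2025:", length(subtypes_2025), "\n")
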