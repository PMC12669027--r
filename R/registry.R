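#' @importFrom rlang .data
NULL

FAMILY_ROLES <- c("adaptation", "effector-core", "signature-effector",
                  "ancillary", "sensor", "signalling-effector",
                  "ring-nuclease", "transposon")

CAS_TYPES <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Construct a classification registry
#'
#' A registry encodes one version of the CRISPR-Cas taxonomy: the gene
#' families (with roles and legacy names) and the subtype definitions
#' (required, alternative and forbidden gene families, whether the
#' adaptation module and the CRISPR array are dispensable, and the known
#' variants of each subtype). The package bundles transcriptions of the
#' 2020 taxonomy (6 types, 33 subtypes) and the current one (2 classes,
#' 7 types, 46 subtypes); see [load_registry()].
#'
#' @param version Registry version token (e.g. `"2025"`). The bundled
#'   versions `"2020"` and `"2025"` carry additional count invariants that
#'   are enforced by [validate_registry()].
#' @param families Data frame with columns `name`, `role`, `legacy_names`
#'   (list column), one row per gene family.
#' @param subtypes List of subtype definitions as produced by
#'   [subtype_def()].
#' @param legacy_subtype_map Named character vector mapping legacy subtype
#'   ids to current ids (used by [diff_registries()]).
#' @return A validated `cas_registry` object.
#' @export
new_registry <- function(version, families, subtypes,
                         legacy_subtype_map = character(0)) {
  reg <- structure(
    list(version = as.character(version),
         families = tibble::as_tibble(families),
         subtypes = subtypes,
         legacy_subtype_map = legacy_subtype_map),
    class = "cas_registry"
  )
  viol <- validate_registry(reg)
  if (length(viol) > 0L) {
    stop("invalid registry:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  reg
}

#' Define one subtype of the taxonomy
#'
#' @param id Subtype id, e.g. `"I-A"`, `"III-E"`, `"VII"`.
#' @param cas_class Class, 1 or 2.
#' @param cas_type Type, one of `"I"`..`"VII"`; must be consistent with the
#'   id prefix.
#' @param required_all Gene families that must all be present for a locus
#'   of this subtype to be complete (the effector-module inventory,
#'   including the subtype signature).
#' @param required_any List of alternative family sets; at least one member
#'   of each set must be present.
#' @param forbidden Families whose presence disqualifies the subtype.
#' @param adaptation_optional If `TRUE`, cas1/cas2 are not required for
#'   completeness (e.g. type VII, which lacks adaptation modules).
#' @param array_optional If `TRUE`, an attached CRISPR array is not
#'   required (e.g. III-G, where no array has been found).
#' @param variants Ids of known variants nested under this subtype;
#'   variants are not counted as subtypes.
#' @param notes Free-text annotation.
#' @return A `subtype_def` list.
#' @export
subtype_def <- function(id, cas_class, cas_type, required_all,
                        required_any = list(), forbidden = character(0),
                        adaptation_optional = FALSE, array_optional = FALSE,
                        variants = character(0), notes = "") {
  structure(
    list(id = as.character(id),
         cas_class = as.integer(cas_class),
         cas_type = as.character(cas_type),
         required_all = as.character(required_all),
         required_any = lapply(required_any, as.character),
         forbidden = as.character(forbidden),
         adaptation_optional = isTRUE(adaptation_optional),
         array_optional = isTRUE(array_optional),
         variants = as.character(variants),
         notes = as.character(notes)),
    class = "subtype_def"
  )
}

# Roman-numeral type implied by a subtype id ("III-E" -> "III", "VII" -> "VII")
subtype_id_type <- function(id) {
  stem <- sub("-.*$", "", id)
  ifelse(stem %in% CAS_TYPES, stem, NA_character_)
}

#' Load a registry from its JSON serialization
#'
#' The on-disk format is documented JSON with top-level fields `version`,
#' `families` (array of `{name, role, legacy_names}`), `subtypes` (array of
#' subtype definitions) and `legacy_subtype_map` (object mapping legacy to
#' current subtype ids). The file is validated on load; any invariant
#' violation is an error.
#'
#' @param path Path to a registry JSON file, or one of the shorthand
#'   tokens `"2025"` / `"2020"` for the bundled registries.
#' @return A validated `cas_registry`.
#' @examples
#' reg <- load_registry("2025")
#' registry_counts(reg)$n_subtypes
#' @export
load_registry <- function(path) {
  if (path %in% c("2020", "2025")) {
    path <- system.file("extdata", paste0("registry_", path, ".json"),
                        package = "crisprcensus", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("registry file not found: ", path,
                               call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("failed to parse registry JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!is.list(raw) || is.null(raw$version) || is.null(raw$subtypes) ||
      is.null(raw$families)) {
    stop("registry file '", path,
         "' lacks version/families/subtypes fields", call. = FALSE)
  }
  families <- tibble::tibble(
    name = vapply(raw$families, function(f) f$name, ""),
    role = vapply(raw$families, function(f) f$role, ""),
    legacy_names = lapply(raw$families,
                          function(f) as.character(unlist(f$legacy_names)))
  )
  subtypes <- lapply(raw$subtypes, function(s) {
    subtype_def(
      id = s$id, cas_class = s$cas_class, cas_type = s$cas_type,
      required_all = as.character(unlist(s$required_all)),
      required_any = lapply(s$required_any,
                            function(a) as.character(unlist(a))),
      forbidden = as.character(unlist(s$forbidden)),
      adaptation_optional = isTRUE(s$adaptation_optional),
      array_optional = isTRUE(s$array_optional),
      variants = as.character(unlist(s$variants)),
      notes = if (is.null(s$notes)) "" else s$notes
    )
  })
  legacy <- unlist(raw$legacy_subtype_map)
  if (is.null(legacy)) legacy <- character(0)
  new_registry(raw$version, families, subtypes, legacy)
}

#' Write a registry back to JSON
#'
#' `load_registry(save_registry(reg, path))` round-trips to an equal
#' registry.
#'
#' @param reg A `cas_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(reg, path) {
  stopifnot(inherits(reg, "cas_registry"))
  out <- list(
    version = reg$version,
    families = lapply(seq_len(nrow(reg$families)), function(i) {
      list(name = reg$families$name[i], role = reg$families$role[i],
           legacy_names = as.list(reg$families$legacy_names[[i]]))
    }),
    subtypes = lapply(reg$subtypes, function(s) {
      list(id = s$id, cas_class = s$cas_class, cas_type = s$cas_type,
           required_all = as.list(s$required_all),
           required_any = lapply(s$required_any, as.list),
           forbidden = as.list(s$forbidden),
           adaptation_optional = s$adaptation_optional,
           array_optional = s$array_optional,
           variants = as.list(s$variants), notes = s$notes)
    }),
    legacy_subtype_map = as.list(reg$legacy_subtype_map)
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  })
  invisible(path)
}

#' List a registry's invariant violations
#'
#' Returns a character vector of human-readable violations; an empty vector
#' means the registry is valid. Violations are data, not errors, so a
#' partially broken registry can be inspected.
#'
#' @param reg A parsed (not necessarily valid) registry.
#' @return Character vector of violation messages, possibly empty.
#' @export
validate_registry <- function(reg) {
  v <- character(0)
  fam <- reg$families
  if (anyDuplicated(fam$name)) {
    v <- c(v, paste0("duplicate gene family name(s): ",
                     paste(unique(fam$name[duplicated(fam$name)]),
                           collapse = ", ")))
  }
  bad_role <- !(fam$role %in% FAMILY_ROLES)
  if (any(bad_role)) {
    v <- c(v, paste0("gene family '", fam$name[bad_role],
                     "' has unknown role '", fam$role[bad_role], "'"))
  }
  ids <- vapply(reg$subtypes, function(s) s$id, "")
  if (anyDuplicated(ids)) {
    v <- c(v, paste0("duplicate subtype id(s): ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (s in reg$subtypes) {
    implied <- subtype_id_type(s$id)
    if (is.na(implied) || implied != s$cas_type) {
      v <- c(v, paste0("subtype '", s$id, "': cas_type '", s$cas_type,
                       "' inconsistent with id prefix"))
    }
    if (!s$cas_class %in% c(1L, 2L)) {
      v <- c(v, paste0("subtype '", s$id, "': cas_class must be 1 or 2"))
    }
    both <- intersect(s$required_all, s$forbidden)
    if (length(both) > 0L) {
      v <- c(v, paste0("subtype '", s$id, "': families both required and ",
                       "forbidden: ", paste(both, collapse = ", ")))
    }
    refs <- unique(c(s$required_all, unlist(s$required_any), s$forbidden))
    dangling <- setdiff(refs, fam$name)
    if (length(dangling) > 0L) {
      v <- c(v, paste0("subtype '", s$id, "': unknown gene family ",
                       "reference(s): ", paste(dangling, collapse = ", ")))
    }
  }
  # Versioned count invariants for the bundled taxonomies
  if (identical(reg$version, "2025")) {
    cc <- registry_counts(reg, validate = FALSE)
    if (cc$n_classes != 2L) v <- c(v, "version 2025 must have 2 classes")
    if (cc$n_types != 7L) v <- c(v, "version 2025 must have 7 types")
    if (cc$n_subtypes != 46L) v <- c(v, "version 2025 must have 46 subtypes")
    if (!identical(unname(cc$per_class["1"]), 21L)) {
      v <- c(v, "version 2025 must have 21 class 1 subtypes")
    }
  } else if (identical(reg$version, "2020")) {
    cc <- registry_counts(reg, validate = FALSE)
    if (cc$n_types != 6L) v <- c(v, "version 2020 must have 6 types")
    if (cc$n_subtypes != 33L) v <- c(v, "version 2020 must have 33 subtypes")
  }
  v
}

#' Tabulate a registry's taxonomy counts
#'
#' Counts are computed by enumeration over the subtype definitions, never
#' cached.
#'
#' @param reg A `cas_registry`.
#' @param validate Check the registry first (default `TRUE`).
#' @return List with `n_classes`, `n_types`, `n_subtypes`, `per_type`
#'   (named integer vector of subtype counts per type) and `per_class`.
#' @examples
#' registry_counts(load_registry("2025"))$per_type
#' @export
registry_counts <- function(reg, validate = TRUE) {
  if (validate) {
    viol <- validate_registry(reg)
    if (length(viol) > 0L) {
      stop("registry is invalid; see validate_registry()", call. = FALSE)
    }
  }
  types <- vapply(reg$subtypes, function(s) s$cas_type, "")
  classes <- vapply(reg$subtypes, function(s) s$cas_class, 0L)
  per_type <- vapply(split(types, factor(types, levels = CAS_TYPES)),
                     length, 0L)
  per_type <- per_type[per_type > 0L]
  per_class <- vapply(split(classes, as.character(classes)), length, 0L)
  list(n_classes = length(unique(classes)),
       n_types = length(unique(types)),
       n_subtypes = length(reg$subtypes),
       per_type = per_type,
       per_class = per_class)
}

#' Subtype additions and removals between two registry versions
#'
#' Legacy subtype ids are mapped to their current names (using the legacy
#' maps of both registries) before the set difference, so renames do not
#' count as additions. The operation is antisymmetric:
#' `diff_registries(a, b)$added == diff_registries(b, a)$removed`.
#'
#' @param new,old Two validated registries.
#' @return List with character vectors `added` and `removed`.
#' @examples
#' d <- diff_registries(load_registry("2025"), load_registry("2020"))
#' length(d$added)  # 13
#' @export
diff_registries <- function(new, old) {
  stopifnot(inherits(new, "cas_registry"), inherits(old, "cas_registry"))
  map <- c(new$legacy_subtype_map, old$legacy_subtype_map)
  canon <- function(ids) {
    hit <- ids %in% names(map)
    ids[hit] <- unname(map[ids[hit]])
    unique(ids)
  }
  new_ids <- canon(vapply(new$subtypes, function(s) s$id, ""))
  old_ids <- canon(vapply(old$subtypes, function(s) s$id, ""))
  list(added = sort(setdiff(new_ids, old_ids)),
       removed = sort(setdiff(old_ids, new_ids)))
}

#' Look up one subtype definition
#' @param reg A `cas_registry`.
#' @param id Subtype id.
#' @return The `subtype_def`, or an error if absent.
#' @export
registry_subtype <- function(reg, id) {
  ids <- vapply(reg$subtypes, function(s) s$id, "")
  i <- match(id, ids)
  if (is.na(i)) stop("unknown subtype id: ", id, call. = FALSE)
  reg$subtypes[[i]]
}

#' Gene family table of a registry
#' @param reg A `cas_registry`.
#' @return Tibble with columns `name`, `role`, `legacy_names`.
#' @export
registry_families <- function(reg) reg$families

#' Core cas gene test
#'
#' Core cas genes (cas1-cas14, including lettered variants such as cas8a,
#' cas12f, cas9d and the fused cas7-11e/i effectors) are the universal
#' marker set that seeds locus assembly. Families such as csf1, csn2, csx26
#' or crf1 are not core.
#'
#' @param family Character vector of gene family names.
#' @return Logical vector.
#' @examples
#' is_core_family(c("cas1", "cas12a", "csf1", "cas7-11e"))
#' @export
is_core_family <- function(family) {
  grepl("^cas(1[0-4]|[1-9])($|[a-z0-9-])", family)
}

# Families that appear in exactly one subtype's required_all set: such a
# family on its own is diagnostic evidence for that subtype.
unique_signature_map <- function(reg) {
  pairs <- do.call(rbind, lapply(reg$subtypes, function(s) {
    if (length(s$required_all) == 0L) return(NULL)
    data.frame(family = s$required_all, subtype = s$id,
               stringsAsFactors = FALSE)
  }))
  tab <- table(unique(pairs)$family)
  uniq <- names(tab)[tab == 1L]
  pairs <- pairs[pairs$family %in% uniq, , drop = FALSE]
  stats::setNames(pairs$subtype, pairs$family)
}

#' @export
print.cas_registry <- function(x, ...) {
  cc <- registry_counts(x, validate = FALSE)
  cat("CRISPR-Cas classification registry, version ", x$version, "\n",
      "  ", cc$n_classes, " classes, ", cc$n_types, " types, ",
      cc$n_subtypes, " subtypes; ", nrow(x$families), " gene families\n",
      sep = "")
  invisible(x)
}
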