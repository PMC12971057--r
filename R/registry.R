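# Profile registry: maps each profile name to its bitscore significance
# cutoff, chelator category, and role in classification. The registry (not
# the code) carries the chelator-group mapping, so new chelating groups can
# be added without code changes.

REGISTRY_CATEGORIES <- c(
  "catechol", "salicylate", "hydroxamate", "beta-OHAsp", "beta-OHHis",
  "graminine", "Dmaq", "pyoverdine-chromophore",
  "NRPS-core", "NRPS-domain-marker", "negative-constraint", "transporter",
  "other")

REGISTRY_ROLES <- c("marker", "core", "negative", "transporter")

# Chelator categories that name a chelating-group in a region's profile.
CHELATOR_GROUPS <- c(
  "catechol", "salicylate", "hydroxamate", "beta-OHAsp", "beta-OHHis",
  "graminine", "Dmaq", "pyoverdine-chromophore", "NRPS-domain-marker")

#' Build or validate a profile registry
#'
#' A profile registry is a data frame with columns `profile` (unique name),
#' `cutoff` (bitscore significance cutoff, bits, >= 0), `category` (one of
#' the chelator groups, `NRPS-core`, `NRPS-domain-marker`,
#' `negative-constraint`, `transporter` or `other`), and `role` (one of
#' `marker`, `core`, `negative`, `transporter`).
#'
#' @param x A data frame with the four registry columns.
#' @return A validated `profile_registry`.
#' @export
as_profile_registry <- function(x) {
  if (inherits(x, "profile_registry")) return(x)
  stopifnot(is.data.frame(x))
  need <- c("profile", "cutoff", "category", "role")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("registry is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, need]
  x$profile <- as.character(x$profile)
  x$cutoff <- as.numeric(x$cutoff)
  x$category <- as.character(x$category)
  x$role <- as.character(x$role)
  dup <- unique(x$profile[duplicated(x$profile)])
  if (length(dup) > 0L) {
    stop("duplicate profile name(s) in registry: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(x$category), REGISTRY_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop("unknown registry category token(s): ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(x$role), REGISTRY_ROLES)
  if (length(bad_role) > 0L) {
    stop("unknown registry role token(s): ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$cutoff)) || any(x$cutoff < 0)) {
    stop("registry cutoffs must be finite and >= 0", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("profile_registry", "data.frame")
  x
}

#' Read a profile registry from TSV or JSON
#'
#' The TSV dialect has a header line `profile  cutoff  category  role`; the
#' JSON dialect is an array of objects with the same fields. Duplicate
#' profile names and unknown category/role tokens are rejected.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` registry file.
#' @return A `profile_registry`.
#' @export
read_profile_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  }
  as_profile_registry(x)
}

#' Write a profile registry as TSV
#'
#' @param registry A `profile_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_registry <- function(registry, path) {
  registry <- as_profile_registry(registry)
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The bundled default registry
#'
#' Returns the toy registry shipped with the package: all identifiers of the
#' canonical NRP-metallophore rule (chelator biosynthesis markers, the NRPS
#' core domains, the negative-constraint profiles) plus the three
#' siderophore-transporter Pfam families PF00593 (TonB-dependent receptor),
#' PF01032 (FecCD transport family) and PF01497 (periplasmic binding
#' protein). Cutoffs are illustrative round values; real deployments
#' substitute profile-specific calibrated cutoffs (see [choose_cutoff()]).
#'
#' @return A `profile_registry`.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "registry_core.tsv",
                      package = "metallominer", mustWork = TRUE)
  read_profile_registry(path)
}

#' @export
print.profile_registry <- function(x, ...) {
  cat(sprintf("<profile_registry> %d profiles (%d marker, %d core, %d negative, %d transporter)\n",
              nrow(x), sum(x$role == "marker"), sum(x$role == "core"),
              sum(x$role == "negative"), sum(x$role == "transporter")))
  print.data.frame(x, ...)
  invisible(x)
}

registry_lookup <- function(registry, profiles, field) {
  i <- match(profiles, registry$profile)
  if (anyNA(i)) {
    stop("profile(s) missing from registry: ",
         paste(sort(profiles[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  registry[[field]][i]
}

#' Check that a rule's identifiers resolve in a registry
#'
#' @param rule A `rule_expr`.
#' @param registry A `profile_registry`.
#' @return `TRUE`, invisibly; errors if any identifier is missing.
#' @export
validate_rule_registry <- function(rule, registry) {
  registry <- as_profile_registry(registry)
  ids <- list_identifiers(rule)
  all_ids <- union(ids$positive, ids$negated)
  missing <- setdiff(all_ids, registry$profile)
  if (length(missing) > 0L) {
    stop("rule identifier(s) not in registry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
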