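# Indication-confounding annotation and consolidated result bundles.
#
# A drug-outcome association can be driven by the treated condition rather
# than the drug ("confounding by indication"): autoimmune disease, genital
# tract infection, metabolic disease, thyroid dysfunction and progestogen use
# are themselves risk factors for spontaneous abortion, so drugs indicated
# for them are annotated rather than interpreted at face value.

.INDICATION_CATEGORIES <- c("autoimmune", "reproductive_tract_infection",
                            "metabolic", "thyroid", "progestogen_use")

#' Indication-confounding categories
#' @return The five-member controlled vocabulary of risk-factor categories.
#' @export
indication_categories <- function() .INDICATION_CATEGORIES

#' Load a drug-to-indication map
#'
#' The map is user-editable YAML: drug name to a list of category codes from
#' [indication_categories()]. A small illustrative map covering well-known
#' drugs ships with the package (`system.file("extdata",
#' "indication_map.yaml", package = "pvsignal")`); it is an example, not a
#' licensed terminology extract.
#'
#' @param path YAML file path.
#' @return Named list (normalized drug name -> character categories).
#' @export
load_indication_map <- function(path = system.file("extdata",
                                                   "indication_map.yaml",
                                                   package = "pvsignal")) {
  raw <- yaml::read_yaml(path)
  map <- lapply(raw, function(x) as.character(unlist(x)))
  names(map) <- normalize_drug(names(map))
  bad <- setdiff(unique(unlist(map)), .INDICATION_CATEGORIES)
  if (length(bad))
    stop("unknown indication categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  map
}

#' Annotate drugs for indication confounding
#'
#' @param drugs Character vector of drug names.
#' @param map Named list from [load_indication_map()] (or built in code).
#' @return data.table: `drug`, `confounded` flag, `categories`
#'   (comma-separated triggers), `note` (`"unmapped"` for drugs absent from
#'   the map).
#' @export
annotate_indication_confounding <- function(drugs, map = load_indication_map()) {
  bad <- setdiff(unique(unlist(map)), .INDICATION_CATEGORIES)
  if (length(bad))
    stop("unknown indication categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  dn <- normalize_drug(drugs)
  rows <- lapply(dn, function(d) {
    cats <- map[[d]]
    if (is.null(cats))
      data.table(drug = d, confounded = FALSE, categories = "",
                 note = "unmapped")
    else
      data.table(drug = d, confounded = length(cats) > 0,
                 categories = paste(cats, collapse = ","), note = "")
  })
  rbindlist(rows)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Consolidate stage outputs into a report bundle
#'
#' Merges any subset of per-drug stage outputs into one master table keyed by
#' normalized drug name, together with a run manifest (timestamp, seed,
#' config hash, per-stage row counts). Column name collisions across stages
#' are suffixed; duplicate drug keys within a stage are a hard error.
#'
#' @param signals [signal_scan()] output.
#' @param subgroups `comparison` table from [subgroup_analysis()].
#' @param tto [tto_table()] output.
#' @param model [cross_validate()] metrics (stored in the manifest).
#' @param confounding [annotate_indication_confounding()] output.
#' @param config,seed Run provenance recorded in the manifest.
#' @return List of class `report_bundle`: `master` data.table + `manifest`.
#' @export
consolidate <- function(signals = NULL, subgroups = NULL, tto = NULL,
                        model = NULL, confounding = NULL, config = NULL,
                        seed = NULL) {
  stages <- list(signals = signals, subgroups = subgroups, tto = tto,
                 confounding = confounding)
  stages <- Filter(Negate(is.null), stages)
  if (!length(stages) && is.null(model))
    stop("no stage outputs supplied", call. = FALSE)
  master <- NULL
  for (nm in names(stages)) {
    st <- as.data.table(stages[[nm]])
    if (!"drug" %in% names(st))
      stop(sprintf("stage '%s' lacks a drug column", nm), call. = FALSE)
    st[, drug := normalize_drug(drug)]
    dup <- st$drug[duplicated(st$drug)]
    if (length(dup))
      stop(sprintf("stage '%s' has colliding drug keys after normalization: %s",
                   nm, paste(unique(dup), collapse = ", ")), call. = FALSE)
    other <- setdiff(names(st), "drug")
    setnames(st, other, paste(nm, other, sep = "."))
    master <- if (is.null(master)) st else
      merge(master, st, by = "drug", all = TRUE)
  }
  manifest <- list(
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config) else NA_character_,
    stage_rows = lapply(stages, nrow),
    model = if (!is.null(model))
      list(mean_auc = model$mean_auc, accuracy = model$accuracy,
           accuracy_ci = model$accuracy_ci, n_folds = length(model$auc))
      else NULL)
  structure(list(master = master, manifest = manifest),
            class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' `master.csv` plus `manifest.json`; a bundle written and re-read under the
#' same seed and config is identical.
#'
#' @param bundle A `report_bundle`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the file paths.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fm <- file.path(directory, "master.csv")
  fj <- file.path(directory, "manifest.json")
  if (!is.null(bundle$master)) fwrite(bundle$master, fm)
  jsonlite::write_json(bundle$manifest, fj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(master = fm, manifest = fj))
}

#' Read a report bundle written by [write_bundle()]
#' @param directory Bundle directory.
#' @return A `report_bundle`.
#' @export
read_bundle <- function(directory) {
  fm <- file.path(directory, "master.csv")
  master <- if (file.exists(fm)) fread(fm) else NULL
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(master = master, manifest = manifest),
            class = "report_bundle")
}
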