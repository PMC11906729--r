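#' @keywords internal
participant_fields <- function() {
  c("participant_id", "site", "age", "sex", "gaba_cr", "gaba_w",
    "fgm", "fwm", "fcsf", "moca", "education_years", "fit_error_pct",
    "qc_visual_pass", "acquired")
}

participant_required <- function() {
  c("participant_id", "site", "age", "sex")
}

#' Read participant records from CSV
#'
#' One row per participant. Columns are resolved through `schema`, a named
#' character vector mapping canonical field names to the column names used in
#' the file, so arbitrary site exports can be ingested without renaming.
#' Empty cells become `NA`; there are no numeric sentinels.
#'
#' Canonical fields: `participant_id`, `site`, `age` (years), `sex`
#' (`"male"`/`"female"`), `gaba_cr` and `gaba_w` (GABA+ in Cr- and
#' water-referenced institutional units), `fgm`/`fwm`/`fcsf` (voxel tissue
#' fractions), `moca` (0-30), `education_years`, `fit_error_pct`,
#' `qc_visual_pass` and `acquired` (logical). Only the first four are
#' required; missing optional columns yield all-`NA` fields (`qc_visual_pass`
#' and `acquired` default to `TRUE` when their columns are absent, i.e. a
#' file of clean scans).
#'
#' @param path CSV file with a header row.
#' @param schema Named character vector `c(canonical = "file_column", ...)`;
#'   fields not named in the schema are looked up under their canonical name.
#' @return A `data.frame` with the canonical columns, one row per input row,
#'   row order preserved, validated by [validate_participants()].
#' @export
read_participants <- function(path, schema = character()) {
  if (!file.exists(path)) stop("participant file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  fields <- participant_fields()
  colmap <- stats::setNames(fields, fields)
  if (length(schema)) {
    bad <- setdiff(names(schema), fields)
    if (length(bad)) stop("schema maps unknown field(s): ",
                          paste(bad, collapse = ", "))
    colmap[names(schema)] <- schema
  }
  missing_req <- participant_required()[
    !(colmap[participant_required()] %in% names(raw))]
  if (length(missing_req)) {
    stop("missing required column(s): ",
         paste(colmap[missing_req], collapse = ", "),
         " (for field(s) ", paste(missing_req, collapse = ", "), ")")
  }
  n <- nrow(raw)
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    participant_id = as.character(raw[[colmap["participant_id"]]]),
                    site = as.character(raw[[colmap["site"]]]))
  num_fields <- c("age", "gaba_cr", "gaba_w", "fgm", "fwm", "fcsf",
                  "moca", "education_years", "fit_error_pct")
  get_col <- function(f) if (colmap[f] %in% names(raw)) raw[[colmap[f]]] else rep(NA, n)
  out$age <- parse_numeric(get_col("age"), "age")
  out$sex <- tolower(as.character(get_col("sex")))
  for (f in setdiff(num_fields, "age")) {
    out[[f]] <- parse_numeric(get_col(f), f)
  }
  out$qc_visual_pass <- parse_logical(get_col("qc_visual_pass"), default = TRUE)
  out$acquired <- parse_logical(get_col("acquired"), default = TRUE)
  out <- out[, fields]
  validate_participants(out)
  out
}

parse_numeric <- function(x, field) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  suppress <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(suppress))
  if (length(bad)) {
    stop("non-numeric value in `", field, "` at row ", bad[1],
         ": \"", x[bad[1]], "\"")
  }
  suppress
}

parse_logical <- function(x, default = NA) {
  if (all(is.na(x))) return(rep(default, length(x)))
  if (is.logical(x)) return(ifelse(is.na(x), default, x))
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out[is.na(out)] <- default
  out
}

#' Validate participant records
#'
#' Checks the record-level invariants: positive age, known sex labels, voxel
#' tissue fractions in `[0, 1]` summing to `1 +/- 0.02` when all three are
#' present, MoCA within 0-30, and at least one GABA measure for acquired
#' scans that passed visual QC.
#'
#' @param records Data frame from [read_participants()] (or built in code
#'   with the same columns).
#' @return The records, invisibly; errors name the first offending row.
#' @export
validate_participants <- function(records) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(participant_fields(), names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  bad_age <- which(!is.na(records$age) & records$age <= 0)
  if (length(bad_age)) stop("nonpositive age at row ", bad_age[1])
  if (anyNA(records$age)) stop("missing age at row ", which(is.na(records$age))[1])
  bad_sex <- which(!records$sex %in% c("male", "female"))
  if (length(bad_sex)) stop("sex must be \"male\" or \"female\" (row ", bad_sex[1], ")")
  for (f in c("fgm", "fwm", "fcsf")) {
    bad <- which(!is.na(records[[f]]) & (records[[f]] < 0 | records[[f]] > 1))
    if (length(bad)) stop("`", f, "` outside [0, 1] at row ", bad[1])
  }
  all3 <- !is.na(records$fgm) & !is.na(records$fwm) & !is.na(records$fcsf)
  tsum <- records$fgm + records$fwm + records$fcsf
  bad_sum <- which(all3 & (tsum < 0.98 | tsum > 1.02))
  if (length(bad_sum)) {
    stop("tissue fractions sum to ", round(tsum[bad_sum[1]], 4),
         " at row ", bad_sum[1], " (must lie in [0.98, 1.02])")
  }
  bad_moca <- which(!is.na(records$moca) &
                      (records$moca < 0 | records$moca > 30))
  if (length(bad_moca)) stop("MoCA outside 0-30 at row ", bad_moca[1])
  need_gaba <- records$acquired %in% TRUE & records$qc_visual_pass %in% TRUE
  no_gaba <- which(need_gaba & is.na(records$gaba_cr) & is.na(records$gaba_w))
  if (length(no_gaba)) {
    stop("acquired, QC-passed record without any GABA measure at row ",
         no_gaba[1])
  }
  invisible(records)
}

#' Write participant records to CSV
#'
#' Inverse of [read_participants()] under the identity schema: nulls are
#' written as empty cells and a read-back reproduces the records.
#'
#' @param records Participant data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  validate_participants(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read lifespan observations from CSV
#'
#' Each row is one (age, GABA) measurement belonging to a dataset (cohort);
#' all rows of a dataset share one latent scaling factor and one reference
#' method. Columns: `dataset_id`, `age`, `gaba`, `reference_method`
#' (`"Cr"` or `"water"`), resolvable through `schema` as in
#' [read_participants()].
#'
#' @param path CSV file.
#' @param schema Named character vector mapping canonical names to file
#'   column names.
#' @return A validated `data.frame` with the four canonical columns.
#' @export
read_lifespan <- function(path, schema = character()) {
  if (!file.exists(path)) stop("lifespan file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  fields <- c("dataset_id", "age", "gaba", "reference_method")
  colmap <- stats::setNames(fields, fields)
  if (length(schema)) colmap[names(schema)] <- schema
  miss <- fields[!(colmap %in% names(raw))]
  if (length(miss)) stop("missing required column(s): ",
                         paste(colmap[miss], collapse = ", "))
  out <- data.frame(
    dataset_id = as.character(raw[[colmap["dataset_id"]]]),
    age = parse_numeric(raw[[colmap["age"]]], "age"),
    gaba = parse_numeric(raw[[colmap["gaba"]]], "gaba"),
    reference_method = as.character(raw[[colmap["reference_method"]]]),
    stringsAsFactors = FALSE)
  validate_lifespan(out)
  out
}

#' Validate lifespan observations
#'
#' Enforces the assumptions of the pooled trajectory model: positive GABA,
#' positive age, at least two observations per dataset, and every dataset's
#' age range overlapping at least one other dataset's (datasets are only
#' comparable through the shared curve where their ages overlap).
#'
#' @param obs Lifespan observation data frame.
#' @return `obs`, invisibly.
#' @export
validate_lifespan <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("dataset_id", "age", "gaba") %in% names(obs)))
  if (anyNA(obs$age) || anyNA(obs$gaba)) stop("lifespan rows must be complete")
  if (any(obs$gaba <= 0)) stop("GABA must be positive (row ",
                               which(obs$gaba <= 0)[1], ")")
  if (any(obs$age <= 0)) stop("age must be positive")
  sizes <- table(obs$dataset_id)
  if (any(sizes < 2)) {
    stop("dataset(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ids <- names(sizes)
  if (length(ids) > 1) {
    lo <- tapply(obs$age, obs$dataset_id, min)[ids]
    hi <- tapply(obs$age, obs$dataset_id, max)[ids]
    for (i in seq_along(ids)) {
      overlaps <- any(lo[-i] <= hi[i] & hi[-i] >= lo[i])
      if (!overlaps) {
        stop("dataset ", ids[i], " has an age range disjoint from all ",
             "others; the shared-curve model requires overlap")
      }
    }
  }
  invisible(obs)
}
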