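#' @importFrom stats sd var setNames aggregate pt qt cor model.matrix as.formula
#' @importFrom utils read.csv write.csv
NULL

# Factor-level conventions used throughout: the first-named class of each
# factor (Iberian, HO, fed) is the numerator of reported fold changes.
.breeds   <- c("Iberian", "Duroc")
.diets    <- c("HO", "CH")
.statuses <- c("fed", "fasting")

.cp_columns <- c("gene", "animal", "breed", "diet", "status",
                 "plate", "box", "replicate", "cp")

#' Canonical fatty-acid names
#'
#' The canonical spellings of the fatty acids reported in the motivating
#' feeding trial, used to normalise column headers on import.
#'
#' @return Character vector of canonical fatty-acid names.
#' @export
canonical_fa_names <- function() {
  c("C14:0", "C16:0", "C16:1n-9", "C16:1n-7", "C17:0", "C17:1",
    "C18:0", "C18:1n-9", "C18:1n-7", "C18:2n-6", "C18:3n-3", "C18:4n-3",
    "C20:0", "C20:1n-9", "C20:2", "C20:4n-6", "C20:3n-3",
    "C22:4n-6", "C22:5n-3", "C22:6n-3")
}

# Map a vector of FA labels to canonical spellings where recognisable
# ("C18.1n9", "c18:1 n-9" -> "C18:1n-9"); unknown labels returned unchanged.
.normalise_fa_name <- function(x) {
  canon <- canonical_fa_names()
  key <- function(v) gsub("[^a-z0-9]", "", tolower(v))
  idx <- match(key(x), key(canon))
  ifelse(is.na(idx), x, canon[idx])
}

#' Validate a table of qPCR well measurements
#'
#' Checks the long-format well table against the schema used across the
#' package: one row per well with `gene`, `animal`, `breed`, `diet`,
#' `status`, `plate`, `box`, `replicate` and `cp`.  Cp values must lie in
#' (0, 45); breed, diet and status must use the package's factor levels.
#'
#' @param wells data.frame of well measurements.
#' @return The validated data.frame (invisibly usable), with label columns
#'   as character and `cp` numeric.
#' @export
validate_wells <- function(wells) {
  missing <- setdiff(.cp_columns, names(wells))
  if (length(missing) > 0)
    stop("well table is missing column(s): ", paste(missing, collapse = ", "))
  wells <- as.data.frame(wells)
  for (col in setdiff(.cp_columns, c("cp", "replicate")))
    wells[[col]] <- as.character(wells[[col]])
  wells$cp <- as.numeric(wells$cp)
  if (anyNA(wells$cp))
    stop("non-numeric or missing cp values")
  if (any(wells$cp <= 0 | wells$cp >= 45))
    stop("cp values must lie in (0, 45); offending rows: ",
         paste(utils::head(which(wells$cp <= 0 | wells$cp >= 45), 5), collapse = ", "))
  bad <- setdiff(unique(wells$breed), .breeds)
  if (length(bad) > 0) stop("unknown breed level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(wells$diet), .diets)
  if (length(bad) > 0) stop("unknown diet level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(wells$status), .statuses)
  if (length(bad) > 0) stop("unknown status level(s): ", paste(bad, collapse = ", "))
  wells
}

#' Read an amplification-efficiency table
#'
#' Efficiencies are given on the percentage convention (100 = perfect
#' doubling) and converted to amplification factors `E = 1 + pct/100`,
#' the exponent base of the Cp transformation.
#'
#' @param path CSV with header `gene,efficiency_percent`.
#' @return Named numeric vector of amplification factors `E` in (1, 2].
#' @export
read_efficiency_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "efficiency_percent"), names(tab))
  if (length(missing) > 0)
    stop("efficiency table is missing column(s): ", paste(missing, collapse = ", "))
  pct <- as.numeric(tab$efficiency_percent)
  if (anyNA(pct) || any(pct <= 0 | pct > 100))
    stop("efficiency_percent must lie in (0, 100]")
  setNames(1 + pct / 100, tab$gene)
}

#' Read a long-format Cp table together with its efficiency table
#'
#' @param path CSV of well measurements (see [validate_wells()] for the schema).
#' @param efficiency_path CSV with header `gene,efficiency_percent`.
#' @return List with `wells` (validated data.frame) and `efficiencies`
#'   (named amplification factors).  Every gene present in the Cp table
#'   must have an efficiency.
#' @export
read_cp_table <- function(path, efficiency_path) {
  wells <- validate_wells(read.csv(path, stringsAsFactors = FALSE))
  eff <- read_efficiency_table(efficiency_path)
  orphan <- setdiff(unique(wells$gene), names(eff))
  if (length(orphan) > 0)
    stop("gene(s) without amplification efficiency: ", paste(orphan, collapse = ", "))
  list(wells = wells, efficiencies = eff)
}

#' Write a well table to CSV
#'
#' @param wells data.frame of well measurements.
#' @param path Output path.
#' @export
write_cp_table <- function(wells, path) {
  write.csv(validate_wells(wells)[.cp_columns], path, row.names = FALSE, quote = FALSE)
}

.fa_id_columns <- c("sample", "depot", "layer", "breed", "diet", "litter", "box")

#' Read a fatty-acid profile table
#'
#' One row per sample; identifier columns `sample,depot,layer,breed,diet,
#' litter,box` followed by one column per fatty acid (weight percent of
#' total fatty acids).  Fatty-acid headers are normalised to canonical
#' spellings; unrecognised headers are kept with a warning.
#'
#' @param path CSV path.
#' @return data.frame of profiles (empty data.frame for an empty file).
#' @export
read_fa_table <- function(path) {
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0)
    return(data.frame())
  validate_fa_profiles(tab)
}

#' Validate fatty-acid profiles
#'
#' @param profiles data.frame as described in [read_fa_table()].
#' @return Validated data.frame with normalised fatty-acid column names.
#' @export
validate_fa_profiles <- function(profiles) {
  profiles <- as.data.frame(profiles, check.names = FALSE)
  missing <- setdiff(.fa_id_columns, names(profiles))
  if (length(missing) > 0)
    stop("fatty-acid table is missing column(s): ", paste(missing, collapse = ", "))
  fa_cols <- setdiff(names(profiles), .fa_id_columns)
  norm <- .normalise_fa_name(fa_cols)
  unknown <- fa_cols[!(norm %in% canonical_fa_names()) & fa_cols != "other"]
  if (length(unknown) > 0)
    warning("unrecognised fatty-acid column(s) retained: ",
            paste(unknown, collapse = ", "))
  names(profiles)[match(fa_cols, names(profiles))] <- norm
  vals <- as.matrix(profiles[norm])
  if (any(vals < 0, na.rm = TRUE))
    stop("negative fatty-acid percentage")
  tot <- rowSums(vals, na.rm = TRUE)
  if (any(tot > 100 + 0.5))
    stop("fatty-acid percentages sum above 100 beyond rounding tolerance")
  profiles
}

#' Write a fatty-acid profile table to CSV
#'
#' @param profiles data.frame of profiles.
#' @param path Output path.
#' @export
write_fa_table <- function(profiles, path) {
  write.csv(validate_fa_profiles(profiles), path, row.names = FALSE, quote = FALSE)
}

#' Columns identifying one fatty-acid profile sample
#' @return Character vector of identifier column names.
#' @export
fa_id_columns <- function() .fa_id_columns

#' Fatty-acid value columns of a profile table
#' @param profiles data.frame of profiles.
#' @return Character vector of fatty-acid column names present.
#' @export
fa_value_columns <- function(profiles)
  setdiff(names(profiles), c(.fa_id_columns, "other"))
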