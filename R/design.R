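#' The eight treatment cells of the expression design
#'
#' Breed (Iberian/Duroc) crossed with diet (HO/CH) and feeding status
#' (fed/fasting).  Cell labels are `breed.diet.status`.
#'
#' @return data.frame with `cell`, `breed`, `diet`, `status`.
#' @export
treatment_cells <- function() {
  grid <- expand.grid(status = .statuses, diet = .diets, breed = .breeds,
                      stringsAsFactors = FALSE)[, c("breed", "diet", "status")]
  grid$cell <- paste(grid$breed, grid$diet, grid$status, sep = ".")
  grid[, c("cell", "breed", "diet", "status")]
}

#' Contrast vectors for the main and interaction effects
#'
#' Named weight vectors over the eight treatment cells.  Main effects
#' average the four cells of the first-named class (Iberian, HO, fed)
#' against the four cells of the other class, so a negative contrast on
#' the transformed scale (lower y = higher expression) back-transforms
#' to a fold change above 1 for the first-named class.  Interaction
#' contrasts are differences of differences (first-named minus
#' other-named in both factors).
#'
#' @return Named list of numeric weight vectors (each summing to zero),
#'   names `breed`, `status`, `diet`, `breed:status`, `breed:diet`,
#'   `diet:status`.
#' @export
effect_contrasts <- function() {
  cells <- treatment_cells()
  sgn <- function(col, first) ifelse(cells[[col]] == first, 1, -1)
  b <- sgn("breed", "Iberian"); d <- sgn("diet", "HO"); s <- sgn("status", "fed")
  contrasts <- list(
    "breed"        = b / 4,
    "status"       = s / 4,
    "diet"         = d / 4,
    "breed:status" = b * s / 4,
    "breed:diet"   = b * d / 4,
    "diet:status"  = d * s / 4)
  lapply(contrasts, function(w) setNames(w, cells$cell))
}
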