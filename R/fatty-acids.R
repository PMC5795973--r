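#' Default fatty-acid index memberships
#'
#' Named sets of fatty acids summed into the SFA, MUFA and PUFA indices
#' and the n-6 / n-3 families.  The memberships reproduce the index rows
#' of the motivating trial's composition tables exactly; note that
#' C17:1 is not counted in MUFA and C20:2 is not counted in PUFA (the
#' printed index rows only sum without them), and both exclusions can
#' be overridden.
#'
#' @return Named list of character vectors: `SFA`, `MUFA`, `PUFA`,
#'   `n6`, `n3`.
#' @export
fa_index_sets <- function() {
  list(
    SFA  = c("C14:0", "C16:0", "C17:0", "C18:0", "C20:0"),
    MUFA = c("C16:1n-9", "C16:1n-7", "C18:1n-9", "C18:1n-7", "C20:1n-9"),
    PUFA = c("C18:2n-6", "C18:3n-3", "C18:4n-3", "C20:4n-6", "C20:3n-3",
             "C22:4n-6", "C22:5n-3", "C22:6n-3"),
    n6   = c("C18:2n-6", "C20:4n-6", "C22:4n-6"),
    n3   = c("C18:3n-3", "C18:4n-3", "C20:3n-3", "C22:5n-3", "C22:6n-3"))
}

#' Compute fatty-acid summary indices
#'
#' Sums the member fatty acids of each index set per sample and derives
#' the per-sample n-6/n-3 ratio (the ratio is computed per sample, not
#' from the index sums of a table of means).  Fatty acids named in a set
#' but absent from the data are treated as 0 with a warning.
#'
#' @param profiles data.frame of fatty-acid profiles (or a named numeric
#'   vector for a single profile).
#' @param defs Index memberships, default [fa_index_sets()].
#' @return For a data.frame: the input with `SFA`, `MUFA`, `PUFA`, `n6`,
#'   `n3` and `n6_n3` columns appended; for a vector: a named numeric
#'   vector of the six index values.  A sample with zero n-3 sum gets an
#'   `NA` ratio with a warning.
#' @export
compute_indices <- function(profiles, defs = fa_index_sets()) {
  single <- is.numeric(profiles) && !is.null(names(profiles))
  if (single) profiles <- as.data.frame(as.list(profiles), check.names = FALSE)
  missing <- setdiff(unique(unlist(defs)), names(profiles))
  if (length(missing) > 0)
    warning("fatty acid(s) absent, treated as 0: ", paste(missing, collapse = ", "))
  sum_set <- function(set) {
    present <- intersect(set, names(profiles))
    if (length(present) == 0) return(rep(0, nrow(profiles)))
    rowSums(as.matrix(profiles[present]), na.rm = TRUE)
  }
  profiles$SFA  <- sum_set(defs$SFA)
  profiles$MUFA <- sum_set(defs$MUFA)
  profiles$PUFA <- sum_set(defs$PUFA)
  profiles$n6   <- sum_set(defs$n6)
  profiles$n3   <- sum_set(defs$n3)
  if (any(profiles$n3 == 0))
    warning("n-3 sum is zero for some sample(s); n-6/n-3 ratio set to NA")
  profiles$n6_n3 <- ifelse(profiles$n3 == 0, NA_real_, profiles$n6 / profiles$n3)
  if (single)
    return(unlist(profiles[1, c("SFA", "MUFA", "PUFA", "n6", "n3", "n6_n3")]))
  profiles
}

# Fit value ~ breed*diet (cell-mean coded) + (1|litter) + (1|box),
# dropping single-level random terms with a warning; falls back to OLS
# when no random term remains or the mixed fit degenerates.
.fa_engine <- function(d) {
  d$bd <- factor(paste(d$breed, d$diet, sep = "."))
  re <- character(0)
  for (term in c("litter", "box")) {
    if (length(unique(d[[term]])) > 1) {
      re <- c(re, sprintf("(1 | %s)", term))
    } else {
      warning("random term '", term, "' has a single level and was dropped")
    }
  }
  if (length(re) > 0) {
    form <- as.formula(paste("value ~ 0 + bd +", paste(re, collapse = " + ")))
    fit <- tryCatch(
      lmerTest::lmer(form, data = d, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, mixed = TRUE, levels = levels(d$bd)))
  }
  fit <- stats::lm(value ~ 0 + bd, data = d)
  list(fit = fit, mixed = FALSE, levels = levels(d$bd))
}

# Contrast over cell means for either engine: returns estimate, se, df, p.
.fa_contrast <- function(eng, w) {
  if (eng$mixed) {
    ct <- lmerTest::contest(eng$fit, matrix(w, nrow = 1), joint = FALSE,
                            confint = FALSE)
    return(list(est = ct[["Estimate"]], se = ct[["Std. Error"]],
                df = ct[["df"]], p = ct[["Pr(>|t|)"]]))
  }
  b <- stats::coef(eng$fit)
  V <- stats::vcov(eng$fit)
  est <- sum(w * b)
  se <- sqrt(as.numeric(t(w) %*% V %*% w))
  df <- eng$fit$df.residual
  tt <- est / se
  list(est = est, se = se, df = df,
       p = if (is.finite(tt)) 2 * pt(-abs(tt), df) else NA_real_)
}

#' Breed-by-diet mixed model for one fatty acid or index
#'
#' Fits the composition model: breed, diet and their interaction as
#' fixed effects (cell-mean coding over the four breed-by-diet cells)
#' with litter and box as random intercepts.  Least-squares means of a
#' factor level average the cell means over the other factor; effect
#' p-values come from the corresponding contrasts with Satterthwaite
#' degrees of freedom.
#'
#' @param profiles data.frame of fatty-acid profiles (one row per
#'   sample) containing `breed`, `diet`, `litter`, `box` and the
#'   response column.
#' @param response Name of the fatty-acid or index column to model.
#' @return data.frame with one row per factor level (`CH`, `HO`,
#'   `Duroc`, `Iberian`): `response`, `level`, `lsmean`, `se`, plus the
#'   effect columns `p_breed`, `p_diet`, `p_interaction` (repeated on
#'   every row for convenience).
#' @export
fit_fa_model <- function(profiles, response) {
  if (!(response %in% names(profiles)))
    stop("response column not found: ", response)
  d <- data.frame(value = profiles[[response]],
                  breed = factor(profiles$breed, levels = .breeds),
                  diet = factor(profiles$diet, levels = .diets),
                  litter = as.character(profiles$litter),
                  box = as.character(profiles$box))
  if (length(unique(d$breed)) < 2 || length(unique(d$diet)) < 2)
    stop("both breed and diet need at least two levels")
  eng <- .fa_engine(d)
  lv <- eng$levels  # breed.diet labels
  lev_w <- list(
    CH      = as.numeric(grepl("\\.CH$", lv)) / 2,
    HO      = as.numeric(grepl("\\.HO$", lv)) / 2,
    Duroc   = as.numeric(grepl("^Duroc\\.", lv)) / 2,
    Iberian = as.numeric(grepl("^Iberian\\.", lv)) / 2)
  sgn_b <- ifelse(grepl("^Iberian\\.", lv), 1, -1)
  sgn_d <- ifelse(grepl("\\.HO$", lv), 1, -1)
  eff_w <- list(breed = sgn_b / 2, diet = sgn_d / 2,
                interaction = sgn_b * sgn_d / 1)
  ls <- lapply(lev_w, function(w) .fa_contrast(eng, w))
  ef <- lapply(eff_w, function(w) .fa_contrast(eng, w))
  data.frame(
    response = response,
    level = names(lev_w),
    lsmean = vapply(ls, `[[`, numeric(1), "est"),
    se = vapply(ls, `[[`, numeric(1), "se"),
    p_breed = ef$breed$p,
    p_diet = ef$diet$p,
    p_interaction = ef$interaction$p,
    row.names = NULL)
}

#' Composition table across a family of fatty acids and indices
#'
#' Fits [fit_fa_model()] for every response, reshapes to one row per
#' response (level means side by side), and adjusts the breed and diet
#' p-values across the family by Benjamini--Hochberg with the effective
#' number of tests from the inter-response correlation matrix.
#'
#' @param profiles data.frame of profiles; indices are computed first
#'   when absent.
#' @param responses Character vector of response columns (default: all
#'   fatty-acid columns plus the five indices and the n-6/n-3 ratio).
#' @param defs Index memberships for [compute_indices()].
#' @return data.frame with one row per response: LS means and SEs per
#'   level, nominal and adjusted p-values per effect.
#' @export
fa_table <- function(profiles, responses = NULL, defs = fa_index_sets()) {
  if (!("SFA" %in% names(profiles)))
    profiles <- compute_indices(profiles, defs)
  if (is.null(responses)) {
    fa_cols <- intersect(fa_value_columns(profiles), canonical_fa_names())
    responses <- c(fa_cols, "SFA", "MUFA", "PUFA", "n6", "n3", "n6_n3")
  }
  fits <- lapply(responses, function(r) fit_fa_model(profiles, r))
  wide <- do.call(rbind, lapply(fits, function(f) {
    out <- data.frame(response = f$response[1])
    for (i in seq_len(nrow(f))) {
      out[[paste0("lsmean_", f$level[i])]] <- f$lsmean[i]
      out[[paste0("se_", f$level[i])]] <- f$se[i]
    }
    out$p_breed <- f$p_breed[1]
    out$p_diet <- f$p_diet[1]
    out$p_interaction <- f$p_interaction[1]
    out
  }))
  # effective number of tests from the correlation of the responses
  vals <- as.matrix(profiles[responses])
  ok <- apply(vals, 2, function(z) stats::sd(z, na.rm = TRUE) > 1e-12)
  corr <- diag(length(responses))
  if (sum(ok) >= 2)
    corr[ok, ok] <- stats::cor(vals[, ok, drop = FALSE],
                               use = "pairwise.complete.obs")
  diag(corr) <- 1
  m_eff <- effective_tests(corr)
  wide$padj_breed <- adjust_pvalues(wide$p_breed, m_eff)
  wide$padj_diet <- adjust_pvalues(wide$p_diet, m_eff)
  wide$padj_interaction <- adjust_pvalues(wide$p_interaction, m_eff)
  attr(wide, "m_eff") <- m_eff
  wide
}

#' Screen for fat-layer effects within each breed
#'
#' Preliminary model run before pooling layers: within each breed (and
#' each depot present) fits the composition model augmented with the
#' fat layer (outer/inner) and the layer-by-diet interaction as fixed
#' effects, keeping litter and box random plus an animal intercept for
#' the paired layers of the same animal.  Reports effect p-values only.
#'
#' @param profiles data.frame of profiles including a `layer` column
#'   with both `inner` and `outer` represented.
#' @param responses Response columns (default: canonical fatty acids
#'   present plus the indices if computed).
#' @return data.frame: `breed`, `depot`, `response`, `p_layer`,
#'   `p_layer_diet`.
#' @export
layer_screen <- function(profiles, responses = NULL) {
  layers <- unique(profiles$layer)
  if (!all(c("inner", "outer") %in% layers))
    stop("both fat layers (inner, outer) must be present")
  if (is.null(responses))
    responses <- intersect(fa_value_columns(profiles), canonical_fa_names())
  out <- list()
  for (b in unique(profiles$breed)) {
    for (dp in unique(profiles$depot)) {
      sub <- profiles[profiles$breed == b & profiles$depot == dp, ]
      if (nrow(sub) == 0) next
      if (!all(c("inner", "outer") %in% sub$layer))
        stop("both fat layers required within breed ", b, ", depot ", dp)
      for (r in responses) {
        d <- data.frame(value = sub[[r]],
                        layer = factor(sub$layer, levels = c("inner", "outer")),
                        diet = factor(sub$diet, levels = .diets),
                        litter = as.character(sub$litter),
                        box = as.character(sub$box),
                        animal = as.character(sub$sample))
        re <- c("(1 | animal)")
        for (term in c("litter", "box"))
          if (length(unique(d[[term]])) > 1)
            re <- c(re, sprintf("(1 | %s)", term))
        form <- as.formula(paste("value ~ diet * layer +",
                                 paste(re, collapse = " + ")))
        fit <- tryCatch(
          lmerTest::lmer(form, data = d, REML = TRUE,
                         control = lme4::lmerControl(calc.derivs = FALSE,
                                                     check.conv.singular = "ignore")),
          error = function(e) NULL)
        if (is.null(fit)) {
          p_layer <- NA_real_; p_ld <- NA_real_
        } else {
          an <- stats::anova(fit, type = 3)
          p_layer <- an["layer", "Pr(>F)"]
          p_ld <- an["diet:layer", "Pr(>F)"]
        }
        out[[length(out) + 1]] <- data.frame(
          breed = b, depot = dp, response = r,
          p_layer = p_layer, p_layer_diet = p_ld)
      }
    }
  }
  do.call(rbind, out)
}
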