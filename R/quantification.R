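#' Run all main-effect and interaction contrasts for the target genes
#'
#' For every target gene and every named effect (breed, status, diet and
#' the three two-way interactions) builds the corresponding contrast over
#' the gene's eight cell means and tests it.  With `normalize = TRUE`
#' (reference-anchored normalisation) the same contrast averaged over the
#' reference genes is subtracted, so the standard error reflects the
#' combined weight vector; with `normalize = FALSE` only the shared
#' sample random effect absorbs sample-level variation.
#'
#' @param fit `qpcr_fit` covering targets and references on the full
#'   eight-cell design.
#' @param targets Character vector of target genes.
#' @param references Character vector of reference genes (disjoint from
#'   targets); required when `normalize` is on.
#' @param normalize Logical; subtract the reference-gene contrast.
#' @param effects Named list of cell contrasts, default
#'   [effect_contrasts()].
#' @return data.frame with one row per gene and effect: `gene`, `effect`,
#'   `diff`, `se`, `df`, `t_stat`, `p_nominal`.
#' @export
run_all_contrasts <- function(fit, targets, references = character(0),
                              normalize = TRUE, effects = effect_contrasts()) {
  if (normalize && length(references) == 0)
    stop("reference gene set must not be empty when normalize = TRUE")
  if (length(intersect(targets, references)) > 0)
    stop("targets and references must be disjoint")
  absent <- setdiff(c(targets, if (normalize) references), fit$genes)
  if (length(absent) > 0)
    stop("gene(s) not in the fit: ", paste(absent, collapse = ", "))
  cells <- treatment_cells()$cell
  if (!all(cells %in% fit$cells))
    stop("fit does not cover the full eight-cell design")
  out <- vector("list", length(targets) * length(effects))
  k <- 1
  for (g in targets) {
    for (eff in names(effects)) {
      w_cell <- effects[[eff]]
      w <- setNames(as.numeric(w_cell), paste(g, names(w_cell), sep = "|"))
      if (normalize) {
        for (r in references) {
          w_ref <- setNames(-as.numeric(w_cell) / length(references),
                            paste(r, names(w_cell), sep = "|"))
          w <- c(w, w_ref)
        }
      }
      row <- estimate_contrast(fit, w, name = eff)
      out[[k]] <- data.frame(gene = g, effect = eff, diff = row$diff,
                             se = row$se, df = row$df, t_stat = row$t_stat,
                             p_nominal = row$p_nominal)
      k <- k + 1
    }
  }
  do.call(rbind, out)
}

#' Back-transform contrasts to fold changes with asymmetric intervals
#'
#' Applies `FC = 2^-diff`, `SE(FC) = 2^-se`, and the asymmetric 95%
#' interval `[2^-(diff + t(df, .975) se), 2^-(diff - t(df, .975) se)]`.
#' The geometric mean of the bounds equals the fold change, and a fold
#' change above 1 means higher expression in the first-named class
#' (Iberian, fed, HO).
#'
#' @param contrasts data.frame with `diff`, `se`, `df` columns (e.g.
#'   from [run_all_contrasts()]).
#' @param level Confidence level (default 0.95).
#' @return The input with `fc`, `se_fc`, `ci_low`, `ci_high` appended.
#' @export
to_fold_change <- function(contrasts, level = 0.95) {
  if (any(contrasts$se <= 0)) stop("standard errors must be positive")
  if (any(contrasts$df <= 0)) stop("degrees of freedom must be positive")
  tq <- qt(1 - (1 - level) / 2, df = contrasts$df)
  contrasts$fc <- 2^(-contrasts$diff)
  contrasts$se_fc <- 2^(-contrasts$se)
  contrasts$ci_low <- 2^(-(contrasts$diff + tq * contrasts$se))
  contrasts$ci_high <- 2^(-(contrasts$diff - tq * contrasts$se))
  contrasts
}

#' Effective number of independent tests
#'
#' Eigenvalue-dispersion estimate from the inter-gene correlation
#' matrix: `m_eff = 1 + (M - 1) (1 - Var(lambda) / M)`, with the
#' eigenvalue variance using denominator `M - 1`; the result is clipped
#' to `[1, M]`.  Identity correlation gives `m_eff = M`; a rank-one
#' (all-correlated) matrix gives 1.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @return Effective number of tests (scalar).
#' @export
effective_tests <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || any(abs(corr - t(corr)) > 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal")
  if (any(corr < -1 - 1e-8 | corr > 1 + 1e-8))
    stop("correlations must lie in [-1, 1]")
  M <- nrow(corr)
  if (M == 1) return(1)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  m_eff <- 1 + (M - 1) * (1 - stats::var(lambda) / M)
  min(max(m_eff, 1), M)
}

#' Benjamini--Hochberg step-up with an effective test count
#'
#' Standard BH step-up with the multiplier `m_eff` replacing the number
#' of tests while the observed ranks are kept: sort ascending, set
#' `q_(i) = m_eff p_(i) / i`, enforce monotonicity from the largest rank
#' down, clip at 1, and return in the original order.
#'
#' @param p Nominal p-values in `[0, 1]`.
#' @param m_eff Effective number of tests (>= 1).
#' @return Adjusted p-values, same order as `p`.
#' @export
adjust_pvalues <- function(p, m_eff) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m_eff < 1) stop("m_eff must be at least 1")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  q <- m_eff * p[o] / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(pmax(q, p[o]), 1)  # an adjusted p never undercuts the nominal p
  q[order(o)]
}

#' Inter-gene correlation matrix of normalised expression
#'
#' Collapses wells to per-sample gene means, subtracts the per-sample
#' mean of the reference genes (removing sample loading), and computes
#' Pearson correlations between target genes across samples.  Feeds
#' [effective_tests()].
#'
#' @param transformed data.frame of transformed wells.
#' @param targets Target gene set.
#' @param references Reference gene set used for per-sample anchoring
#'   (may be empty, in which case raw per-sample means are correlated).
#' @return Symmetric correlation matrix over `targets`.
#' @export
correlation_matrix <- function(transformed, targets, references = character(0)) {
  m <- sample_gene_matrix(transformed)
  if (ncol(m) < 3) stop("at least 3 samples are required")
  expr <- m[targets, , drop = FALSE]
  const <- apply(expr, 1, function(z) stats::sd(z) < 1e-12)
  if (length(references) > 0)
    expr <- sweep(expr, 2, colMeans(m[references, , drop = FALSE]))
  corr <- diag(length(targets))
  dimnames(corr) <- list(targets, targets)
  ok <- !const
  if (any(const))
    warning("gene(s) constant across samples, correlations set to 0: ",
            paste(targets[const], collapse = ", "))
  if (sum(ok) >= 2)
    corr[ok, ok] <- stats::cor(t(expr[ok, , drop = FALSE]))
  diag(corr) <- 1
  corr
}

#' Full relative-quantification analysis
#'
#' Orchestrates the expression pipeline: efficiency-adjusted
#' transformation, joint mixed-model fit, all main and interaction
#' contrasts per target gene, fold-change back-transformation with
#' asymmetric intervals, and per-effect-family multiplicity adjustment
#' using the effective number of tests.
#'
#' @param wells data.frame of well measurements.
#' @param efficiencies Named amplification factors.
#' @param targets Target genes (default: all genes except `references`).
#' @param references Reference genes (default `ACTB`, `PPIA`).
#' @param normalize Reference-anchored normalisation (default TRUE).
#' @param level Confidence level for the fold-change intervals.
#' @return List with `results` (data.frame: gene, effect, fold change,
#'   interval, p-values), `fit`, `m_eff`, and `correlation`.
#' @export
qpcr_analysis <- function(wells, efficiencies, targets = NULL,
                          references = c("ACTB", "PPIA"),
                          normalize = TRUE, level = 0.95) {
  transformed <- transform_wells(wells, efficiencies)
  if (is.null(targets))
    targets <- setdiff(sort(unique(transformed$gene)), references)
  fit <- fit_expression_model(transformed)
  res <- run_all_contrasts(fit, targets, references, normalize = normalize)
  res <- to_fold_change(res, level = level)
  corr <- correlation_matrix(transformed, targets, references)
  m_eff <- effective_tests(corr)
  res$p_adjusted <- NA_real_
  for (eff in unique(res$effect)) {
    sel <- res$effect == eff
    res$p_adjusted[sel] <- adjust_pvalues(res$p_nominal[sel], m_eff)
  }
  cols <- c("gene", "effect", "fc", "ci_low", "ci_high", "p_nominal",
            "p_adjusted", "diff", "se", "df", "t_stat", "se_fc")
  list(results = res[cols], fit = fit, m_eff = m_eff, correlation = corr)
}
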