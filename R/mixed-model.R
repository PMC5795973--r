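#' Build design matrices for the joint expression model
#'
#' Constructs the response vector, the gene-by-treatment-cell fixed
#' design (cell-mean coding, one column per gene:cell combination) and
#' the random-effect grouping factors of the joint model: plate within
#' gene, box within gene, animal within gene, and the biopsy sample
#' (animal crossed with status) shared across genes.
#'
#' @param transformed data.frame of transformed wells (see
#'   [transform_wells()]).
#' @return List with `y`, `X` (dense model matrix with `gene|cell`
#'   column names), `groupings` (named list of factors), and `index`
#'   (data.frame mapping fixed-effect columns to gene and cell).
#' @export
expression_model_matrices <- function(transformed) {
  d <- transformed
  d$cell <- paste(d$breed, d$diet, d$status, sep = ".")
  genes <- sort(unique(d$gene))
  cells_present <- sort(unique(d$cell))
  gc <- factor(paste(d$gene, d$cell, sep = "|"),
               levels = as.vector(outer(genes, cells_present,
                                        function(g, c) paste(g, c, sep = "|"))))
  empty <- levels(gc)[tabulate(gc, nbins = nlevels(gc)) == 0]
  if (length(empty) > 0)
    stop("fixed design is rank deficient; empty gene:cell combination(s): ",
         paste(empty, collapse = ", "))
  X <- model.matrix(~ 0 + gc)
  colnames(X) <- levels(gc)
  index <- data.frame(
    gene = sub("\\|.*$", "", levels(gc)),
    cell = sub("^.*\\|", "", levels(gc)))
  groupings <- list(
    "gene:plate"  = factor(paste(d$gene, d$plate, sep = "|")),
    "gene:box"    = factor(paste(d$gene, d$box, sep = "|")),
    "gene:animal" = factor(paste(d$gene, d$animal, sep = "|")),
    "sample"      = factor(paste(d$animal, d$status, sep = "|")))
  list(y = d$y, X = X, groupings = groupings, index = index)
}

#' Fit the joint expression mixed model by REML
#'
#' Fits `y = TG(gene, cell) + plate(gene) + box(gene) + animal(gene) +
#' sample + e` with independent homoscedastic random components (one
#' variance per grouping, shared across genes) by REML via
#' [lmerTest::lmer()], giving Satterthwaite denominator degrees of
#' freedom for contrasts.  Random groupings with a single observed level
#' are dropped (their variance is reported as 0).  Variance components
#' whose unconstrained optimum is negative are pinned at 0 by the
#' optimiser's boundary.
#'
#' @inheritParams expression_model_matrices
#' @return Object of class `qpcr_fit`: list with `model` (the lmerTest
#'   fit), `beta` (named fixed-effect estimates, `gene|cell`), `cov_beta`,
#'   `vc` (named variance components incl. `residual`), `reml_loglik`,
#'   `index`, `n_obs`, `n_params`, `genes`, `cells`, `dropped` (random
#'   terms dropped for having one level).
#' @export
fit_expression_model <- function(transformed) {
  mm <- expression_model_matrices(transformed)
  d <- transformed
  d$gc <- factor(paste(d$gene, paste(d$breed, d$diet, d$status, sep = "."),
                       sep = "|"), levels = colnames(mm$X))
  for (nm in names(mm$groupings)) d[[make.names(nm)]] <- mm$groupings[[nm]]
  terms_all <- setNames(make.names(names(mm$groupings)), names(mm$groupings))
  keep <- vapply(mm$groupings, function(f) nlevels(droplevels(f)) > 1, logical(1))
  re_terms <- paste0("(1 | ", terms_all[keep], ")")
  if (length(re_terms) == 0)
    stop("no random grouping has more than one level; use a fixed-effects model")
  form <- as.formula(paste("y ~ 0 + gc +", paste(re_terms, collapse = " + ")))
  fit <- lmerTest::lmer(form, data = d, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  vc <- setNames(numeric(length(terms_all) + 1),
                 c(names(terms_all), "residual"))
  for (nm in names(terms_all)) {
    row <- vc_tab$grp == terms_all[[nm]]
    if (any(row)) vc[nm] <- vc_tab$vcov[row]
  }
  vc["residual"] <- vc_tab$vcov[vc_tab$grp == "Residual"]
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^gc", "", names(beta))
  cov_beta <- as.matrix(stats::vcov(fit))
  dimnames(cov_beta) <- list(names(beta), names(beta))
  structure(list(
    model = fit,
    beta = beta,
    cov_beta = cov_beta,
    vc = vc,
    reml_loglik = as.numeric(stats::logLik(fit)),
    index = mm$index,
    n_obs = nrow(d),
    n_params = length(beta),
    genes = sort(unique(d$gene)),
    cells = sort(unique(mm$index$cell)),
    dropped = names(terms_all)[!keep]), class = "qpcr_fit")
}

#' @export
print.qpcr_fit <- function(x, ...) {
  cat("Joint expression mixed-model fit (REML)\n")
  cat("  observations:", x$n_obs, " fixed effects:", x$n_params, "\n")
  cat("  genes:", length(x$genes), " cells:", length(x$cells), "\n")
  cat("  restricted log-likelihood:", format(x$reml_loglik), "\n")
  cat("  variance components:\n")
  print(round(x$vc, 6))
  invisible(x)
}

#' Estimate a contrast of fixed-effect cell means
#'
#' Computes `diff = w' beta` with its standard error from the
#' fixed-effect covariance, Satterthwaite denominator degrees of
#' freedom, and a two-sided t test.
#'
#' @param fit `qpcr_fit` object.
#' @param weights Numeric contrast vector summing to zero; either
#'   full-length in the order of `fit$beta`, or named by `gene|cell`
#'   (missing entries are 0).
#' @param name Label for the contrast.
#' @return One-row data.frame: `name`, `diff`, `se`, `df`, `t_stat`,
#'   `p_nominal`.
#' @export
estimate_contrast <- function(fit, weights, name = "contrast") {
  w <- numeric(length(fit$beta))
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), names(fit$beta))
    if (length(unknown) > 0)
      stop("unknown fixed-effect name(s) in weights: ",
           paste(unknown, collapse = ", "))
    w[match(names(weights), names(fit$beta))] <- weights
  } else {
    if (length(weights) != length(fit$beta))
      stop("unnamed weights must match the number of fixed effects")
    w <- as.numeric(weights)
  }
  if (all(w == 0)) stop("contrast weights are all zero")
  if (abs(sum(w)) > 1e-8) stop("contrast weights must sum to zero")
  ct <- lmerTest::contest(fit$model, matrix(w, nrow = 1), joint = FALSE,
                          confint = FALSE)
  data.frame(name = name,
             diff = ct[["Estimate"]],
             se = ct[["Std. Error"]],
             df = ct[["df"]],
             t_stat = ct[["t value"]],
             p_nominal = ct[["Pr(>|t|)"]])
}

#' Exact restricted log-likelihood at given variance components
#'
#' Evaluates the restricted (REML) log-likelihood of a variance-component
#' model `V = sum_q s2_q Z_q Z_q' + s2_e I` for candidate components,
#' independently of any optimiser:
#' `l_R = -1/2 [ (n-p) log 2*pi + log|V| + log|X'V^-1 X| + r'V^-1 r ]`
#' with `r` the generalised-least-squares residual.  Exposed so tests
#' can audit a fitted optimum by grid search.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (full column rank).
#' @param groupings Named list of factors (one per random grouping).
#' @param vc Named non-negative variances: one entry per grouping name
#'   plus `residual`.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, groupings, vc) {
  if (any(vc < 0)) stop("variance components must be non-negative")
  if (!("residual" %in% names(vc))) stop("vc must include 'residual'")
  miss <- setdiff(names(groupings), names(vc))
  if (length(miss) > 0) stop("vc missing component(s): ", paste(miss, collapse = ", "))
  n <- length(y); p <- ncol(X)
  V <- Matrix::Diagonal(n, vc[["residual"]])
  for (nm in names(groupings)) {
    Z <- Matrix::sparse.model.matrix(~ 0 + f, data.frame(f = groupings[[nm]]))
    V <- V + vc[[nm]] * Matrix::tcrossprod(Z)
  }
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(V)),
                 error = function(e) stop("singular marginal covariance"))
  ldV <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
  Vi_X <- Matrix::solve(V, X)
  XtViX <- as.matrix(Matrix::crossprod(X, Vi_X))
  beta <- solve(XtViX, as.matrix(Matrix::crossprod(Vi_X, y)))
  r <- y - X %*% beta
  q <- as.numeric(Matrix::crossprod(r, Matrix::solve(V, r)))
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + ldV +
                       determinant(XtViX)$modulus + q))
}

#' Generalised-least-squares fixed effects at given variance components
#'
#' Solves the mixed-model equations for the fixed effects at fixed
#' variance components, the companion of [reml_loglik()] for auditing a
#' fitted optimum.
#'
#' @inheritParams reml_loglik
#' @return Named numeric vector of fixed-effect estimates.
#' @export
gls_beta <- function(y, X, groupings, vc) {
  n <- length(y)
  V <- Matrix::Diagonal(n, vc[["residual"]])
  for (nm in names(groupings)) {
    Z <- Matrix::sparse.model.matrix(~ 0 + f, data.frame(f = groupings[[nm]]))
    V <- V + vc[[nm]] * Matrix::tcrossprod(Z)
  }
  Vi_X <- Matrix::solve(V, X)
  XtViX <- as.matrix(Matrix::crossprod(X, Vi_X))
  beta <- solve(XtViX, as.matrix(Matrix::crossprod(Vi_X, y)))
  setNames(as.numeric(beta), colnames(X))
}

#' Brute-force REML maximisation by grid search plus polish
#'
#' Audits an optimiser's solution independently: evaluates
#' [reml_loglik()] over a multiplicative grid of candidate variance
#' components (including 0 for the non-residual components) and polishes
#' the best grid point with Nelder--Mead on the log-variance scale.
#' Intended for small instances (tens of observations).
#'
#' @inheritParams reml_loglik
#' @param anchor Named positive variances used to centre the grid
#'   (e.g. a moment estimate or the variance of `y`).
#' @param grid_mult Multiplicative grid offsets applied to `anchor`.
#' @return List with `vc` (best components found) and `loglik`.
#' @export
reml_brute_force <- function(y, X, groupings, anchor = NULL,
                             grid_mult = c(0.05, 0.25, 1, 4)) {
  comps <- c(names(groupings), "residual")
  if (is.null(anchor))
    anchor <- setNames(rep(stats::var(y), length(comps)), comps)
  grids <- lapply(comps, function(nm) {
    g <- anchor[[nm]] * grid_mult
    if (nm != "residual") g <- c(0, g)
    g
  })
  combos <- do.call(expand.grid, setNames(grids, comps))
  best <- -Inf; best_vc <- NULL
  for (i in seq_len(nrow(combos))) {
    vc <- setNames(as.numeric(combos[i, ]), comps)
    ll <- tryCatch(reml_loglik(y, X, groupings, vc), error = function(e) -Inf)
    if (ll > best) { best <- ll; best_vc <- vc }
  }
  # polish on log scale; zeroed components enter at a small floor
  floor_v <- max(best_vc["residual"] * 1e-8, 1e-12)
  start <- log(pmax(best_vc, floor_v))
  obj <- function(lv) {
    vc <- setNames(exp(lv), comps)
    -tryCatch(reml_loglik(y, X, groupings, vc), error = function(e) -Inf)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  vc_pol <- setNames(exp(opt$par), comps)
  # snap tiny components to the boundary and re-evaluate
  vc_snap <- ifelse(vc_pol < floor_v * 10 & comps != "residual", 0, vc_pol)
  names(vc_snap) <- comps
  ll_snap <- tryCatch(reml_loglik(y, X, groupings, vc_snap),
                      error = function(e) -Inf)
  if (-opt$value >= best) { best <- -opt$value; best_vc <- vc_pol }
  if (ll_snap >= best) { best <- ll_snap; best_vc <- vc_snap }
  list(vc = best_vc, loglik = best)
}
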