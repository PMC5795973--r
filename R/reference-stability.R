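#' Per-sample expression matrix for stability analysis
#'
#' Collapses technical replicates to one mean transformed value per gene
#' and biopsy sample (animal crossed with feeding status).  Stability of
#' candidate normalisers concerns biological samples, so wells are
#' averaged first.
#'
#' @param transformed data.frame of transformed wells (needs `gene`,
#'   `animal`, `status`, `y`).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
sample_gene_matrix <- function(transformed) {
  sample_id <- paste(transformed$animal, transformed$status, sep = ":")
  m <- tapply(transformed$y, list(transformed$gene, sample_id), mean)
  m[order(rownames(m)), , drop = FALSE]
}

#' geNorm expression-stability measure M
#'
#' For each candidate gene j, `M_j` is the mean over all other candidates
#' k of the standard deviation across samples of the pairwise difference
#' `y_j - y_k` (equivalently the SD of the log2 expression ratio).  Lower
#' M means more stable expression; M is invariant to per-gene additive
#' shifts.
#'
#' @param y_matrix Genes-by-samples matrix of per-sample mean transformed
#'   values (at least 3 genes and 2 samples).
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(y_matrix) {
  y_matrix <- as.matrix(y_matrix)
  if (nrow(y_matrix) < 3)
    stop("geNorm requires at least 3 candidate genes")
  if (ncol(y_matrix) < 2)
    stop("geNorm requires at least 2 samples")
  g <- nrow(y_matrix)
  m <- numeric(g)
  for (j in seq_len(g)) {
    others <- setdiff(seq_len(g), j)
    m[j] <- mean(vapply(others, function(k)
      stats::sd(y_matrix[j, ] - y_matrix[k, ]), numeric(1)))
  }
  setNames(m, rownames(y_matrix))
}

#' geNorm stepwise exclusion ranking
#'
#' Iteratively removes the gene with the largest M (recomputing M on the
#' remaining candidates) until two genes remain.  Ties are broken by
#' lexicographic gene identifier, the later name being excluded first.
#'
#' @inheritParams genorm_m
#' @return data.frame with `gene`, `rank` (1 = most stable; the final
#'   pair shares ranks 1 and 2 by identifier), `m_at_exclusion` (the M
#'   value at the step the gene was excluded; for the final pair, their
#'   common pairwise M).
#' @export
genorm_rank <- function(y_matrix) {
  y_matrix <- as.matrix(y_matrix)
  m_full <- genorm_m(y_matrix)  # validates dimensions
  remaining <- rownames(y_matrix)
  out <- data.frame(gene = character(0), rank = integer(0),
                    m_at_exclusion = numeric(0))
  rank_next <- length(remaining)
  while (length(remaining) > 2) {
    m <- genorm_m(y_matrix[remaining, , drop = FALSE])
    # worst M; lexicographically later identifier excluded on ties
    worst <- max(m)
    cand <- sort(names(m)[m >= worst - 1e-12])
    drop_gene <- cand[length(cand)]
    out <- rbind(out, data.frame(gene = drop_gene, rank = rank_next,
                                 m_at_exclusion = m[[drop_gene]]))
    remaining <- setdiff(remaining, drop_gene)
    rank_next <- rank_next - 1L
  }
  pair_m <- stats::sd(y_matrix[remaining[1], ] - y_matrix[remaining[2], ])
  final <- sort(remaining)
  out <- rbind(data.frame(gene = final, rank = c(1L, 2L),
                          m_at_exclusion = pair_m), out)
  rownames(out) <- NULL
  out[order(out$rank), ]
}

#' NormFinder-style model-based stability value
#'
#' Each sample is centred by its across-gene mean (removing sample
#' loading).  For gene g and sample group j the group deviation `d_gj`
#' (group mean of centred values minus the gene's overall centred mean)
#' and the within-group variance `s2_gj` (denominator `n_j - 1`) are
#' combined as `sqrt(d_gj^2 + s2_gj / n_j)` and averaged over groups: a
#' bias--variance combination penalising both systematic group shifts
#' and sampling noise.  With a single group the measure is the SD of the
#' gene's centred values.
#'
#' @inheritParams genorm_m
#' @param groups Group label per sample (length `ncol(y_matrix)`), e.g.
#'   breed, status, or their crossing; every group needs at least 2
#'   samples.
#' @return Named numeric vector of stability values (lower = more stable).
#' @export
normfinder_stability <- function(y_matrix, groups) {
  y_matrix <- as.matrix(y_matrix)
  if (nrow(y_matrix) < 2) stop("NormFinder requires at least 2 genes")
  groups <- as.character(groups)
  if (length(groups) != ncol(y_matrix))
    stop("groups must have one label per sample")
  n_per <- table(groups)
  if (any(n_per < 2))
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  centred <- sweep(y_matrix, 2, colMeans(y_matrix))
  if (length(n_per) == 1L)
    return(apply(centred, 1, stats::sd))
  vals <- apply(centred, 1, function(z) {
    overall <- mean(z)
    per_group <- vapply(names(n_per), function(g) {
      zg <- z[groups == g]
      d <- mean(zg) - overall
      sqrt(d^2 + stats::var(zg) / length(zg))
    }, numeric(1))
    mean(per_group)
  })
  setNames(vals, rownames(y_matrix))
}

#' Combined stability report for candidate reference genes
#'
#' Runs the geNorm exclusion ranking and the NormFinder stability measure
#' on the same per-sample matrix and combines both ranks.
#'
#' @inheritParams normfinder_stability
#' @return data.frame with one row per candidate: `gene`, `genorm_m`
#'   (full-panel M), `genorm_rank`, `normfinder_stability`,
#'   `normfinder_rank`, `combined_rank` (mean of the two ranks).
#' @export
stability_report <- function(y_matrix, groups) {
  y_matrix <- as.matrix(y_matrix)
  gm <- genorm_m(y_matrix)
  gr <- genorm_rank(y_matrix)
  nf <- normfinder_stability(y_matrix, groups)
  genes <- sort(rownames(y_matrix))
  nf_rank <- rank(nf[genes], ties.method = "first")
  out <- data.frame(
    gene = genes,
    genorm_m = unname(gm[genes]),
    genorm_rank = gr$rank[match(genes, gr$gene)],
    normfinder_stability = unname(nf[genes]),
    normfinder_rank = as.integer(nf_rank))
  out$combined_rank <- (out$genorm_rank + out$normfinder_rank) / 2
  out[order(out$combined_rank, out$gene), ]
}

#' Select the normalisation gene set
#'
#' Picks the `n` candidates with the best (lowest) combined rank; ties
#' are broken by gene identifier.
#'
#' @param report data.frame from [stability_report()].
#' @param n Number of reference genes to select (the motivating study
#'   used 2).
#' @return Character vector of selected gene identifiers.
#' @export
select_references <- function(report, n = 2) {
  if (n < 1) stop("n must be at least 1")
  if (n > nrow(report))
    stop("n exceeds the number of candidate genes (", nrow(report), ")")
  report <- report[order(report$combined_rank, report$gene), ]
  report$gene[seq_len(n)]
}
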