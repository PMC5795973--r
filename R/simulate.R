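#' Animal layout emulating the study design
#'
#' 30 Iberian and 19 Duroc males; diets assigned as in the trial (17/13
#' Iberian and 10/9 Duroc on HO/CH), housing boxes allocated round-robin
#' within each breed-by-diet cell, and 19 litters split between the
#' breeds (10 Iberian, 9 Duroc) allocated round-robin within breed.
#'
#' @param n_iberian,n_duroc Animals per breed.
#' @param boxes_per_cell Housing boxes per breed-by-diet cell.
#' @param n_litters Total number of litters across both breeds.
#' @return data.frame with `animal`, `breed`, `diet`, `box`, `litter`.
#' @export
study_animals <- function(n_iberian = 30, n_duroc = 19, boxes_per_cell = 2,
                          n_litters = 19) {
  breed <- rep(c("Iberian", "Duroc"), c(n_iberian, n_duroc))
  diet <- c(rep(c("HO", "CH"), c(ceiling(n_iberian * 17 / 30),
                                 n_iberian - ceiling(n_iberian * 17 / 30))),
            rep(c("HO", "CH"), c(ceiling(n_duroc * 10 / 19),
                                 n_duroc - ceiling(n_duroc * 10 / 19))))
  d <- data.frame(animal = sprintf("A%02d", seq_along(breed)),
                  breed = breed, diet = diet)
  d$box <- NA_character_
  for (cell in split(seq_len(nrow(d)), paste(d$breed, d$diet))) {
    lab <- paste0("box_", d$breed[cell[1]], "_", d$diet[cell[1]], "_")
    d$box[cell] <- paste0(lab, rep_len(seq_len(boxes_per_cell), length(cell)))
  }
  n_lit_ib <- round(n_litters * n_iberian / (n_iberian + n_duroc))
  lit_pool <- list(Iberian = sprintf("L%02d", seq_len(n_lit_ib)),
                   Duroc = sprintf("L%02d", n_lit_ib + seq_len(n_litters - n_lit_ib)))
  d$litter <- NA_character_
  for (b in names(lit_pool)) {
    idx <- which(d$breed == b)
    d$litter[idx] <- rep_len(lit_pool[[b]], length(idx))
  }
  d
}

#' Configuration for the qPCR simulator
#'
#' Defines the generative version of the joint expression model: true
#' cell means per gene (log2 units), the five variance components, the
#' per-gene amplification factors used to invert the Cp transformation,
#' and the design layout.  Defaults mirror the study: 49 animals, both
#' feeding statuses biopsied per animal, the 15-gene panel with the
#' trial's amplification efficiencies, triplicate wells, and
#' gene-balanced plates of about 4 animals (both statuses) assigned
#' stratified across treatment cells.
#'
#' @param animals data.frame from [study_animals()].
#' @param genes Gene identifiers; defaults to the study panel.
#' @param efficiencies Named amplification factors for `genes`.
#' @param cell_means Genes-by-cells matrix of true values (log2 units);
#'   default a flat baseline of 25 for every gene and cell (Cp around
#'   26-29 cycles depending on efficiency).
#' @param vc Named variance components `plate`, `box`, `animal`,
#'   `sample`, `residual` (squared log2 units).  Defaults reflect
#'   typical qPCR magnitudes: well replicate SD 0.14, plate SD 0.2,
#'   box SD 0.07, animal SD 0.22, sample/RT SD 0.28.
#' @param replicates Technical replicates per sample and gene.
#' @param animals_per_plate Animals (both statuses) per qPCR plate.
#' @param seed Integer seed; the simulator is deterministic given it.
#' @return List of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(animals = study_animals(),
                            genes = names(study_efficiencies()),
                            efficiencies = study_efficiencies(),
                            cell_means = NULL,
                            vc = c(plate = 0.04, box = 0.005, animal = 0.05,
                                   sample = 0.08, residual = 0.02),
                            replicates = 3, animals_per_plate = 4,
                            seed = 1) {
  if (any(vc < 0)) stop("variances must be non-negative")
  miss <- setdiff(genes, names(efficiencies))
  if (length(miss) > 0) stop("efficiency missing for: ", paste(miss, collapse = ", "))
  if (any(efficiencies[genes] <= 1))
    stop("amplification factor must exceed 1 (non-amplifying reaction)")
  cells <- treatment_cells()$cell
  if (is.null(cell_means)) {
    cell_means <- matrix(25, nrow = length(genes), ncol = length(cells),
                         dimnames = list(genes, cells))
  }
  stopifnot(all(rownames(cell_means) == genes), all(colnames(cell_means) == cells))
  structure(list(animals = animals, genes = genes,
                 efficiencies = efficiencies[genes], cell_means = cell_means,
                 vc = vc, replicates = replicates,
                 animals_per_plate = animals_per_plate, seed = seed),
            class = "qpcr_sim_config")
}

#' Inject a treatment effect into a simulator configuration
#'
#' Adds the pattern `w * diff / sum(w^2)` of the named effect contrast to
#' one gene's cell means so that the contrast evaluates exactly to
#' `diff` (log2 units; `diff = -log2(FC)` gives fold change FC in favour
#' of the first-named class).
#'
#' @param cfg `qpcr_sim_config`.
#' @param gene Gene to modify.
#' @param effect Effect name (one of `names(effect_contrasts())`).
#' @param diff True contrast value on the transformed scale.
#' @return The modified configuration.
#' @export
inject_effect <- function(cfg, gene, effect, diff) {
  w <- effect_contrasts()[[effect]]
  if (is.null(w)) stop("unknown effect: ", effect)
  if (!(gene %in% rownames(cfg$cell_means))) stop("unknown gene: ", gene)
  cfg$cell_means[gene, names(w)] <-
    cfg$cell_means[gene, names(w)] + w * diff / sum(w^2)
  cfg
}

#' Simulate a qPCR well table from the generative joint model
#'
#' Draws every random component (gene-specific plate, box and animal
#' effects, the shared sample effect, and the well residual) from
#' zero-mean normals with the configured variances, forms the
#' transformed value `y`, and inverts the efficiency-adjusted
#' transformation to `Cp = y / log2(E_g)`.  Identical seeds give
#' identical tables.
#'
#' @param cfg `qpcr_sim_config`.
#' @return List with `wells` (simulated well table), `truth` (the
#'   configuration's cell means and variance components), and
#'   `efficiencies`.
#' @export
simulate_qpcr <- function(cfg) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  set.seed(cfg$seed)
  an <- cfg$animals
  # stratified plate assignment: interleave animals across cells, chunk
  cell_of <- paste(an$breed, an$diet)
  order_interleaved <- order(stats::ave(seq_len(nrow(an)), cell_of,
                                        FUN = seq_along), cell_of)
  an <- an[order_interleaved, ]
  an$plate <- paste0("P", sprintf("%02d", (seq_len(nrow(an)) - 1) %/%
                                    cfg$animals_per_plate + 1))
  samples <- merge(an, data.frame(status = .statuses), by = NULL)
  samples$sample <- paste(samples$animal, samples$status, sep = "|")
  samples$cell <- paste(samples$breed, samples$diet, samples$status, sep = ".")
  genes <- cfg$genes
  draw <- function(levels, sd) setNames(stats::rnorm(length(levels), 0, sd), levels)
  lv <- function(a, b) as.vector(outer(genes, unique(b), paste, sep = "|"))
  eff_plate <- draw(lv(genes, an$plate), sqrt(cfg$vc[["plate"]]))
  eff_box <- draw(lv(genes, an$box), sqrt(cfg$vc[["box"]]))
  eff_animal <- draw(lv(genes, an$animal), sqrt(cfg$vc[["animal"]]))
  eff_sample <- draw(unique(samples$sample), sqrt(cfg$vc[["sample"]]))
  grid <- merge(samples, data.frame(gene = genes), by = NULL)
  grid <- grid[rep(seq_len(nrow(grid)), each = cfg$replicates), ]
  grid$replicate <- rep_len(seq_len(cfg$replicates), nrow(grid))
  gk <- function(g, x) paste(g, x, sep = "|")
  y <- cfg$cell_means[cbind(grid$gene, grid$cell)] +
    eff_plate[gk(grid$gene, grid$plate)] +
    eff_box[gk(grid$gene, grid$box)] +
    eff_animal[gk(grid$gene, grid$animal)] +
    eff_sample[grid$sample] +
    stats::rnorm(nrow(grid), 0, sqrt(cfg$vc[["residual"]]))
  wells <- data.frame(gene = grid$gene, animal = grid$animal,
                      breed = grid$breed, diet = grid$diet,
                      status = grid$status, plate = grid$plate,
                      box = grid$box, replicate = grid$replicate,
                      cp = unname(y / log2(cfg$efficiencies[grid$gene])))
  rownames(wells) <- NULL
  list(wells = wells,
       truth = list(cell_means = cfg$cell_means, vc = cfg$vc, seed = cfg$seed),
       efficiencies = cfg$efficiencies)
}

#' Breed-by-diet cell mean fatty-acid vectors for a depot
#'
#' Combines the published marginal LS means additively,
#' `cell(breed, diet) = m_breed + m_diet - mean(m_CH, m_HO)`, clipped at
#' 0, so the breed marginals reproduce the printed breed columns
#' exactly.  An unreported `other` component absorbs `100 - sum` so the
#' vectors close to 100 while keeping the printed values.
#'
#' @param depot `"backfat"` or `"ham"`.
#' @return Matrix with one row per breed-by-diet cell (`Iberian.HO`,
#'   ...), columns the canonical fatty acids plus `other`.
#' @export
fa_cell_means <- function(depot = c("backfat", "ham")) {
  tab <- study_fa_lsmeans(depot)
  tab <- tab[tab$type == "fa", ]
  fa <- tab$fatty_acid
  m <- list(CH = tab$mean_CH, HO = tab$mean_HO,
            Duroc = tab$mean_Duroc, Iberian = tab$mean_Iberian)
  diet_centre <- (m$CH + m$HO) / 2
  cells <- expand.grid(diet = .diets, breed = .breeds, stringsAsFactors = FALSE)
  out <- t(apply(cells, 1, function(r)
    pmax(m[[r[["breed"]]]] + m[[r[["diet"]]]] - diet_centre, 0)))
  colnames(out) <- fa
  rownames(out) <- paste(cells$breed, cells$diet, sep = ".")
  other <- pmax(100 - rowSums(out), 0)
  cbind(out, other = other)
}

#' Configuration for the fatty-acid profile simulator
#'
#' @param animals data.frame from [study_animals()].
#' @param depots Depots to simulate (`backfat`, `ham`).
#' @param layers Fat layers per depot.
#' @param cell_means Named list, one matrix per depot as produced by
#'   [fa_cell_means()]; defaults to the study-derived cell means.
#' @param litter_sd,box_sd,residual_sd Log-scale (multiplicative)
#'   standard deviations of the litter, box and per-sample noise.
#'   Defaults (0.03/0.02/0.05) reproduce between-animal SDs of about 1
#'   percentage point on a 20% fatty acid, in line with the published
#'   SEMs.
#' @param seed Integer seed.
#' @return List of class `fa_sim_config`.
#' @export
fa_sim_config <- function(animals = study_animals(),
                          depots = c("backfat", "ham"),
                          layers = c("inner", "outer"),
                          cell_means = NULL,
                          litter_sd = 0.03, box_sd = 0.02, residual_sd = 0.05,
                          seed = 1) {
  if (is.null(cell_means))
    cell_means <- setNames(lapply(depots, fa_cell_means), depots)
  stopifnot(all(depots %in% names(cell_means)))
  if (any(c(litter_sd, box_sd, residual_sd) < 0)) stop("SDs must be non-negative")
  structure(list(animals = animals, depots = depots, layers = layers,
                 cell_means = cell_means, litter_sd = litter_sd,
                 box_sd = box_sd, residual_sd = residual_sd, seed = seed),
            class = "fa_sim_config")
}

#' Simulate fatty-acid profiles on the centred log-ratio scale
#'
#' For each animal, depot and layer the breed-by-diet cell mean vector
#' is perturbed multiplicatively, `x = m * exp(litter + box + residual)`
#' with independent per-fatty-acid normal draws, and closed to 100%.
#' Zero entries of the mean vector stay exactly 0 (no mass is created).
#' Litter and box effects are shared across depots and layers of the
#' same animal; identical seeds give identical tables.
#'
#' @param cfg `fa_sim_config`.
#' @return data.frame of fatty-acid profiles (one row per animal, depot
#'   and layer) with identifier columns plus the fatty-acid percentages
#'   and the `other` filler.
#' @export
simulate_fa <- function(cfg) {
  stopifnot(inherits(cfg, "fa_sim_config"))
  set.seed(cfg$seed + 1L)  # stream separate from the qPCR simulator
  an <- cfg$animals
  fa_names <- colnames(cfg$cell_means[[cfg$depots[1]]])
  k <- length(fa_names)
  draw_mat <- function(levels, sd) {
    m <- matrix(stats::rnorm(length(levels) * k, 0, sd), nrow = length(levels),
                dimnames = list(levels, fa_names))
    m
  }
  lit_eff <- draw_mat(unique(an$litter), cfg$litter_sd)
  box_eff <- draw_mat(unique(an$box), cfg$box_sd)
  out <- list()
  for (dp in cfg$depots) {
    means <- cfg$cell_means[[dp]]
    for (ly in cfg$layers) {
      eps <- draw_mat(an$animal, cfg$residual_sd)
      m <- means[paste(an$breed, an$diet, sep = "."), , drop = FALSE]
      x <- m * exp(lit_eff[an$litter, , drop = FALSE] +
                     box_eff[an$box, , drop = FALSE] + eps)
      x[m == 0] <- 0
      x <- x * 100 / rowSums(x)
      prof <- data.frame(sample = an$animal, depot = dp, layer = ly,
                         breed = an$breed, diet = an$diet,
                         litter = an$litter, box = an$box,
                         check.names = FALSE)
      prof[fa_names] <- as.data.frame(x, check.names = FALSE)
      out[[length(out) + 1]] <- prof
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
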