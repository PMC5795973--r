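# Shared builders for small deterministic fixtures.

# A reduced animal layout: n_ib + n_du animals, diets balanced enough for
# all eight treatment cells to be filled.
small_animals <- function(n_ib = 8, n_du = 8, boxes_per_cell = 2) {
  study_animals(n_ib, n_du, boxes_per_cell = boxes_per_cell)
}

# A small simulated qPCR dataset with a couple of targets and both
# normalisers; returns the simulate_qpcr() list.
small_qpcr_sim <- function(seed = 1, genes = c("SCD", "LEP", "ACTB", "PPIA"),
                           vc = c(plate = 0.04, box = 0.005, animal = 0.05,
                                  sample = 0.08, residual = 0.02),
                           animals = small_animals(), effects = list()) {
  cfg <- qpcr_sim_config(animals = animals, genes = genes,
                         efficiencies = study_efficiencies()[genes],
                         vc = vc, seed = seed)
  for (e in effects)
    cfg <- inject_effect(cfg, e$gene, e$effect, e$diff)
  simulate_qpcr(cfg)
}

# Deterministic well table, one gene per row group; cp chosen inside (0, 45).
tiny_wells <- function() {
  expand.grid(gene = c("SCD", "ACTB"), animal = c("A1", "A2"),
              status = c("fed", "fasting"), replicate = 1:2,
              stringsAsFactors = FALSE) |>
    within({
      breed <- ifelse(animal == "A1", "Iberian", "Duroc")
      diet <- "HO"
      plate <- "P1"
      box <- "B1"
      cp <- 24 + (gene == "ACTB") * 2 + (animal == "A2") * 0.5
    })
}

# Balanced fatty-acid fixture: two breeds x two diets x two litters x
# 2 animals per cell, deterministic values plus optional noise.
balanced_fa_profiles <- function(seed = 1, resid_sd = 0.3) {
  set.seed(seed)
  grid <- expand.grid(breed = c("Iberian", "Duroc"), diet = c("HO", "CH"),
                      litter = c("L1", "L2"), rep = 1:2,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("S%02d", seq_len(nrow(grid)))
  grid$depot <- "backfat"; grid$layer <- "inner"
  grid$box <- paste0("box_", grid$breed, "_", grid$diet)
  base <- 20 + 2 * (grid$breed == "Iberian") + 3 * (grid$diet == "CH")
  grid$`C16:0` <- base + rnorm(nrow(grid), 0, resid_sd)
  grid$`C18:0` <- 10 + rnorm(nrow(grid), 0, resid_sd)
  grid$`C18:1n-9` <- 45 + rnorm(nrow(grid), 0, resid_sd)
  grid[c("sample", "depot", "layer", "breed", "diet", "litter", "box",
         "C16:0", "C18:0", "C18:1n-9")]
}
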