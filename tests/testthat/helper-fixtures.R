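# Shared fixtures, generated in code. The molecule panel mixes ring and
# acyclic volatiles so scaffold behavior is exercised everywhere.

fixture_smiles <- function() c(
  toluene = "Cc1ccccc1",
  ethylbenzene = "CCc1ccccc1",
  phenethyl_alcohol = "OCCc1ccccc1",
  phenylethyl_acetate = "CC(=O)OCCc1ccccc1",
  furfural = "O=Cc1ccco1",
  pentylfuran = "CCCCCc1ccco1",
  hexanal = "CCCCCC=O",
  ethanol = "CCO",
  ethyl_acetate = "CCOC(C)=O",
  isoamyl_acetate = "CC(C)CCOC(C)=O")

fixture_compound_table <- function() {
  data.frame(
    name = c("toluene", "", "2-phenylethyl acetate", "hexanal", "unknownium",
             "dup-ethanol-a", "dup-ethanol-b"),
    smiles = c("", "O=Cc1ccco1", "", "CCCCCC=O", "", "CCO", "C(C)O"),
    descriptors = c("solvent", "sweet;woody", "floral;rose", "green;grassy",
                    "fruity", "alcoholic", "sweet"),
    threshold_mg_L = c("1.2", "3.5", "0.37", "0.005;0.009", "1", "990", "1010"),
    stringsAsFactors = FALSE)
}

# small cached synthetic corpus shared by model-level tests
synth_cache <- new.env(parent = emptyenv())
fixture_synth <- function(n = 150, seed = 3, noise_sd = 0.4) {
  key <- paste(n, seed, noise_sd)
  if (is.null(synth_cache[[key]])) {
    spec <- synth_spec(n_molecules = n, seed = seed, noise_sd = noise_sd)
    smi <- as.character(gen_molecules(spec))
    synth_cache[[key]] <- list(
      spec = spec, smiles = smi,
      labels = gen_labels(smi, spec),
      y = gen_thresholds(smi, spec))
  }
  synth_cache[[key]]
}

gbdt_default_config <- function() {
  list(n_estimators = 600L, max_depth = 6L, learning_rate = 0.1,
       subsample = 1.0, colsample_bytree = 1.0, reg_lambda = 1.0)
}
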