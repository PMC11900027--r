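# Shared fixtures: small study configurations and hand-built matrices.

# Desk-scale configuration: full seven-treatment design, reduced gene count
# with proportionally reduced response sets.
small_config <- function(seed = 1, n_genes = 400, ...) {
  synth_config(n_genes = n_genes,
               shared_acute_set_size = 20,
               acute_specific_sizes = c(acetamiprid = 20, clothianidin = 40,
                                        sulfoxaflor = 4),
               shared_chronic_set_size = 10,
               chronic_strong_down_n = 2,
               chronic_specific_sizes = c(acetamiprid = 4, clothianidin = 12,
                                          sulfoxaflor = 4),
               seed = seed, ...)
}

# Global null at a small gene count.
small_null_config <- function(seed = 1, n_genes = 300, ...) {
  null_synth_config(n_genes = n_genes, seed = seed, ...)
}

# Structured configuration for the colony-confounding diagnostic: strong
# colony effects, one chronic response set, nothing else.
confound_config_struct <- function(seed = 1, n_genes = 300) {
  synth_config(n_genes = n_genes, colony_effect_sd = 0.8,
               shared_acute_set_size = 0, shared_chronic_set_size = 0,
               chronic_strong_down_n = 0,
               acute_specific_sizes = c(acetamiprid = 0, clothianidin = 0,
                                        sulfoxaflor = 0),
               chronic_specific_sizes = c(acetamiprid = 0,
                                          clothianidin = 50,
                                          sulfoxaflor = 0),
               chronic_specific_lfc_range = c(1, 2),
               seed = seed)
}

# A bare count matrix with ids.
make_counts <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# Two-group sample table (control vs one treatment), single colony by
# default so the design reduces to the group contrast.
two_group_samples <- function(n_control, n_treat, treatment = "treat",
                              colonies = 1) {
  n <- n_control + n_treat
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    treatment = rep(c("control", treatment), c(n_control, n_treat)),
    compound = rep(c("none", treatment), c(n_control, n_treat)),
    scheme = rep(c("none", "acute"), c(n_control, n_treat)),
    colony = ((seq_len(n) - 1) %% colonies) + 1,
    stringsAsFactors = FALSE
  )
}
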