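# Shared fixture builders used across test files. All models are built in
# code; nothing is read from disk.

mets_df <- function(ids) {
  # ids like "A_c": species = prefix, compartment = suffix
  sp <- sub("_[^_]*$", "", ids)
  cp <- sub("^.*_", "", ids)
  data.frame(id = ids, species = sp, compartment = cp,
             stringsAsFactors = FALSE)
}

# linear chain: EX -> T -> R1 -> ... -> Rk -> DM, all in subsystem "Chain"
make_chain_model <- function(chain_len = 2, uptake = 1000) {
  ids <- c("A_e", "A_c", paste0("M", seq_len(chain_len), "_c"))
  rxns <- list(
    EX = list(mets = c(A_e = -1), lb = -uptake, ub = 1000,
              subsystem = "Exchange"),
    T1 = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 1000, gpr = "GT",
              subsystem = "Transport"))
  prev <- "A_c"
  for (k in seq_len(chain_len)) {
    cur <- paste0("M", k, "_c")
    rxns[[paste0("R", k)]] <- list(
      mets = stats::setNames(c(-1, 1), c(prev, cur)), lb = 0, ub = 1000,
      gpr = paste0("G", k), subsystem = "Chain")
    prev <- cur
  }
  rxns$DM <- list(mets = stats::setNames(-1, prev), lb = 0, ub = 1000,
                  subsystem = "Exchange")
  contextcore:::build_model(mets_df(ids), rxns, id = "CHAIN")
}

# two parallel 2-reaction paths between a core source and a core sink
make_two_path_model <- function() {
  ids <- c("A_c", "X1_c", "X2_c", "B_c")
  rxns <- list(
    SRC = list(mets = c(A_c = 1), lb = 0, ub = 1000, gpr = "GS",
               subsystem = "Boundary"),
    P1a = list(mets = c(A_c = -1, X1_c = 1), lb = 0, ub = 1000, gpr = "GP1",
               subsystem = "Path1"),
    P1b = list(mets = c(X1_c = -1, B_c = 1), lb = 0, ub = 1000, gpr = "GP1b",
               subsystem = "Path1"),
    P2a = list(mets = c(A_c = -1, X2_c = 1), lb = 0, ub = 1000, gpr = "GP2",
               subsystem = "Path2"),
    P2b = list(mets = c(X2_c = -1, B_c = 1), lb = 0, ub = 1000, gpr = "GP2b",
               subsystem = "Path2"),
    SNK = list(mets = c(B_c = -1), lb = 0, ub = 1000, gpr = "GK",
               subsystem = "Boundary"))
  contextcore:::build_model(mets_df(ids), rxns, id = "TWOPATH")
}

# six-reaction toy where biomass consumes two metabolites, one of which is
# only produced by the penalized reaction R5
make_biomass_model <- function() {
  ids <- c("A_e", "A_c", "B_c", "E_c", "D_c")
  rxns <- list(
    EX  = list(mets = c(A_e = -1), lb = -1000, ub = 1000,
               subsystem = "Exchange"),
    T1  = list(mets = c(A_e = -1, A_c = 1), lb = 0, ub = 1000, gpr = "GT",
               subsystem = "Transport"),
    R1  = list(mets = c(A_c = -1, B_c = 1), lb = 0, ub = 1000, gpr = "G1",
               subsystem = "PathX"),
    R5  = list(mets = c(A_c = -1, E_c = 1), lb = 0, ub = 1000, gpr = "G5",
               subsystem = "PathX"),
    Rd  = list(mets = c(A_c = -1, D_c = 1), lb = 0, ub = 1000, gpr = "GD",
               subsystem = "PathY"),
    DMd = list(mets = c(D_c = -1), lb = 0, ub = 1000, subsystem = "Exchange"),
    BIO = list(mets = c(B_c = -1, E_c = -1), lb = 0, ub = 1000,
               subsystem = "Biomass"))
  contextcore:::build_model(mets_df(ids), rxns, objective = "BIO",
                            id = "BIOTOY")
}

# glycolysis-flavoured toy for cofactor filtering: HEX consumes glc (real
# substrate) and atp (cofactor, adp produced); ADK is a pure-cofactor
# reaction; OXP regenerates atp in a different subsystem
make_cofactor_model <- function() {
  ids <- c("glc_e", "glc_c", "g6p_c", "atp_c", "adp_c", "amp_c")
  rxns <- list(
    EX_GLC = list(mets = c(glc_e = -1), lb = -10, ub = 1000,
                  subsystem = "Exchange"),
    T_GLC  = list(mets = c(glc_e = -1, glc_c = 1), lb = 0, ub = 1000,
                  gpr = "SLC2A1", subsystem = "Transport"),
    HEX    = list(mets = c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
                  lb = 0, ub = 1000, gpr = "HK1", subsystem = "Glycolysis"),
    DM_G6P = list(mets = c(g6p_c = -1), lb = 0, ub = 1000,
                  subsystem = "Exchange"),
    OXP    = list(mets = c(adp_c = -1, atp_c = 1), lb = 0, ub = 1000,
                  gpr = "ATP5A", subsystem = "OxPhos"),
    ADK    = list(mets = c(atp_c = -1, amp_c = -1, adp_c = 2), lb = -1000,
                  ub = 1000, gpr = "AK1", subsystem = "NucMet"),
    DM_AMP = list(mets = c(amp_c = 1), lb = -1000, ub = 1000,
                  subsystem = "Exchange"))
  contextcore:::build_model(mets_df(ids), rxns, id = "COF")
}

# parameter grid of random fixture configurations with <= 15 reactions
random_model_configs <- function(n) {
  grid <- expand.grid(n_pathways = 1:3, chain_len = 1:4, n_blocked = 0:3)
  grid$n_rxn <- grid$n_pathways * (3 + grid$chain_len) + grid$n_blocked
  grid <- grid[grid$n_rxn <= 15, ]
  grid[rep(seq_len(nrow(grid)), length.out = n), ]
}
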