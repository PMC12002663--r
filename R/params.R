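## Parameter layout and default kinetic constants.
##
## The order of `cl_param_names` is a binary contract with the C++ rhs
## (enum `par` in src/models.cpp); never reorder, only append.

cl_param_names <- c(
  ## Per/Cry mRNA, cytoplasmic and nuclear PER-CRY complex
  "vbp", "vsp", "kab", "hab", "kip", "hip", "vmp", "kmp",
  "ksp", "k1", "k2", "vdpc", "vdpn", "kdp",
  ## Bmal1 mRNA and BMAL1-CLOCK heterodimer
  "vbb", "vsb", "kib", "hib", "dmb", "ksb", "db",
  ## Rev-erba mRNA and REV-ERBa protein (+ reverse-coupling gate)
  "vbr", "vsr", "kar", "har", "kir", "hir", "dmr", "ksr", "dr", "kc2", "hc2",
  ## constitutive BMAL1-CLOCK synthesis (Model 1 only)
  "ksb0",
  ## Wee1 mRNA and WEE1 protein (forward-coupling branch)
  "vbw", "vsw", "kaw", "haw", "dmw", "ksw", "dw",
  ## cyclin B / MPF / APC relaxation oscillator
  "vsc", "vdc", "kdc", "kdl",
  "vb1", "vs1", "kam", "ham", "kcb", "hcb", "v2", "kwee", "k2g",
  "vs3", "ka3", "ha3", "v4", "k4",
  ## Model 3 cyclin cascade (CycD -> CycE -> CycA -> CycB) and p21
  "vd0", "ddd", "ve", "kde", "de", "va", "kea", "da", "bcb", "kacb",
  "vp", "dp21", "krev", "hrev", "kp21",
  ## PER-CRY inactivation of BMAL1-CLOCK (Models 2-3)
  "kbp",
  ## coupling strengths and module time-scale factors
  "c1", "c2", "scl", "scc"
)

## Degradation parameters of the PER-CRY complex species (cytoplasmic and
## nuclear protein, not mRNA); these are the rates divided by the KL001
## dose factor.
cl_percry_degradation <- c("vdpc", "vdpn")

## Default kinetic constants.  Rates are 1/h or conc/h, Michaelis and
## activation/repression constants are concentrations (arbitrary units),
## Hill coefficients are dimensionless.  The raw constants put the clock
## limit cycle near 11.5 h and the MPF cycle near 23.7 h; the module
## time-scale factors scl/scc are calibrated by `build_model()` so that the
## uncoupled deterministic periods hit the requested clock period and
## autonomous cell cycle period exactly.
cl_default_params <- c(
  vbp = 0.05, vsp = 1.2, kab = 1, hab = 2, kip = 1, hip = 4,
  vmp = 0.7, kmp = 0.3,
  ksp = 0.9, k1 = 0.6, k2 = 0.1, vdpc = 0.8, vdpn = 0.8, kdp = 0.3,
  vbb = 0.05, vsb = 4.5, kib = 1, hib = 4, dmb = 1.0, ksb = 0.8, db = 0.6,
  vbr = 0.05, vsr = 2.6, kar = 1.5, har = 2, kir = 1, hir = 2,
  dmr = 0.5, ksr = 0.4, dr = 0.3, kc2 = 0.25, hc2 = 4,
  ksb0 = 0.9,
  vbw = 0.3, vsw = 1.2, kaw = 1.15, haw = 4, dmw = 0.8, ksw = 0.8, dw = 0.8,
  vsc = 0.15, vdc = 1.2, kdc = 0.1, kdl = 0.05,
  vb1 = 0.15, vs1 = 2.5, kam = 0.25, ham = 2, kcb = 1.0, hcb = 2,
  v2 = 0.3625, kwee = 0.15, k2g = 0.1,
  vs3 = 1.0, ka3 = 0.4, ha3 = 2, v4 = 0.35, k4 = 0.1,
  vd0 = 0.4, ddd = 0.4, ve = 0.5, kde = 0.5, de = 0.4,
  va = 0.8, kea = 0.3, da = 0.4, bcb = 0.7, kacb = 0.25,
  vp = 0.2, dp21 = 0.4, krev = 1, hrev = 2, kp21 = 2,
  kbp = 1.6,
  c1 = 0, c2 = 0, scl = 1, scc = 1
)

cl_species <- list(
  `1` = c("per_cry_mrna", "per_cry_c", "per_cry_n", "bmal1_clock",
          "wee1_mrna", "wee1", "cyclin_b", "mpf", "apc"),
  `2` = c("per_cry_mrna", "per_cry_c", "per_cry_n", "bmal1_mrna",
          "bmal1_clock", "reverb_mrna", "reverb",
          "wee1_mrna", "wee1", "cyclin_b", "mpf", "apc"),
  `3` = c("per_cry_mrna", "per_cry_c", "per_cry_n", "bmal1_mrna",
          "bmal1_clock", "reverb_mrna", "reverb",
          "wee1_mrna", "wee1", "cyc_d", "cyc_e", "cyc_a",
          "cyclin_b", "mpf", "apc", "p21")
)

## Clock-side species (receive the clock_noise_scale multiplier); everything
## else is counted as cell-cycle side.
cl_clock_species <- list(
  `1` = c("per_cry_mrna", "per_cry_c", "per_cry_n", "bmal1_clock"),
  `2` = c("per_cry_mrna", "per_cry_c", "per_cry_n", "bmal1_mrna",
          "bmal1_clock", "reverb_mrna", "reverb"),
  `3` = c("per_cry_mrna", "per_cry_c", "per_cry_n", "bmal1_mrna",
          "bmal1_clock", "reverb_mrna", "reverb")
)

cl_species_names <- function(model_id) {
  cl_species[[as.character(model_id)]]
}

cl_mpf_index <- function(model_id) {
  match("mpf", cl_species_names(model_id))
}

## A reasonable on-attractor starting state for each model (interior of the
## positive orthant; transients are discarded by burn-in anyway).
cl_default_init <- function(model_id) {
  sp <- cl_species_names(model_id)
  x <- rep(0.3, length(sp))
  names(x) <- sp
  x["bmal1_clock"] <- 1.5
  x[c("wee1_mrna", "wee1")] <- 0.4
  x["mpf"] <- 0.05
  x["apc"] <- 0.05
  x
}
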