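## shared fixtures, all built in code

## default scheme with every rate constant replaced (frozen system when 0)
scheme_with_k <- function(k, D_O2 = NULL, Ea_kJ = NULL) {
  sch <- default_scheme()
  sch$k_ref <- rep_len(k, length(sch$k_ref))
  if (!is.null(D_O2)) sch$D_O2 <- D_O2
  if (!is.null(Ea_kJ)) sch$Ea <- Ea_kJ * 1000
  sch
}

## default scheme minus the O2-producing deoxygenation reaction
scheme_no_o2_production <- function() {
  sch <- default_scheme()
  keep <- colnames(sch$stoich) != "deoxygenation"
  sch$stoich <- sch$stoich[, keep, drop = FALSE]
  sch$k_ref <- sch$k_ref[keep]
  sch
}

## generic little scheme: A + B -> C with unit rate
scheme_abc <- function(k = 1) {
  reaction_scheme(
    species = data.frame(name = c("A", "B", "C"), role = "other",
                         diffusive = FALSE),
    reactions = list(list(name = "assoc", reactants = c(A = 1, B = 1),
                          products = c(C = 1), k_ref = k)),
    T_ref_C = 20, D_O2_m2_s = 0, Ea_kJ_mol = 0)
}

## random mass-action scheme over myoglobin-style species (no conservation
## constraint: all roles "other") for oracle comparisons
random_scheme <- function(n_species = 5, n_reactions = 6) {
  repeat {
    st <- matrix(sample(c(-2L, -1L, 0L, 0L, 1L), n_species * n_reactions,
                        replace = TRUE), n_species, n_reactions)
    if (all(colSums(st < 0) > 0)) break
  }
  sp <- data.frame(name = paste0("S", seq_len(n_species)), role = "other",
                   diffusive = FALSE)
  sch <- reaction_scheme(sp, list(list(name = "dummy",
                                       reactants = c(S1 = 1),
                                       products = c(S2 = 1), k_ref = 0)),
                         T_ref_C = 20, D_O2_m2_s = 0, Ea_kJ_mol = 10)
  ## swap in the random stoichiometry directly (bypasses conservation rules
  ## that only apply to myoglobin-form rows anyway)
  sch$stoich <- st
  rownames(sch$stoich) <- sp$name
  colnames(sch$stoich) <- paste0("r", seq_len(n_reactions))
  sch$k_ref <- stats::runif(n_reactions, 0.1, 2)
  sch
}

## independent brute-force mass action: plain triple loop
brute_force_rates <- function(C, stoich, k) {
  M <- nrow(stoich); N <- ncol(stoich)
  dC <- numeric(M)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      rate <- k[j]
      for (ii in seq_len(M)) {
        if (stoich[ii, j] < 0) rate <- rate * C[ii]^(-stoich[ii, j])
      }
      dC[i] <- dC[i] + stoich[i, j] * rate
    }
  }
  dC
}

## complementary error function via the normal CDF (independent of any
## package code)
erfc_ref <- function(x) 2 * stats::pnorm(-x * sqrt(2))

## six-condition temperature x oxygen cross used by the calibration studies
cross_design <- function(T_C = c(2, 6, 10), pO2 = c(20, 100)) {
  make_design("custom", expand.grid(T_C = T_C, pO2_pct = pO2,
                                    aging_d = 14, angle_deg = 0))
}

## quick lookup of the first time (h) a kinetics series falls below `level`
crossing_time_h <- function(ck, level) {
  i <- which(ck$values < level)[1]
  if (is.na(i)) Inf else ck$times_h[i]
}
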