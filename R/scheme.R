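#' Mass-action reaction schemes for myoglobin redox chemistry
#'
#' A reaction scheme bundles the chemical species, the stoichiometric matrix,
#' the rate constants at a reference temperature, the oxygen diffusivity, and
#' a single activation energy used to rescale every rate constant with
#' storage temperature. Myoglobin forms are carried as dimensionless
#' fractions that the scheme must conserve (their stoichiometric rows sum to
#' zero in every reaction), while dissolved oxygen is in mol m-3; rate
#' constant units therefore depend on the reaction order and are documented
#' in the scheme file.
#'
#' @param species data.frame with columns `name` (unique identifiers),
#'   `role` (one of `"myoglobin-form"`, `"dissolved-gas"`, `"other"`) and
#'   `diffusive` (logical; only diffusive species receive a diffusion term).
#' @param reactions list of reactions, each a list with elements `reactants`
#'   and `products` (named numeric vectors of multiplicities), `k_ref`
#'   (non-negative rate constant at the reference temperature) and an
#'   optional `name`.
#' @param T_ref_C reference temperature of the rate constants, degrees C.
#' @param D_O2_m2_s diffusivity of dissolved oxygen in the meat, m2 s-1.
#' @param Ea_kJ_mol activation energy applied to all reactions, kJ mol-1.
#' @param o2_solubility_mol_m3_per_pct dissolved-oxygen concentration at the
#'   exposed surface per percent headspace oxygen, mol m-3 per percent.
#' @param name optional scheme label.
#'
#' @return An object of class `reaction_scheme`: a list with elements
#'   `species`, `stoich` (M x N matrix, negative entries consumed, positive
#'   produced), `k_ref`, `T_ref_K`, `D_O2`, `Ea` (J mol-1),
#'   `o2_solubility` and `name`.
#' @seealso [read_scheme()], [default_scheme()], [mass_action_rates()],
#'   [arrhenius_scale()]
#' @export
reaction_scheme <- function(species, reactions, T_ref_C, D_O2_m2_s,
                            Ea_kJ_mol, o2_solubility_mol_m3_per_pct = 0.017,
                            name = "unnamed scheme") {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  need <- c("name", "role", "diffusive")
  if (!all(need %in% names(species)))
    stop_parse("species", "need columns %s", paste(need, collapse = ", "))
  species$diffusive <- as.logical(species$diffusive)

  M <- nrow(species)
  N <- length(reactions)
  stoich <- matrix(0L, nrow = M, ncol = N,
                   dimnames = list(species$name, NULL))
  k_ref <- numeric(N)
  rnames <- character(N)
  for (j in seq_len(N)) {
    rx <- reactions[[j]]
    rnames[j] <- rx$name %||% paste0("r", j)
    for (side in c("reactants", "products")) {
      v <- rx[[side]]
      if (is.null(v)) next
      if (is.null(names(v)) || any(!nzchar(names(v))))
        stop_parse(side, "multiplicities must be named by species (reaction %d)", j)
      unknown <- setdiff(names(v), species$name)
      if (length(unknown))
        stop_parse(side, "unknown species '%s' in reaction %d",
                   unknown[1], j)
      sgn <- if (side == "reactants") -1L else 1L
      for (s in names(v))
        stoich[s, j] <- stoich[s, j] + sgn * as.integer(v[[s]])
    }
    if (is.null(rx$k_ref) || !is_number(rx$k_ref))
      stop_parse("k_ref", "reaction %d lacks a numeric rate constant", j)
    k_ref[j] <- rx$k_ref
  }
  colnames(stoich) <- rnames

  out <- structure(list(
    species = species,
    stoich = stoich,
    k_ref = k_ref,
    T_ref_K = T_ref_C + 273.15,
    D_O2 = D_O2_m2_s,
    Ea = Ea_kJ_mol * 1000,
    o2_solubility = o2_solubility_mol_m3_per_pct,
    name = name
  ), class = "reaction_scheme")
  validate_scheme(out)
  out
}

#' @noRd
validate_scheme <- function(x) {
  sp <- x$species
  if (anyDuplicated(sp$name))
    stop_validation("unique-names", "duplicated species name '%s'",
                    sp$name[duplicated(sp$name)][1])
  roles <- c("myoglobin-form", "dissolved-gas", "other")
  if (!all(sp$role %in% roles))
    stop_validation("role", "unknown role '%s'",
                    setdiff(sp$role, roles)[1])
  if (any(x$k_ref < 0))
    stop_validation("k-nonnegative", "rate constant %d is negative",
                    which(x$k_ref < 0)[1])
  if (x$D_O2 < 0)
    stop_validation("D-nonnegative", "oxygen diffusivity is negative")
  if (!is_number(x$T_ref_K) || x$T_ref_K <= 0)
    stop_validation("T-ref", "reference temperature must be positive kelvin")
  if (ncol(x$stoich) > 0 && any(colSums(x$stoich < 0) == 0))
    stop_validation("has-reactant",
                    "reaction '%s' consumes nothing",
                    colnames(x$stoich)[which(colSums(x$stoich < 0) == 0)[1]])
  mbrows <- sp$role == "myoglobin-form"
  if (any(mbrows) && ncol(x$stoich) > 0) {
    colsum <- colSums(x$stoich[mbrows, , drop = FALSE])
    if (any(colsum != 0))
      stop_validation("myoglobin-conserved",
                      "myoglobin rows of reaction '%s' sum to %d, not 0",
                      colnames(x$stoich)[which(colsum != 0)[1]],
                      colsum[which(colsum != 0)[1]])
  }
  invisible(x)
}

#' Read a reaction scheme from a JSON or YAML file
#'
#' The file format is strict: unknown keys are rejected so that typos in
#' rate-constant names cannot silently disappear. Required top-level keys are
#' `species`, `reactions`, `T_ref_C`, `D_O2_m2_s` and `Ea_kJ_mol`; optional
#' keys are `o2_solubility_mol_m3_per_pct`, `name` and `description`. Each
#' species entry has `name`, `role`, `diffusive`; each reaction entry has
#' `reactants`, `products` (maps species -> multiplicity), `k_ref` and an
#' optional `name`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` scheme file.
#' @return A validated [reaction_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path))
    stop_parse("path", "scheme file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop_parse("path", "unsupported scheme format '.%s' (use json or yaml)", ext)
  }
  allowed <- c("species", "reactions", "T_ref_C", "D_O2_m2_s", "Ea_kJ_mol",
               "o2_solubility_mol_m3_per_pct", "name", "description")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop_parse(unknown[1], "unknown top-level key")
  for (key in c("species", "reactions", "T_ref_C", "D_O2_m2_s", "Ea_kJ_mol"))
    if (is.null(raw[[key]])) stop_parse(key, "missing required key")

  sp_allowed <- c("name", "role", "diffusive")
  species <- do.call(rbind, lapply(raw$species, function(s) {
    unknown <- setdiff(names(s), sp_allowed)
    if (length(unknown)) stop_parse(unknown[1], "unknown species key")
    for (key in sp_allowed)
      if (is.null(s[[key]])) stop_parse(key, "missing species key")
    data.frame(name = s$name, role = s$role,
               diffusive = as.logical(s$diffusive),
               stringsAsFactors = FALSE)
  }))

  rx_allowed <- c("name", "reactants", "products", "k_ref")
  reactions <- lapply(raw$reactions, function(r) {
    unknown <- setdiff(names(r), rx_allowed)
    if (length(unknown)) stop_parse(unknown[1], "unknown reaction key")
    r$reactants <- unlist(r$reactants)
    r$products <- unlist(r$products)
    r
  })

  reaction_scheme(
    species = species, reactions = reactions,
    T_ref_C = raw$T_ref_C, D_O2_m2_s = raw$D_O2_m2_s,
    Ea_kJ_mol = raw$Ea_kJ_mol,
    o2_solubility_mol_m3_per_pct =
      raw$o2_solubility_mol_m3_per_pct %||% 0.017,
    name = raw$name %||% basename(path)
  )
}

#' Write a reaction scheme to a JSON file
#'
#' @param scheme a [reaction_scheme()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  st <- scheme$stoich
  reactions <- lapply(seq_len(ncol(st)), function(j) {
    col <- st[, j]
    list(name = colnames(st)[j],
         reactants = as.list(-col[col < 0]),
         products = as.list(col[col > 0]),
         k_ref = scheme$k_ref[j])
  })
  obj <- list(
    name = scheme$name,
    species = lapply(seq_len(nrow(scheme$species)), function(i)
      as.list(scheme$species[i, ])),
    reactions = reactions,
    T_ref_C = scheme$T_ref_K - 273.15,
    D_O2_m2_s = scheme$D_O2,
    Ea_kJ_mol = scheme$Ea / 1000,
    o2_solubility_mol_m3_per_pct = scheme$o2_solubility
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The packaged default myoglobin oxidation scheme
#'
#' A deliberately small stand-in for the full published 22-reaction myoglobin
#' oxidation scheme (whose constants are not reproduced here): four species
#' (Mb, MbO2, MMb, dissolved O2) and five reactions -- oxygenation
#' Mb + O2 -> MbO2, deoxygenation MbO2 -> Mb + O2, autoxidation of both the
#' deoxy form (Mb -> MMb, faster) and the oxy form (MbO2 -> MMb, slower), and
#' metmyoglobin reduction MMb -> Mb. Constants are tuned (see
#' `tools/tune_default_scheme.R` in the source tree) so that at 2 degC and
#' 20% headspace O2 the predicted surface a*/a*0 holds near 1 for about 10
#' days before browning, and so that raising O2 to 100% delays browning by a
#' few days, matching the qualitative storage behaviour the models target.
#' Users with access to a full scheme can drop in their own file via
#' [read_scheme()].
#'
#' @return A [reaction_scheme()].
#' @export
default_scheme <- function() {
  read_scheme(system.file("extdata", "default_scheme.json",
                          package = "myocolor", mustWork = TRUE))
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat("Reaction scheme:", x$name, "\n")
  cat(sprintf("  %d species (%s), %d reactions\n",
              nrow(x$species), paste(x$species$name, collapse = ", "),
              ncol(x$stoich)))
  cat(sprintf("  T_ref = %.2f K, Ea = %.1f kJ/mol, D_O2 = %.3g m2/s\n",
              x$T_ref_K, x$Ea / 1000, x$D_O2))
  if (ncol(x$stoich)) {
    k <- signif(x$k_ref, 4)
    for (j in seq_len(ncol(x$stoich))) {
      col <- x$stoich[, j]
      lhs <- paste(ifelse(-col[col < 0] > 1,
                          paste0(-col[col < 0], " "), ""),
                   names(col[col < 0]), sep = "", collapse = " + ")
      rhs <- paste(ifelse(col[col > 0] > 1,
                          paste0(col[col > 0], " "), ""),
                   names(col[col > 0]), sep = "", collapse = " + ")
      cat(sprintf("  %-14s %s -> %s   k_ref = %g\n",
                  colnames(x$stoich)[j], lhs, rhs, k[j]))
    }
  }
  invisible(x)
}

#' Mass-action reaction rates
#'
#' Evaluates the time derivative of every species under exact mass-action
#' semantics: each reaction proceeds at its rate constant times the product
#' of its reactant concentrations raised to their stoichiometric
#' multiplicities, and species change at the stoichiometric combination of
#' reaction rates, dCi/dt = sum_j a_ij k_j prod_{a_ij<0} Ci^(-a_ij).
#'
#' @param C numeric vector of species concentrations (length M, ordered as
#'   `scheme$species`), or an M x n matrix of concentration profiles.
#' @param scheme a [reaction_scheme()].
#' @param k rate constants to use (length N); defaults to the scheme's
#'   reference constants. Pass the output of [arrhenius_scale()] for other
#'   temperatures.
#' @return Time derivatives with the same shape as `C`.
#' @export
mass_action_rates <- function(C, scheme, k = scheme$k_ref) {
  st <- scheme$stoich
  vec <- is.null(dim(C))
  if (vec) C <- matrix(C, ncol = 1)
  if (nrow(C) != nrow(st))
    stop("dimension mismatch: C has ", nrow(C), " species, scheme has ",
         nrow(st), call. = FALSE)
  if (length(k) != ncol(st))
    stop("dimension mismatch: k has length ", length(k), ", scheme has ",
         ncol(st), " reactions", call. = FALSE)
  dC <- ma_rates(C, st, k)
  if (vec) drop(dC) else dC
}

## internal fast path shared with the PDE right-hand side: C is M x n.
#' @noRd
ma_rates <- function(C, stoich, k) {
  n <- ncol(C)
  N <- length(k)
  rates <- matrix(0, nrow = N, ncol = n)
  for (j in seq_len(N)) {
    r <- rep.int(k[j], n)
    cons <- which(stoich[, j] < 0)
    for (i in cons) {
      ord <- -stoich[i, j]
      r <- r * (if (ord == 1) C[i, ] else C[i, ]^ord)
    }
    rates[j, ] <- r
  }
  stoich %*% rates
}

#' Arrhenius temperature scaling of rate constants
#'
#' Rescales every rate constant of a scheme from its reference temperature to
#' a storage temperature using a single activation energy, in the relative
#' form k_j(T) = k_j(T_ref) exp(-(Ea/R)(1/T - 1/T_ref)) with
#' R = 8.314 J mol-1 K-1. This form returns exactly `k_ref` at `T = T_ref`
#' (the absolute one-exponential form does not, which is why the relative
#' form is used here).
#'
#' @param scheme a [reaction_scheme()].
#' @param T_K absolute temperature, kelvin (scalar).
#' @param Ea_J_mol optional activation-energy override, J mol-1; defaults to
#'   the scheme's value.
#' @return Numeric vector of N rate constants at `T_K`.
#' @export
arrhenius_scale <- function(scheme, T_K, Ea_J_mol = scheme$Ea) {
  stopifnot(is_number(T_K), T_K > 0)
  scheme$k_ref * exp(-(Ea_J_mol / R_GAS) * (1 / T_K - 1 / scheme$T_ref_K))
}
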