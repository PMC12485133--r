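#' Build a mass-action reaction network for a GAP assay condition
#'
#' Constructs the species list, reactions and conservation groups of the
#' endpoint-assay model. The mechanism has three layers: membrane recruitment
#' of the PH module (PH binds PIP2 sites), substrate binding (PH binds
#' membrane-anchored Arf.GTP; associations between two membrane-resident
#' partners are enhanced by `lambda_membrane`, with thermodynamically
#' consistent cycle closure -- the PH.Arf complex retains its membrane
#' attachment as an avidity species), and catalysis (the GAP domain engages
#' either free Arf.GTP, slowly and hydrolyzing at `kcat_basal`, or PH-bound
#' Arf.GTP, hydrolyzing at `alpha_allostery * kcat_basal`). GTP hydrolysis is
#' irreversible and Arf starts fully GTP loaded.
#'
#' @param condition An [assay_condition()]; `pip2_mol_percent = 0` removes
#'   membrane sites.
#' @param params A [kinetic_params()].
#' @param membrane_on,ph_arf_on Toggles used by [decompose_activation()]:
#'   setting either `FALSE` removes membrane sites or PH-Arf binding.
#' @param alpha Override for the allosteric multiplier (default
#'   `params$alpha_allostery`).
#' @return List of class `reaction_network`: `species` tibble (`name`,
#'   `compartment`), `reactions` tibble (`rate`, `r1`, `r2`, `products` list
#'   column), stoichiometry matrix `S`, conservation `groups`, and the
#'   initial-condition template `init0`.
#' @export
build_network <- function(condition, params = default_kinetic_params(),
                          membrane_on = TRUE, ph_arf_on = TRUE,
                          alpha = NULL) {
  alpha <- alpha %||% params$alpha_allostery
  sites <- if (membrane_on) membrane_sites(condition, params) else 0
  kcat <- params$kcat_basal
  kcat_act <- alpha * params$kcat_basal
  lam <- params$lambda_membrane
  kon_pa <- if (ph_arf_on) params$kon_ph_arf else 0

  sp <- function(name, compartment) tibble(name = name, compartment = compartment)
  rx <- function(rate, r1, r2 = NA_character_, products = character()) {
    tibble(rate = rate, r1 = r1, r2 = r2, products = list(products))
  }

  if (condition$construct == "ZA") {
    species <- bind_rows(sp("ZA", "solution"), sp("ArfGTP", "membrane"),
                         sp("ArfGDP", "membrane"), sp("ZAA", "membrane"))
    reactions <- bind_rows(
      rx(params$kon_za_arf, "ZA", "ArfGTP", "ZAA"),
      rx(params$koff_za_arf, "ZAA", NA, c("ZA", "ArfGTP")),
      rx(kcat, "ZAA", NA, c("ZA", "ArfGDP")))
    groups <- list(arf = c("ArfGTP", "ArfGDP", "ZAA"),
                   enzyme = c("ZA", "ZAA"))
    enzyme_species <- "ZA"
  } else if (condition$construct == "trans") {
    species <- bind_rows(
      sp("PH_s", "solution"), sp("PH_m", "membrane"), sp("M", "membrane"),
      sp("ArfGTP", "membrane"), sp("ArfGDP", "membrane"),
      sp("PHA_s", "membrane"), sp("PHA_m", "membrane"),
      sp("ZA", "solution"), sp("ZAA", "membrane"),
      sp("ZPHA_s", "membrane"), sp("ZPHA_m", "membrane"))
    reactions <- bind_rows(
      rx(params$kon_ph_membrane, "PH_s", "M", "PH_m"),
      rx(params$koff_ph_membrane, "PH_m", NA, c("PH_s", "M")),
      rx(kon_pa, "PH_s", "ArfGTP", "PHA_s"),
      rx(params$koff_ph_arf, "PHA_s", NA, c("PH_s", "ArfGTP")),
      rx(kon_pa * lam, "PH_m", "ArfGTP", "PHA_m"),
      rx(params$koff_ph_arf, "PHA_m", NA, c("PH_m", "ArfGTP")),
      # cycle closure: membrane affinity of the PH.Arf complex carries the
      # avidity bonus, koff scaled by 1/lambda
      rx(params$kon_ph_membrane, "PHA_s", "M", "PHA_m"),
      rx(params$koff_ph_membrane / lam, "PHA_m", NA, c("PHA_s", "M")),
      rx(params$kon_za_arf, "ZA", "ArfGTP", "ZAA"),
      rx(params$koff_za_arf, "ZAA", NA, c("ZA", "ArfGTP")),
      rx(kcat, "ZAA", NA, c("ZA", "ArfGDP")),
      rx(params$kon_za_arf_activated, "ZA", "PHA_s", "ZPHA_s"),
      rx(params$koff_za_arf_activated, "ZPHA_s", NA, c("ZA", "PHA_s")),
      rx(params$kon_za_arf_activated, "ZA", "PHA_m", "ZPHA_m"),
      rx(params$koff_za_arf_activated, "ZPHA_m", NA, c("ZA", "PHA_m")),
      rx(kcat_act, "ZPHA_s", NA, c("ZA", "PH_s", "ArfGDP")),
      rx(kcat_act, "ZPHA_m", NA, c("ZA", "PH_m", "ArfGDP")))
    groups <- list(
      arf = c("ArfGTP", "ArfGDP", "PHA_s", "PHA_m", "ZAA", "ZPHA_s", "ZPHA_m"),
      ph = c("PH_s", "PH_m", "PHA_s", "PHA_m", "ZPHA_s", "ZPHA_m"),
      za = c("ZA", "ZAA", "ZPHA_s", "ZPHA_m"),
      sites = c("M", "PH_m", "PHA_m", "ZPHA_m"))
    enzyme_species <- "ZA"
  } else {  # tandem enzymes: PZA (PH binds Arf) or PHdZA (it does not)
    if (condition$construct == "PHdZA") kon_pa <- 0
    species <- bind_rows(
      sp("E_s", "solution"), sp("E_m", "membrane"), sp("M", "membrane"),
      sp("ArfGTP", "membrane"), sp("ArfGDP", "membrane"),
      sp("EA_s", "membrane"), sp("EA_m", "membrane"),
      sp("EAx_s", "membrane"), sp("EAx_m", "membrane"),
      sp("EZ_s", "membrane"), sp("EZ_m", "membrane"))
    reactions <- bind_rows(
      rx(params$kon_ph_membrane, "E_s", "M", "E_m"),
      rx(params$koff_ph_membrane, "E_m", NA, c("E_s", "M")),
      rx(kon_pa, "E_s", "ArfGTP", "EA_s"),
      rx(params$koff_ph_arf, "EA_s", NA, c("E_s", "ArfGTP")),
      rx(kon_pa * lam, "E_m", "ArfGTP", "EA_m"),
      rx(params$koff_ph_arf, "EA_m", NA, c("E_m", "ArfGTP")),
      rx(params$kon_ph_membrane, "EA_s", "M", "EA_m"),
      rx(params$koff_ph_membrane / lam, "EA_m", NA, c("EA_s", "M")),
      rx(params$k_engage, "EA_s", NA, "EAx_s"),
      rx(params$k_disengage, "EAx_s", NA, "EA_s"),
      rx(params$k_engage, "EA_m", NA, "EAx_m"),
      rx(params$k_disengage, "EAx_m", NA, "EA_m"),
      rx(kcat_act, "EAx_s", NA, c("E_s", "ArfGDP")),
      rx(kcat_act, "EAx_m", NA, c("E_m", "ArfGDP")),
      rx(params$kon_za_arf, "E_s", "ArfGTP", "EZ_s"),
      rx(params$koff_za_arf, "EZ_s", NA, c("E_s", "ArfGTP")),
      rx(params$kon_za_arf * lam, "E_m", "ArfGTP", "EZ_m"),
      rx(params$koff_za_arf, "EZ_m", NA, c("E_m", "ArfGTP")),
      rx(kcat, "EZ_s", NA, c("E_s", "ArfGDP")),
      rx(kcat, "EZ_m", NA, c("E_m", "ArfGDP")))
    groups <- list(
      arf = c("ArfGTP", "ArfGDP", "EA_s", "EA_m", "EAx_s", "EAx_m",
              "EZ_s", "EZ_m"),
      enzyme = c("E_s", "E_m", "EA_s", "EA_m", "EAx_s", "EAx_m",
                 "EZ_s", "EZ_m"),
      sites = c("M", "E_m", "EA_m", "EAx_m", "EZ_m"))
    enzyme_species <- "E_s"
  }
  reactions <- reactions[reactions$rate > 0, ]
  init0 <- setNames(numeric(nrow(species)), species$name)
  init0["ArfGTP"] <- condition$arf_total
  if ("M" %in% species$name) init0["M"] <- sites
  if (condition$construct == "trans") init0["PH_s"] <- condition$ph_fixed
  structure(list(species = species, reactions = reactions,
                 S = stoichiometry_matrix(species$name, reactions),
                 groups = groups, init0 = init0,
                 enzyme_species = enzyme_species,
                 condition = condition),
            class = "reaction_network")
}

stoichiometry_matrix <- function(species, reactions) {
  S <- matrix(0, length(species), nrow(reactions),
              dimnames = list(species, NULL))
  for (j in seq_len(nrow(reactions))) {
    S[reactions$r1[j], j] <- S[reactions$r1[j], j] - 1
    if (!is.na(reactions$r2[j])) S[reactions$r2[j], j] <- S[reactions$r2[j], j] - 1
    for (pr in reactions$products[[j]]) S[pr, j] <- S[pr, j] + 1
  }
  S
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> construct %s: %d species, %d reactions\n",
              x$condition$construct, nrow(x$species), nrow(x$reactions)))
  invisible(x)
}

# flatten the network into the fixed-length parameter vector the compiled
# RHS expects (padded: the DLL stores a static buffer of 4096 doubles)
pack_network <- function(network) {
  sp <- network$species$name
  r1 <- match(network$reactions$r1, sp)
  r2 <- match(network$reactions$r2, sp)
  r2[is.na(r2)] <- 0
  p <- c(length(sp), nrow(network$reactions),
         as.vector(rbind(network$reactions$rate, r1, r2)),
         as.vector(network$S))
  if (length(p) > 4096) abort("network too large for the compiled solver")
  c(p, numeric(4096 - length(p)))
}

#' Load a reaction network from a YAML description
#'
#' Allows the default mechanism to be replaced without code changes. The YAML
#' document must contain `species` (list of `{name, compartment}`),
#' `reactions` (list of `{rate, reactants (1-2 names), products}`), optional
#' `groups` (named lists of species) and `init` (named concentrations).
#'
#' @param path YAML file path.
#' @param condition An [assay_condition()] attached for bookkeeping.
#' @return A `reaction_network`.
#' @export
network_from_yaml <- function(path, condition = assay_condition()) {
  doc <- yaml::read_yaml(path)
  species <- bind_rows(lapply(doc$species, function(s) {
    tibble(name = s$name, compartment = s$compartment %||% "solution")
  }))
  reactions <- bind_rows(lapply(doc$reactions, function(r) {
    stopifnot_named("reaction rate must be nonnegative" = r$rate >= 0,
                    "1 or 2 reactants per reaction" =
                      length(r$reactants) %in% 1:2)
    tibble(rate = r$rate, r1 = r$reactants[[1]],
           r2 = if (length(r$reactants) == 2) r$reactants[[2]] else NA_character_,
           products = list(unlist(r$products)))
  }))
  init0 <- setNames(numeric(nrow(species)), species$name)
  for (nm in names(doc$init %||% list())) init0[nm] <- doc$init[[nm]]
  structure(list(species = species, reactions = reactions,
                 S = stoichiometry_matrix(species$name, reactions),
                 groups = doc$groups %||% list(), init0 = init0,
                 enzyme_species = doc$enzyme_species %||% species$name[1],
                 condition = condition),
            class = "reaction_network")
}
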