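# Deterministic miniature iron-metabolism fixture.
#
# The generator emits a small growth-optimising network whose optimum is
# known in closed form, so the LP machinery, the cofactor formalism and the
# perturbation analyses can all be validated against hand arithmetic:
#
#   glucose --> precursor chain --> biomass  (precursor synthesis carries an
#     Fe-S cofactor requirement, like branched-chain amino acid synthesis)
#   glucose + O2 --> energy (respiration, haem-requiring, O2 bound-limited)
#   glucose --> energy (fermentation, O2-free but less glucose-efficient)
#   iron uptake: low-affinity route capped at the 1 uM threshold-derived
#     bound and requiring the haem pathway genes; high-affinity route
#     requiring secretory copper (Ccc2/Fet3 analogue) and, when the regulon
#     circuit is enabled, the iron-depletion signal AS
#   haem synthesis from cytosolic iron; biomass consumes haem directly
#   mitochondrial Fe-S biogenesis on an ES/SS scaffold cycle, sole route
#     through an arh1-analogue gene
#
# With defaults the optimum is mu = (G + (y-1) O)/2 = 0.7 with respiration
# pinned at the O2 bound (0.2) and iron comfortably in excess; iron becomes
# binding under low-iron or copper-starved scenarios, reproducing the
# qualitative benchmark table of environmental/genetic challenges.

#' Fixture configuration
#'
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @param n_pathway_reactions approximate number of core pathway reactions;
#'   the precursor chain is padded with mass-neutral steps to reach it.
#' @param iron_exchange_bound,copper_exchange_bound medium availability of
#'   iron/copper as uptake bound magnitudes (mmol/gDW/h).
#' @param cofactor_magnitude stoichiometric coefficient of the cofactor
#'   requirements (dimensionless per catalytic event).
#' @param include_scaffold,include_regulon include the ES/SS scaffold cycle
#'   and the AS/PS regulon circuit; the regulon requires the scaffold.
#' @param glucose_bound glucose uptake bound (unit uptake by default).
#' @param o2_bound oxygen uptake bound.
#' @param resp_yield energy yield of respiration relative to fermentation.
#' @param biomass_haem_coeff haem consumed per unit biomass (structural iron
#'   demand of growth).
#' @param iron_threshold_uM,copper_threshold_uM,conversion_factor affinity
#'   switching thresholds and the concentration-to-flux conversion factor.
#' @param jitter relative half-width of uniform bound jitter (0 = none);
#'   jitter is kept small enough not to change the active-constraint regime.
#' @param essentiality_labels named character vector of observed labels
#'   overriding the built-in reference (`"viable"`/`"inviable"`).
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_pathway_reactions = 25L,
                           iron_exchange_bound = 0.5,
                           copper_exchange_bound = 0.1,
                           cofactor_magnitude = 1e-6,
                           include_scaffold = TRUE,
                           include_regulon = TRUE,
                           glucose_bound = 1,
                           o2_bound = 0.2,
                           resp_yield = 3,
                           biomass_haem_coeff = 0.1,
                           iron_threshold_uM = 1,
                           copper_threshold_uM = 20,
                           conversion_factor = 0.065,
                           jitter = 0,
                           essentiality_labels = NULL) {
  cfg <- as.list(environment())
  if (cfg$include_regulon && !cfg$include_scaffold)
    stop("contradictory fixture config: regulon circuit requires the scaffold cycle")
  if (any(c(cfg$iron_exchange_bound, cfg$copper_exchange_bound) < 0))
    stop("exchange bounds must be >= 0")
  structure(cfg, class = "fixture_config")
}

# closed-form optimum of the fixture backbone given an iron supply cap.
# Returns mu, v_r (respiration), v_f (fermentation).  Assumes the padded
# chain regime established by fixture_config defaults (+/- small jitter).
fixture_backbone_optimum <- function(G, O, y, demand_per_mu, supply) {
  mu_resp <- G * y / (y + 1)               # all-respiratory candidate
  mu_energy <- if (mu_resp <= y * O) mu_resp else (G + (y - 1) * O) / 2
  mu <- mu_energy
  if (demand_per_mu > 0 && demand_per_mu * mu > supply)
    mu <- supply / demand_per_mu           # iron-limited growth
  v_r <- min(O, mu / y)
  # parsimonious choice: respiration up to need/cap, fermentation remainder
  v_f <- max(mu - y * v_r, 0)
  list(mu = mu, v_r = v_r, v_f = v_f)
}

#' Generate the miniature iron-metabolism fixture
#'
#' @param config a [fixture_config()].
#' @return list with elements:
#'   * `model`: the cofactor-augmented `metabolic_model`;
#'   * `model_unaugmented`: the same network before cofactor augmentation
#'     (for sweeps and augmentation-neutrality checks);
#'   * `bundle`: reference values derived by hand arithmetic, independent of
#'     any LP: realized parameters, expected growth/fluxes of the
#'     parsimonious optimum, observed and expected-predicted essentiality
#'     labels with the implied confusion matrix, and the expected
#'     qualitative directions of the benchmark scenarios.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  jit <- function(v) if (config$jitter > 0)
    v * (1 + stats::runif(1, -config$jitter, config$jitter)) else v
  G <- jit(config$glucose_bound)
  O <- jit(config$o2_bound)
  Fe <- jit(config$iron_exchange_bound)
  Cu <- config$copper_exchange_bound
  y <- config$resp_yield
  h <- config$biomass_haem_coeff
  x <- config$cofactor_magnitude
  lo_cap <- threshold_to_bound(affinity_threshold("iron",
                                                  config$iron_threshold_uM,
                                                  config$conversion_factor))
  cu_cap <- threshold_to_bound(affinity_threshold("copper",
                                                  config$copper_threshold_uM,
                                                  config$conversion_factor))

  m <- metabolic_model("iron_fixture",
                       compartments = c(e = "extracellular", c = "cytoplasm",
                                        m = "mitochondrion"),
                       default_growth_rate = 0.1)
  for (sp in list(c("glc_e", "e"), c("glc_c", "c"), c("o2_e", "e"),
                  c("o2_c", "c"), c("fe_e", "e"), c("fe_c", "c"),
                  c("cu_e", "e"), c("cu_c", "c"), c("cu_sp", "c"),
                  c("haem_c", "c"), c("prec_c", "c"), c("nrg_c", "c")))
    m <- add_species(m, sp[1], sp[1], sp[2])

  m <- add_reaction(m, "EX_glc", c(glc_e = -1), lb = -G, ub = 1000)
  m <- add_reaction(m, "EX_o2", c(o2_e = -1), lb = -O, ub = 1000)
  m <- add_reaction(m, "EX_fe", c(fe_e = -1), lb = -Fe, ub = 1000)
  m <- add_reaction(m, "EX_cu", c(cu_e = -1), lb = -Cu, ub = 1000)
  m <- add_reaction(m, "GLCt", c(glc_e = -1, glc_c = 1), gpr = "gGLT1",
                    membrane_spanning = TRUE)
  m <- add_reaction(m, "O2t", c(o2_e = -1, o2_c = 1), membrane_spanning = TRUE)
  m <- add_reaction(m, "CUt", c(cu_e = -1, cu_c = 1), ub = cu_cap,
                    gpr = "gCTR1", membrane_spanning = TRUE)
  m <- add_reaction(m, "CCC2", c(cu_c = -1, cu_sp = 1), gpr = "gCCC2")
  m <- add_reaction(m, "FETLO", c(fe_e = -1, fe_c = 1), ub = lo_cap,
                    gpr = "gFET4", membrane_spanning = TRUE)
  m <- add_reaction(m, "FETHI", c(fe_e = -1, fe_c = 1),
                    gpr = "gFET3 and gFTR1", membrane_spanning = TRUE)
  m <- add_reaction(m, "HEMS", c(fe_c = -1, haem_c = 1),
                    gpr = "gHEM1 and gHEM2")

  # precursor chain, padded towards n_pathway_reactions core reactions
  core_base <- 16L
  npad <- max(0L, as.integer(config$n_pathway_reactions) - core_base)
  if (!config$include_scaffold) npad <- max(0L, npad - 5L)
  chain_in <- "glc_c"
  if (npad > 0) {
    for (i in seq_len(npad))
      m <- add_species(m, paste0("prei", i, "_c"), compartment = "c")
    m <- add_reaction(m, "GLYC",
                      stats::setNames(c(-1, 1), c("glc_c", "prei1_c")),
                      gpr = "gGLY1 or gGLY2")
    if (npad > 1) for (i in seq_len(npad - 1L))
      m <- add_reaction(m, paste0("PRE", i),
                        stats::setNames(c(-1, 1),
                                        c(paste0("prei", i, "_c"),
                                          paste0("prei", i + 1L, "_c"))))
    m <- add_reaction(m, paste0("PRE", npad),
                      stats::setNames(c(-1, 1),
                                      c(paste0("prei", npad, "_c"), "prec_c")))
  } else {
    m <- add_reaction(m, "GLYC", c(glc_c = -1, prec_c = 1),
                      gpr = "gGLY1 or gGLY2")
  }

  m <- add_reaction(m, "RESP",
                    stats::setNames(c(-1, -1, y), c("glc_c", "o2_c", "nrg_c")),
                    gpr = "gCYT1 and gCOX1")
  m <- add_reaction(m, "FERM", c(glc_c = -1, nrg_c = 1), gpr = "gADH1")
  m <- add_reaction(m, "BIOMASS",
                    stats::setNames(c(-1, -1, -h), c("prec_c", "nrg_c", "haem_c")),
                    name = "growth")
  m <- set_objective(m, "BIOMASS")

  if (config$include_scaffold) {
    for (sp in list(c("so4_e", "e"), c("sdon_m", "m"), c("fe_m", "m"),
                    c("feX_c", "c"), c("fes_c", "c")))
      m <- add_species(m, sp[1], sp[1], sp[2])
    m <- add_reaction(m, "EX_so4", c(so4_e = -1), lb = -1000, ub = 1000)
    m <- add_reaction(m, "SO4t", c(so4_e = -1, sdon_m = 1), gpr = "gCYS",
                      membrane_spanning = TRUE)
    m <- add_reaction(m, "FEMIT", c(fe_c = -1, fe_m = 1),
                      gpr = "gMRS3 or gMRS4", membrane_spanning = TRUE)
    m <- add_reaction(m, "FEMIT2a", c(fe_c = -1, feX_c = 1), gpr = "gYFH1")
    m <- add_reaction(m, "FEMIT2b", c(feX_c = -1, fe_m = 1), gpr = "gYFH1",
                      membrane_spanning = TRUE)
    m <- build_scaffold_cycle(m, list(
      donor = "sdon_m", iron = "fe_m", compartment = "m",
      clusters = list(list(species = "fes_m", iron_per_cluster = 2,
                           routes = "gARH1", load_gpr = "gNFS1"))))
    m <- add_reaction(m, "FESX", c(fes_m = -1, fes_c = 1), gpr = "gATM1",
                      membrane_spanning = TRUE)
  }
  if (config$include_regulon) {
    m <- build_regulon_circuit(m, list(
      high_affinity_uptake = "FETHI",
      mito_compartment = "m", envelope_compartment = "e",
      relay_gpr = "gMSN5"))
  }
  m <- couple_haem_to_low_affinity(m, c("gHEM1", "gHEM2"), "FETLO")

  # cofactor requirements: Fe-S on precursor synthesis and secretory copper
  # on high-affinity uptake bind availability (free_to_spent); the
  # respiratory haem requirement is recorded literally (net zero).
  tab <- rbind(
    if (config$include_scaffold)
      cofactor_requirement("GLYC", "fes_c", x, "free_to_spent"),
    cofactor_requirement("FETHI", "cu_sp", x, "free_to_spent"),
    cofactor_requirement("RESP", "haem_c", x, "literal_both_sides"))
  base_model <- m
  m <- augment_model(m, tab)
  validate_model(m)

  bundle <- fixture_bundle(config, m, G = G, O = O, Fe = Fe, Cu = Cu, y = y,
                           h = h, x = x, lo_cap = lo_cap, cu_cap = cu_cap,
                           npad = npad)
  list(model = m, model_unaugmented = base_model, bundle = bundle)
}

# hand-derived reference values (independent of the LP machinery)
fixture_bundle <- function(config, model, G, O, Fe, Cu, y, h, x, lo_cap,
                           cu_cap, npad) {
  with_scaffold <- config$include_scaffold
  with_regulon <- config$include_regulon
  xs <- if (with_scaffold) x else 0
  demand_per_mu <- h + 2 * xs            # haem iron + cluster iron per growth
  opt <- fixture_backbone_optimum(G, O, y, demand_per_mu, supply = Fe)
  mu <- opt$mu; v_r <- opt$v_r; v_f <- opt$v_f
  D <- demand_per_mu * mu
  fetlo <- min(lo_cap, D)
  fethi <- D - fetlo
  fl <- c(EX_glc = -(mu + v_r + v_f), EX_o2 = -v_r, EX_fe = -D,
          EX_cu = -x * fethi, GLCt = mu + v_r + v_f, O2t = v_r,
          CUt = x * fethi, CCC2 = x * fethi, FETLO = fetlo, FETHI = fethi,
          HEMS = h * mu, GLYC = mu, RESP = v_r, FERM = v_f, BIOMASS = mu,
          DM_cu_sp_spent = x * fethi)
  if (npad > 0) fl[paste0("PRE", seq_len(npad))] <- mu
  if (with_scaffold) {
    fl[c("EX_so4", "SO4t", "FEMIT", "FEMIT2a", "FEMIT2b", "FESX",
         "fes_m_scaffold_load", "fes_m_maturation", "DM_fes_c_spent")] <-
      c(-xs * mu, xs * mu, 2 * xs * mu, 0, 0, xs * mu, xs * mu, xs * mu,
        xs * mu)
  }
  if (with_regulon) {
    fl[c("PS_relay", "AS_branch", "AS_relay", "SIG_relay", "SIG_regen")] <-
      c(fethi + xs * mu, fethi, fethi, xs * mu, fethi + xs * mu)
  }

  # expected essentiality: closed-form single-deletion outcomes
  genes <- model$genes
  mu_lo_only <- fixture_backbone_optimum(G, O, y, demand_per_mu,
                                         supply = min(Fe, lo_cap))$mu
  pred <- stats::setNames(rep("viable", length(genes)), genes)
  lethal <- c("gGLT1", "gHEM1", "gHEM2")
  if (with_scaffold) lethal <- c(lethal, "gARH1", "gNFS1", "gCYS", "gATM1")
  if (with_regulon) lethal <- c(lethal, "gMSN5")
  pred[intersect(lethal, genes)] <- "inviable"
  ratio <- stats::setNames(rep(1, length(genes)), genes)
  ratio[pred == "inviable"] <- 0
  ratio["gADH1"] <- min(y * O, G * y / (y + 1)) / mu
  ratio["gCYT1"] <- ratio["gCOX1"] <-
    fixture_backbone_optimum(G, 0, 1, demand_per_mu, supply = Fe)$mu / mu
  for (g in intersect(c("gCTR1", "gCCC2", "gFET3", "gFTR1"), genes))
    ratio[g] <- mu_lo_only / mu
  observed <- stats::setNames(rep("viable", length(genes)), genes)
  obs_inviable <- c("gGLT1", "gHEM1", "gHEM2",
                    if (with_scaffold) c("gARH1", "gNFS1", "gCYS", "gATM1",
                                         "gYFH1"))
  observed[intersect(obs_inviable, genes)] <- "inviable"
  if (!is.null(config$essentiality_labels)) {
    keep <- intersect(names(config$essentiality_labels), genes)
    observed[keep] <- config$essentiality_labels[keep]
  }
  cmx <- confusion_matrix(
    TP = sum(observed == "viable" & pred == "viable"),
    TN = sum(observed == "inviable" & pred == "inviable"),
    FP = sum(observed == "inviable" & pred == "viable"),
    FN = sum(observed == "viable" & pred == "inviable"))

  # qualitative benchmark expectations (growth and O2 uptake vs control)
  mu_low_fe <- fixture_backbone_optimum(G, O, y, demand_per_mu,
                                        supply = 0.1 * Fe)$mu
  table3 <- list(
    high_iron = c(o2 = "same", growth = "same"),
    low_iron = c(o2 = if (min(O, mu_low_fe / y) < v_r - 1e-9) "down" else "same",
                 growth = "down"),
    high_copper = c(o2 = "same", growth = "same"),
    low_copper = c(o2 = "same", growth = "same"),
    ccc2_no_copper = c(o2 = if (min(O, mu_lo_only / y) < v_r - 1e-9)
      "down" else "same", growth = "down"),
    arh1_half = c(o2 = "down", growth = "down"))

  list(params = list(G = G, O = O, Fe = Fe, Cu = Cu, y = y, h = h, x = x,
                     lo_cap = lo_cap, cu_cap = cu_cap, npad = npad,
                     demand_per_mu = demand_per_mu),
       growth = mu, o2_uptake = v_r, iron_demand = D, fluxes = fl,
       growth_low_affinity_only = mu_lo_only,
       observed = observed, expected_predicted = pred,
       expected_growth_ratio = ratio, expected_confusion = cmx,
       table3 = table3)
}

#' Write a fixture reference bundle as JSON
#' @param bundle a fixture bundle.
#' @param path output path.
#' @export
write_fixture_bundle <- function(bundle, path) {
  bundle$expected_confusion <- unclass(bundle$expected_confusion)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
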