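## The Chatham Rise seabed-mining risk network: variable and edge rosters,
## deterministic CPT constructors (direct removal, direct x indirect
## combination), and the packaged default parameterisation.

decision_vars <- function() {
  list(
    bn_variable("DepthExtraction", c("<10 cm", "10-30 cm", ">30 cm"),
                role = "decision", tier = "operational"),
    bn_variable("ProcessingReturn", c("10 m above seafloor", "at seafloor"),
                role = "decision", tier = "operational"),
    bn_variable("MiningIntensity", c("50%", "75%", "100%"),
                role = "decision", tier = "operational"),
    bn_variable("Distance", c("inside", "near-field", "far-field"),
                role = "decision", tier = "operational"),
    bn_variable("NoduleRemoval", c("yes", "no"),
                role = "decision", tier = "operational"))
}

#' The fifteen benthic functional groups
#'
#' Trait-based groups of Chatham Rise benthos assumed to respond similarly
#' to seabed disturbance. `escape_fraction` is the portion of a group able
#' to flee the path of the mining tool; `depth_sensitive` marks the six
#' infaunal groups whose direct removal depends on the extraction depth;
#' `substrate_affinity` notes dependence on hard substrate (nodules, rock)
#' versus soft sediment.
#'
#' @return A data frame with one row per group: `id` (node-name suffix),
#'   `label`, `habit`, `escape_fraction`, `depth_sensitive`,
#'   `substrate_affinity`, `confidence`.
#' @export
functional_groups <- function() {
  data.frame(
    id = c("SessEncSusp", "SessEncFilt", "SessErectSusp", "SessErectFilt",
           "SoftBodied", "DeepMeio", "SurfMeio", "SmallSessMacro",
           "SmallMobMacro", "LargeSessMacro", "LargeMobMacro",
           "MobGrazEpi", "MobPredEpi", "PredScavHyper", "GrazDepHyper"),
    label = c("Sessile encrusting suspension feeders",
              "Sessile encrusting filter feeders",
              "Sessile erect suspension feeders",
              "Sessile erect filter feeders",
              "Soft-bodied erect suspension and filter feeders",
              "Deep meiofauna", "Surface meiofauna",
              "Small sessile macroinfauna", "Small mobile macroinfauna",
              "Large sessile macroinfauna", "Large mobile macroinfauna",
              "Mobile deposit feeding or grazing epibenthos",
              "Mobile predatory or scavenging epibenthos",
              "Predatory or scavenging hyperbenthos",
              "Grazing or deposit-feeding hyperbenthos"),
    habit = c(rep("epifauna-sessile", 5), rep("infauna", 6),
              rep("epifauna-mobile", 2), rep("hyperbenthos", 2)),
    escape_fraction = c(rep(0, 5), rep(0, 6), 0.2, 0.2, 0.3, 0.3),
    depth_sensitive = c(rep(FALSE, 5), rep(TRUE, 6), rep(FALSE, 4)),
    substrate_affinity = c(rep("hard", 5), rep("soft", 6), rep("soft", 4)),
    confidence = c(rep("moderate", 5), rep("moderate", 6), rep("low", 4)),
    stringsAsFactors = FALSE)
}

biota_node <- function(stage, id) paste0(stage, "_", id)

#' Direct removal fraction in the mining tool's path
#'
#' Outside the mined block no extraction occurs and the fraction is zero.
#' Inside, the removed fraction is the mined proportion of the block
#' (`p(intensity)` of 0.5/0.75/1), reduced by the group's escape fraction
#' and, for infaunal groups, by a depth multiplier encoding that shallow
#' extraction spares deeper-dwelling individuals.
#'
#' @param group Group id or label (a row of [functional_groups()]).
#' @param intensity A `MiningIntensity` state (`"50%"`, `"75%"`, `"100%"`).
#' @param depth A `DepthExtraction` state.
#' @param domain A `Distance` state.
#' @param groups Group table; defaults to [functional_groups()].
#' @param depth_multipliers Named multipliers applied to infaunal groups per
#'   extraction-depth state.
#' @return Fraction of the group removed, in `[0, 1]`.
#' @export
direct_removal_fraction <- function(group, intensity, depth, domain,
                                    groups = functional_groups(),
                                    depth_multipliers = c("<10 cm" = 0.8,
                                                          "10-30 cm" = 0.95,
                                                          ">30 cm" = 1.0)) {
  row <- groups[groups$id == group | groups$label == group, ]
  if (nrow(row) != 1L) stop("unknown functional group '", group, "'",
                            call. = FALSE)
  if (domain != "inside") return(0)
  p <- c("50%" = 0.5, "75%" = 0.75, "100%" = 1.0)[[intensity]]
  mult <- if (row$depth_sensitive) depth_multipliers[[depth]] else 1
  p * (1 - row$escape_fraction) * mult
}

#' Point-mass CPT for direct removal
#'
#' Each parent-state combination maps to a point mass on the decrease bin
#' containing the [direct_removal_fraction()]; fractions landing exactly on
#' a bin edge go to the lower-impact bin.
#'
#' @inheritParams direct_removal_fraction
#' @param bins A [bin_scheme()].
#' @return A [bn_cpt()] with parents `MiningIntensity`, `Distance` and, for
#'   infaunal groups, `DepthExtraction`.
#' @export
direct_cpt <- function(group, bins = decrease_bins(),
                       groups = functional_groups(),
                       depth_multipliers = c("<10 cm" = 0.8,
                                             "10-30 cm" = 0.95,
                                             ">30 cm" = 1.0)) {
  row <- groups[groups$id == group | groups$label == group, ]
  if (nrow(row) != 1L) stop("unknown functional group '", group, "'",
                            call. = FALSE)
  ints <- c("50%", "75%", "100%")
  doms <- c("inside", "near-field", "far-field")
  deps <- c("<10 cm", "10-30 cm", ">30 cm")
  k <- length(bins$labels)
  if (row$depth_sensitive) {
    parents <- c("MiningIntensity", "Distance", "DepthExtraction")
    pstates <- list(MiningIntensity = ints, Distance = doms,
                    DepthExtraction = deps)
    grid <- expand.grid(ints, doms, deps, stringsAsFactors = FALSE)
  } else {
    parents <- c("MiningIntensity", "Distance")
    pstates <- list(MiningIntensity = ints, Distance = doms)
    grid <- expand.grid(ints, doms, stringsAsFactors = FALSE)
  }
  cols <- vapply(seq_len(nrow(grid)), function(i) {
    fr <- direct_removal_fraction(
      row$id, grid[i, 1], if (ncol(grid) >= 3) grid[i, 3] else ">30 cm",
      grid[i, 2], groups = groups, depth_multipliers = depth_multipliers)
    col <- numeric(k)
    col[assign_bin(fr, bins$edges)] <- 1
    col
  }, numeric(k))
  bn_cpt(biota_node("Direct", row$id), parents, cols,
         child_states = bins$labels, parent_states = pstates)
}

#' Combination CPT for immediate decrease
#'
#' The immediate decrease combines direct removal and indirect (plume)
#' impacts on the survivors: with `D1` uniform on the direct-decrease bin
#' and `D2` uniform on the indirect-decrease bin, the total decrease is
#' `T = 1 - (1 - D1)(1 - D2)`. Column `k` is `P(T in bin k)`, computed by
#' midpoint quadrature on an `grid_m x grid_m` grid. The same table serves
#' all functional groups (it depends only on the bin scheme).
#'
#' @param child,direct_parent,indirect_parent Node names.
#' @param bins A [bin_scheme()].
#' @param grid_m Quadrature points per axis (>= 50; default 200).
#' @return A [bn_cpt()] for `child` given `(direct_parent,
#'   indirect_parent)`.
#' @export
combined_immediate_cpt <- function(child = "Immediate",
                                   direct_parent = "Direct",
                                   indirect_parent = "Indirect",
                                   bins = decrease_bins(), grid_m = 200) {
  if (grid_m < 50) stop("grid_m must be >= 50", call. = FALSE)
  k <- length(bins$labels)
  u <- (seq_len(grid_m) - 0.5) / grid_m
  lo <- bins$edges[-length(bins$edges)]
  hi <- bins$edges[-1]
  cols <- matrix(0, nrow = k, ncol = k * k)
  for (j2 in seq_len(k)) {       # indirect bin
    for (j1 in seq_len(k)) {     # direct bin
      d1 <- lo[j1] + u * (hi[j1] - lo[j1])
      d2 <- lo[j2] + u * (hi[j2] - lo[j2])
      t_tot <- 1 - outer(1 - d1, 1 - d2)
      tab <- tabulate(assign_bin(t_tot, bins$edges), nbins = k)
      cols[, (j2 - 1L) * k + j1] <- tab / (grid_m * grid_m)
    }
  }
  bn_cpt(child, c(direct_parent, indirect_parent), cols,
         child_states = bins$labels,
         parent_states = stats::setNames(list(bins$labels, bins$labels),
                                         c(direct_parent, indirect_parent)))
}

## ---------------------------------------------------------------------------
## Default parameterisation (reconstruction; every number overridable via
## the configuration)

# base child distributions plus an additive particle-size tilt, clipped at
# zero and renormalised
tilted_column <- function(base, tilt) {
  col <- pmax(base + tilt, 0)
  col / sum(col)
}

default_pressure_cpts <- function() {
  ssc_states <- c("low", "moderate", "high")
  # VolumeExtracted | DepthExtraction, MiningIntensity
  vol <- array(0, dim = c(3, 3, 3))
  vol_tab <- list(  # [depth][intensity] -> (low, medium, high)
    `<10 cm`   = list(`50%` = c(0.85, 0.14, 0.01), `75%` = c(0.70, 0.27, 0.03),
                      `100%` = c(0.55, 0.40, 0.05)),
    `10-30 cm` = list(`50%` = c(0.35, 0.55, 0.10), `75%` = c(0.20, 0.60, 0.20),
                      `100%` = c(0.10, 0.55, 0.35)),
    `>30 cm`   = list(`50%` = c(0.10, 0.45, 0.45), `75%` = c(0.05, 0.30, 0.65),
                      `100%` = c(0.02, 0.13, 0.85)))
  for (d in 1:3) for (i in 1:3) vol[, d, i] <- vol_tab[[d]][[i]]

  # SuspendedSediment | VolumeExtracted, ParticleSize, ProcessingReturn,
  # Distance; fine particles stay in suspension (tilt up), discharge 10 m
  # above the bed dilutes the near-bed plume (tilt down)
  ssc_base <- list(  # [distance][volume] -> (low, moderate, high)
    inside = list(c(0.10, 0.54, 0.36), c(0.06, 0.53, 0.41), c(0.03, 0.51, 0.46)),
    `near-field` = list(c(0.42, 0.47, 0.11), c(0.25, 0.55, 0.20),
                        c(0.10, 0.55, 0.35)),
    `far-field` = list(c(0.80, 0.18, 0.02), c(0.70, 0.27, 0.03),
                       c(0.55, 0.40, 0.05)))
  ps_tilt_ssc <- list(fine = c(-0.05, 0, 0.05), mixed = c(0, 0, 0),
                      coarse = c(0.05, 0, -0.05))
  pr_tilt <- list(`10 m above seafloor` = c(0.05, 0, -0.05),
                  `at seafloor` = c(0, 0, 0))
  ssc <- array(0, dim = c(3, 3, 3, 2, 3))
  for (v in 1:3) for (ps in 1:3) for (pr in 1:2) for (d in 1:3)
    ssc[, v, ps, pr, d] <- tilted_column(
      ssc_base[[d]][[v]], ps_tilt_ssc[[ps]] + pr_tilt[[pr]])

  # SedimentDeposition | SuspendedSediment, ParticleSize, Distance; coarse
  # particles settle close to the source
  dep_base <- list(  # [distance][ssc] -> (low, moderate, high)
    inside = list(c(0.20, 0.30, 0.50), c(0.05, 0.25, 0.70), c(0.02, 0.15, 0.83)),
    `near-field` = list(c(0.55, 0.35, 0.10), c(0.35, 0.47, 0.18),
                        c(0.12, 0.50, 0.38)),
    `far-field` = list(c(0.85, 0.13, 0.02), c(0.70, 0.25, 0.05),
                       c(0.50, 0.38, 0.12)))
  ps_tilt_dep <- list(fine = c(0.05, 0, -0.05), mixed = c(0, 0, 0),
                      coarse = c(-0.05, 0, 0.05))
  dep <- array(0, dim = c(3, 3, 3, 3))
  for (s in 1:3) for (ps in 1:3) for (d in 1:3)
    dep[, s, ps, d] <- tilted_column(dep_base[[d]][[s]], ps_tilt_dep[[ps]])

  # ContaminantRelease | SedimentContaminants, ParticleSize (fine particles
  # expose more surface area)
  rel <- array(0, dim = c(2, 3, 3))
  p_sig <- rbind(fine = c(0.10, 0.30, 0.60), mixed = c(0.07, 0.25, 0.55),
                 coarse = c(0.05, 0.20, 0.50))  # [ps, contaminants]
  for (cont in 1:3) for (ps in 1:3)
    rel[, cont, ps] <- c(1 - p_sig[ps, cont], p_sig[ps, cont])

  # SedimentChanges | SedimentDeposition, NoduleRemoval
  chg <- array(0, dim = c(2, 3, 2))
  p_chg <- rbind(yes = c(0.60, 0.80, 0.95), no = c(0.15, 0.45, 0.80))
  for (d in 1:3) for (nr in 1:2)
    chg[, d, nr] <- c(1 - p_chg[nr, d], p_chg[nr, d])

  # FoodAvailability | SedimentChanges (disturbed, reworked sediment can
  # carry more accessible organic matter for grazers and scavengers)
  food <- array(c(0.10, 0.90, 0.60, 0.40), dim = c(2, 2))

  list(
    VolumeExtracted = list(parents = c("DepthExtraction", "MiningIntensity"),
                           values = as.numeric(vol)),
    SuspendedSediment = list(
      parents = c("VolumeExtracted", "ParticleSize", "ProcessingReturn",
                  "Distance"),
      values = as.numeric(ssc)),
    SedimentDeposition = list(
      parents = c("SuspendedSediment", "ParticleSize", "Distance"),
      values = as.numeric(dep)),
    ContaminantRelease = list(
      parents = c("SedimentContaminants", "ParticleSize"),
      values = as.numeric(rel)),
    SedimentChanges = list(
      parents = c("SedimentDeposition", "NoduleRemoval"),
      values = as.numeric(chg)),
    FoodAvailability = list(parents = "SedimentChanges",
                            values = as.numeric(food)))
}

# per-group elicitation defaults: weights encode the published importance
# narrative (toxin release weighted lowest everywhere; suspended sediment
# heaviest for hyperbenthos and sessile macroinfauna; deposition heaviest
# for meiofauna, mobile macroinfauna and mobile epifauna)
default_elicitation <- function() {
  ssc_scores <- c(low = 0, moderate = 0.5, high = 1)
  dep_scores <- c(low = 0, moderate = 0.5, high = 1)
  rel_scores <- c(nonsignificant = 0, significant = 1)
  ind <- function(w, best, worst) {
    list(best = best, worst = worst,
         influences = list(
           list(parent = "SuspendedSediment", weight = w[1],
                scores = as.list(ssc_scores)),
           list(parent = "SedimentDeposition", weight = w[2],
                scores = as.list(dep_scores)),
           list(parent = "ContaminantRelease", weight = w[3],
                scores = as.list(rel_scores))))
  }
  indirect <- list(
    SessEncSusp    = ind(c(0.40, 0.50, 0.10), c(1.3, 8), c(12, 1.3)),
    SessEncFilt    = ind(c(0.40, 0.50, 0.10), c(1.3, 8), c(11, 1.5)),
    SessErectSusp  = ind(c(0.50, 0.40, 0.10), c(1.3, 8), c(12, 1.3)),
    SessErectFilt  = ind(c(0.50, 0.40, 0.10), c(1.3, 8), c(11, 1.5)),
    SoftBodied     = ind(c(0.45, 0.45, 0.10), c(1.3, 8), c(9, 2)),
    DeepMeio       = ind(c(0.25, 0.65, 0.10), c(0.25, 7.75), c(7.6, 0.4)),
    SurfMeio       = ind(c(0.25, 0.65, 0.10), c(0.25, 7.75), c(7.6, 0.4)),
    SmallSessMacro = ind(c(0.55, 0.35, 0.10), c(0.25, 7.75), c(7.6, 0.4)),
    SmallMobMacro  = ind(c(0.30, 0.65, 0.05), c(0.25, 7.75), c(7.6, 0.4)),
    LargeSessMacro = ind(c(0.55, 0.35, 0.10), c(0.25, 7.75), c(7.6, 0.4)),
    LargeMobMacro  = ind(c(0.30, 0.65, 0.05), c(0.25, 7.75), c(7.6, 0.4)),
    MobGrazEpi     = ind(c(0.30, 0.60, 0.10), c(1.2, 10), c(4.5, 3.5)),
    MobPredEpi     = ind(c(0.30, 0.60, 0.10), c(1.2, 10), c(4.5, 3.5)),
    PredScavHyper  = ind(c(0.65, 0.25, 0.10), c(1.0, 8), c(2, 2)),
    GrazDepHyper   = ind(c(0.65, 0.25, 0.10), c(1.0, 8), c(2, 2)))

  bins <- decrease_bins()
  imm_scores <- stats::setNames(as.list(c(0, 0.25, 0.5, 0.75, 1)),
                                bins$labels)
  chg_scores <- list(`minor-to-no` = 0, significant = 1)
  food_scores <- list(increased = 0, unchanged = 1)
  yr <- function(id, w_imm, w2 = NULL, p2 = NULL, s2 = NULL, best, worst) {
    infl <- list(list(parent = biota_node("Immediate", id), weight = w_imm,
                      scores = imm_scores))
    if (!is.null(p2))
      infl <- c(infl, list(list(parent = p2, weight = w2, scores = s2)))
    list(best = best, worst = worst, influences = infl)
  }
  year1 <- list(
    SessEncSusp    = yr("SessEncSusp", 0.6, 0.4, "SedimentChanges",
                        chg_scores, c(1.2, 8), c(13, 1.2)),
    SessEncFilt    = yr("SessEncFilt", 0.6, 0.4, "SedimentChanges",
                        chg_scores, c(1.2, 8), c(13, 1.2)),
    SessErectSusp  = yr("SessErectSusp", 0.6, 0.4, "SedimentChanges",
                        chg_scores, c(1.2, 8), c(13, 1.2)),
    SessErectFilt  = yr("SessErectFilt", 0.6, 0.4, "SedimentChanges",
                        chg_scores, c(1.2, 8), c(13, 1.2)),
    SoftBodied     = yr("SoftBodied", 1, best = c(1, 15), worst = c(1.5, 4)),
    DeepMeio       = yr("DeepMeio", 0.8, 0.2, "SedimentChanges", chg_scores,
                        c(1, 10), c(4, 4)),
    SurfMeio       = yr("SurfMeio", 0.8, 0.2, "SedimentChanges", chg_scores,
                        c(1, 10), c(4, 4)),
    SmallSessMacro = yr("SmallSessMacro", 0.8, 0.2, "SedimentChanges",
                        chg_scores, c(1, 10), c(6.5, 2.5)),
    SmallMobMacro  = yr("SmallMobMacro", 0.8, 0.2, "SedimentChanges",
                        chg_scores, c(1, 10), c(5, 3)),
    LargeSessMacro = yr("LargeSessMacro", 0.8, 0.2, "SedimentChanges",
                        chg_scores, c(1, 10), c(6.5, 2.5)),
    LargeMobMacro  = yr("LargeMobMacro", 0.8, 0.2, "SedimentChanges",
                        chg_scores, c(1, 10), c(5, 3)),
    MobGrazEpi     = yr("MobGrazEpi", 0.95, 0.05, "FoodAvailability",
                        food_scores, c(1, 12), c(4.5, 3.5)),
    MobPredEpi     = yr("MobPredEpi", 0.95, 0.05, "FoodAvailability",
                        food_scores, c(1, 12), c(4.5, 3.5)),
    PredScavHyper  = yr("PredScavHyper", 0.85, 0.15, "SedimentChanges",
                        chg_scores, c(1, 15), c(2.5, 4.5)),
    GrazDepHyper   = yr("GrazDepHyper", 0.85, 0.15, "SedimentChanges",
                        chg_scores, c(1, 15), c(2.5, 4.5)))
  list(indirect = indirect, year1 = year1)
}

default_variables <- function(groups, bins) {
  phys <- list(
    bn_variable("VolumeExtracted", c("low", "medium", "high"),
                tier = "pressure", confidence = "moderate"),
    bn_variable("ParticleSize", c("fine", "mixed", "coarse"),
                tier = "environment", confidence = "moderate", nominal = TRUE),
    bn_variable("SedimentContaminants", c("low", "medium", "high"),
                tier = "environment", confidence = "low"),
    bn_variable("SuspendedSediment", c("low", "moderate", "high"),
                tier = "pressure", confidence = "moderate"),
    bn_variable("SedimentDeposition", c("low", "moderate", "high"),
                tier = "pressure", confidence = "moderate"),
    bn_variable("ContaminantRelease", c("nonsignificant", "significant"),
                tier = "pressure", confidence = "low"),
    bn_variable("SedimentChanges", c("minor-to-no", "significant"),
                tier = "pressure", confidence = "moderate"),
    bn_variable("FoodAvailability", c("increased", "unchanged"),
                tier = "environment", confidence = "low"))
  biota <- list()
  for (i in seq_len(nrow(groups))) {
    for (stage in c("Direct", "Indirect", "Immediate", "Year1")) {
      biota[[length(biota) + 1L]] <-
        bn_variable(biota_node(stage, groups$id[i]), bins$labels,
                    tier = "biota", confidence = groups$confidence[i])
    }
  }
  c(decision_vars(), phys, biota)
}

default_edges <- function(groups) {
  e <- rbind(
    c("DepthExtraction", "VolumeExtracted"),
    c("MiningIntensity", "VolumeExtracted"),
    c("VolumeExtracted", "SuspendedSediment"),
    c("ParticleSize", "SuspendedSediment"),
    c("ProcessingReturn", "SuspendedSediment"),
    c("Distance", "SuspendedSediment"),
    c("SuspendedSediment", "SedimentDeposition"),
    c("ParticleSize", "SedimentDeposition"),
    c("Distance", "SedimentDeposition"),
    c("SedimentContaminants", "ContaminantRelease"),
    c("ParticleSize", "ContaminantRelease"),
    c("SedimentDeposition", "SedimentChanges"),
    c("NoduleRemoval", "SedimentChanges"),
    c("SedimentChanges", "FoodAvailability"))
  for (i in seq_len(nrow(groups))) {
    id <- groups$id[i]
    e <- rbind(e,
               c("MiningIntensity", biota_node("Direct", id)),
               c("Distance", biota_node("Direct", id)))
    if (groups$depth_sensitive[i])
      e <- rbind(e, c("DepthExtraction", biota_node("Direct", id)))
    e <- rbind(e,
               c("SuspendedSediment", biota_node("Indirect", id)),
               c("SedimentDeposition", biota_node("Indirect", id)),
               c("ContaminantRelease", biota_node("Indirect", id)),
               c(biota_node("Direct", id), biota_node("Immediate", id)),
               c(biota_node("Indirect", id), biota_node("Immediate", id)),
               c(biota_node("Immediate", id), biota_node("Year1", id)))
    if (groups$habit[i] == "epifauna-mobile") {
      e <- rbind(e, c("FoodAvailability", biota_node("Year1", id)))
    } else if (id != "SoftBodied") {
      e <- rbind(e, c("SedimentChanges", biota_node("Year1", id)))
    }
  }
  colnames(e) <- c("from", "to")
  e
}

#' The packaged default model configuration
#'
#' A self-contained reconstruction of the Chatham Rise seabed-mining risk
#' model: variable roster (73 nodes), rule-generated edge roster (154
#' edges), root priors, directly specified pressure CPTs, per-group
#' best/worst beta elicitation specifications for the indirect and one-year
#' nodes, deterministic constructors for the direct-removal and
#' direct-by-indirect combination CPTs, the two disturbance scenarios, and
#' expert-confidence tags. Every number can be overridden via
#' [apply_config_patch()].
#'
#' @return An object of class `era_config`.
#' @export
default_config <- function() {
  groups <- functional_groups()
  bins <- decrease_bins()
  elic <- default_elicitation()
  cfg <- list(
    name = "chatham-rise-default",
    bins = bins$edges,
    groups = groups,
    variables = lapply(default_variables(groups, bins), unclass),
    edges = default_edges(groups),
    priors = list(ParticleSize = c(0.25, 0.55, 0.20),
                  SedimentContaminants = c(0.70, 0.25, 0.05)),
    pressure_cpts = default_pressure_cpts(),
    elicitation = elic,
    direct = list(depth_multipliers = c("<10 cm" = 0.8, "10-30 cm" = 0.95,
                                        ">30 cm" = 1.0)),
    immediate = list(grid_m = 200),
    scenarios = list(
      high = list(
        name = "high",
        description = "High impact seabed mining operations",
        assignments = c(MiningIntensity = "100%",
                        DepthExtraction = ">30 cm",
                        ProcessingReturn = "at seafloor",
                        NoduleRemoval = "yes")),
      intermediate = list(
        name = "intermediate",
        description = "Surface collector operations",
        assignments = c(MiningIntensity = "50%",
                        DepthExtraction = "<10 cm",
                        ProcessingReturn = "at seafloor",
                        NoduleRemoval = "no"))),
    expected_counts = c(nodes = 73, edges = 154, roots = 7))
  structure(cfg, class = "era_config")
}

elicitation_spec_from_config <- function(child, entry, bins) {
  infl <- lapply(entry$influences, function(x)
    parent_influence(x$parent, x$weight, unlist(x$scores)))
  elicitation_spec(child,
                   beta_spec(entry$best[1], entry$best[2]),
                   beta_spec(entry$worst[1], entry$worst[2]),
                   infl, bins)
}

#' Assemble a network from a model configuration
#'
#' Builds every CPT (explicit tables, beta-elicitation specs, deterministic
#' direct-removal and combination constructors), attaches root priors, and
#' verifies the result: the derived structure must match the configured edge
#' roster and expected counts, and [validate_network()] must come back
#' clean.
#'
#' @param config An `era_config`, e.g. [default_config()].
#' @return A valid `bn_network`.
#' @export
assemble_network <- function(config) {
  bins <- bin_scheme(config$bins)
  groups <- config$groups
  variables <- lapply(config$variables, function(v)
    bn_variable(v$name, v$states, v$role, v$tier, v$confidence, v$nominal))
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  states_of <- function(v) variables[[v]]$states
  cpts <- list()
  for (root in names(config$priors)) {
    cpts[[root]] <- bn_cpt(root, character(0), config$priors[[root]],
                           child_states = states_of(root))
  }
  for (child in names(config$pressure_cpts)) {
    entry <- config$pressure_cpts[[child]]
    cpts[[child]] <- bn_cpt(child, entry$parents, entry$values,
                            child_states = states_of(child),
                            parent_states = stats::setNames(
                              lapply(entry$parents, states_of),
                              entry$parents))
  }
  comb <- combined_immediate_cpt(bins = bins,
                                 grid_m = config$immediate$grid_m)
  for (i in seq_len(nrow(groups))) {
    id <- groups$id[i]
    cpts[[biota_node("Direct", id)]] <-
      direct_cpt(id, bins, groups, config$direct$depth_multipliers)
    cpts[[biota_node("Indirect", id)]] <- build_cpt_from_elicitation(
      elicitation_spec_from_config(biota_node("Indirect", id),
                                   config$elicitation$indirect[[id]], bins))
    imm <- comb
    imm$child <- biota_node("Immediate", id)
    imm$parents <- c(biota_node("Direct", id), biota_node("Indirect", id))
    names(dimnames(imm$values)) <- c(imm$child, imm$parents)
    cpts[[imm$child]] <- imm
    cpts[[biota_node("Year1", id)]] <- build_cpt_from_elicitation(
      elicitation_spec_from_config(biota_node("Year1", id),
                                   config$elicitation$year1[[id]], bins))
  }
  net <- bn_network(variables, cpts,
                    decision_priors = config$decision_priors)
  # the configured roster must agree with the CPT-derived structure
  key <- function(m) sort(paste(m[, 1], m[, 2], sep = "->"))
  if (!identical(key(net$edges), key(config$edges)))
    stop("configured edge roster does not match the CPT-derived structure",
         call. = FALSE)
  bad <- validate_network(net)
  if (length(bad))
    stop("assembled network is invalid:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  if (!is.null(config$expected_counts)) {
    s <- structure_summary(net)
    got <- c(nodes = s$n_nodes, edges = s$n_edges, roots = s$n_roots)
    want <- config$expected_counts
    if (!all(got == want[names(got)]))
      stop("structure counts (", paste(got, collapse = "/"),
           ") do not match the expected counts (",
           paste(want, collapse = "/"), ")", call. = FALSE)
  }
  attr(net, "config") <- config
  net
}

#' The default Chatham Rise network
#'
#' Convenience wrapper: `assemble_network(default_config())`.
#' @return A valid `bn_network` with 73 nodes, 154 edges and 7 roots.
#' @export
chatham_network <- function() assemble_network(default_config())

#' Structural summary of a network
#'
#' @param net A `bn_network`.
#' @return List with `n_nodes`, `n_edges`, `n_roots` (parentless variables)
#'   and `tiers`, a named count of nodes per model tier.
#' @export
structure_summary <- function(net) {
  vn <- node_names(net)
  with_parents <- unique(net$edges[, "to"])
  tiers <- vapply(net$variables, `[[`, character(1), "tier")
  list(n_nodes = length(vn),
       n_edges = nrow(net$edges),
       n_roots = length(setdiff(vn, with_parents)),
       tiers = if (length(tiers)) table(factor(
         tiers, levels = c("operational", "pressure", "environment", "biota")))
       else table(factor(character(0),
                         levels = c("operational", "pressure", "environment",
                                    "biota"))))
}
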