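#' @useDynLib pulmodpm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Resource table access -------------------------------------------------------

pdm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pulmodpm")
  if (!nzchar(path)) stop("resource file not found: ", file, call. = FALSE)
  path
}

#' Read a shipped morphometric resource table
#'
#' The package ships its anatomy tables (airway geometry, lung segment
#' dimensions, connectivity maps) as plain TSV files under `extdata`. This
#' accessor reads one of them verbatim.
#'
#' @param name File name under `extdata`, e.g. `"human_airway_geometry.tsv"`.
#' @return A data frame with the columns of the resource file.
#' @export
read_anatomy_table <- function(name) {
  utils::read.delim(pdm_extdata(name), stringsAsFactors = FALSE)
}

# Reference masses (kg). Goat shares the sheep lung structure.
PDM_REF_MASS <- c(human = 70, sheep = 40, goat = 30)

# Whole-lung reference parameters at reference body mass.
PDM_DEFAULTS <- list(
  D_L_O2_ref   = 40,    # ml/(mmHg*min), resting membrane diffusing capacity
  D_L_CO2      = 800,   # ml/(mmHg*min)
  V_capillary  = 75,    # ml, total pulmonary capillary blood volume
  shunt_baseline = 0.02,
  frc_ml       = 3000,  # functional residual capacity at 70 kg
  deadspace_total_ml = 150 # anatomic dead space target at reference mass
)

stop_invalid <- function(...) {
  stop(structure(class = c("pdm_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Internal constructor shared by the species builders.
new_lung_model <- function(species, body_mass, reference_mass,
                           airways, segments, tree, seg_map,
                           frc_ml, deadspace_total_ml,
                           D_L_O2_ref, D_L_CO2, V_capillary, shunt_baseline) {
  parent <- rep(NA_integer_, nrow(airways))
  for (i in seq_len(nrow(tree))) {
    parent[match(tree$child_id[i], airways$id)] <- tree$parent_id[i]
  }
  children <- lapply(airways$id, function(p) tree$child_id[tree$parent_id == p])
  is_leaf <- lengths(children) == 0L

  # acyclicity / single root
  if (sum(is.na(parent)) != 1L || airways$id[is.na(parent)] != 1L)
    stop("airway tree must have exactly one root with id 1")
  for (i in seq_len(nrow(airways))) {
    seen <- integer(0); j <- airways$id[i]
    while (!is.na(parent[match(j, airways$id)])) {
      if (j %in% seen) stop("airway tree contains a cycle at compartment ", j)
      seen <- c(seen, j)
      j <- parent[match(j, airways$id)]
      if (length(seen) > nrow(airways)) stop("airway tree walk exceeded depth")
    }
  }
  if (!all(seg_map$leaf_id %in% airways$id[is_leaf]))
    stop("segment map references a non-leaf airway compartment")
  if (!setequal(seg_map$segment_id, segments$id) ||
      anyDuplicated(seg_map$segment_id))
    stop("every segment must be fed by exactly one leaf airway compartment")

  segments$f <- segments$volume_pct / sum(segments$volume_pct)
  segments$feeding_airway_id <- seg_map$leaf_id[match(segments$id, seg_map$segment_id)]

  v_upper <- sum(airways$volume_ml)
  ds_left <- max(deadspace_total_ml - v_upper, 0)
  segments$deadspace_ml <- ds_left * segments$f
  segments$alv_volume_ml <- frc_ml * segments$f

  m <- structure(list(
    species = species,
    body_mass = body_mass,
    reference_mass = reference_mass,
    airways = airways,        # id, length_mm, diameter_mm (human), volume_ml
    parent = parent,
    children = children,
    is_leaf = is_leaf,
    segments = segments,      # id, volume_pct, height_pct, f, side, feeding_airway_id,
                              # deadspace_ml, alv_volume_ml
    frc_ml = frc_ml,
    deadspace_total_ml = deadspace_total_ml,
    D_L_O2_ref = D_L_O2_ref,
    D_L_CO2 = D_L_CO2,
    V_capillary = V_capillary,
    shunt_baseline = shunt_baseline
  ), class = "lung_model")

  # scale from reference mass to requested body mass
  if (abs(body_mass - reference_mass) > 0) {
    m$body_mass <- reference_mass
    m <- scale_anatomy(m, body_mass)
  }
  m
}

#' Build the reference human lung model
#'
#' Constructs the anatomic human lung: an 18-compartment asymmetric upper
#' airway tree (trachea to segmental bronchi, Horsfield-type morphometry) and
#' 19 lung segments, each with a conducting dead-space compartment in series
#' with a variable-volume alveolar compartment and a serial capillary train.
#' Airway compartment volumes are cylinders computed from the shipped
#' length/diameter table; segment volumes and heights come from the shipped
#' CT-derived segment table, normalized to fractions of total alveolar volume.
#' The model is scaled from the 70 kg reference by `body_mass` (volumes
#' linearly, diffusing capacities by mass^(2/3)).
#'
#' @param body_mass Body mass in kg (> 0).
#' @param frc_ml Functional residual capacity at reference mass (ml).
#' @param deadspace_total_ml Total anatomic dead space at reference mass (ml);
#'   the part not accounted for by the upper airway tree is distributed over
#'   the segmental conducting compartments in proportion to segment volume.
#' @param V_capillary Total pulmonary capillary volume at reference mass (ml).
#' @param shunt_baseline Healthy anatomic shunt fraction of cardiac output.
#' @return A `lung_model` object.
#' @examples
#' lung <- build_human_lung(70)
#' nrow(lung$airways)    # 18 upper-airway compartments
#' nrow(lung$segments)   # 19 segments
#' @export
build_human_lung <- function(body_mass = 70,
                             frc_ml = PDM_DEFAULTS$frc_ml,
                             deadspace_total_ml = PDM_DEFAULTS$deadspace_total_ml,
                             V_capillary = PDM_DEFAULTS$V_capillary,
                             shunt_baseline = PDM_DEFAULTS$shunt_baseline) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || !is.finite(body_mass) ||
      body_mass <= 0)
    stop_invalid("body_mass must be a positive number")
  aw <- read_anatomy_table("human_airway_geometry.tsv")
  aw$volume_ml <- pi * aw$diameter_mm^2 * aw$length_mm / 4 / 1000
  seg <- read_anatomy_table("human_lung_segments.tsv")
  side <- read_anatomy_table("human_segment_side.tsv")
  seg$side <- side$side[match(seg$id, side$segment_id)]
  tree <- read_anatomy_table("human_airway_tree.tsv")
  smap <- read_anatomy_table("human_airway_segment_map.tsv")
  new_lung_model("human", body_mass, PDM_REF_MASS[["human"]],
                 aw, seg, tree, smap,
                 frc_ml, deadspace_total_ml,
                 PDM_DEFAULTS$D_L_O2_ref, PDM_DEFAULTS$D_L_CO2,
                 V_capillary, shunt_baseline)
}

#' Build the reference sheep lung model
#'
#' The sheep lung is modelled as six lobes (left apical and diaphragmatic;
#' right apical, diaphragmatic, accessory and middle), each a single lobar
#' alveolar compartment fed by one distal airway compartment of the
#' six-compartment asymmetric airway tree. Airway volumes are taken directly
#' from the shipped dimension table; lobar alveolar fractions are the printed
#' percentages renormalized to sum to 1. Whole-lung parameters (diffusing
#' capacity, capillary volume, FRC, dead space) are the human reference values
#' scaled allometrically to the 40 kg sheep reference.
#'
#' @inheritParams build_human_lung
#' @return A `lung_model` object with 6 lobar alveolar compartments.
#' @export
build_sheep_lung <- function(body_mass = 40,
                             shunt_baseline = PDM_DEFAULTS$shunt_baseline) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || !is.finite(body_mass) ||
      body_mass <= 0)
    stop_invalid("body_mass must be a positive number")
  ref <- PDM_REF_MASS[["sheep"]]
  r_vol <- ref / PDM_REF_MASS[["human"]]
  r_area <- r_vol^(2 / 3)
  aw <- read_anatomy_table("sheep_airway_geometry.tsv")
  lob <- read_anatomy_table("sheep_lobes.tsv")
  names(lob)[names(lob) == "lobe"] <- "lobe_name"
  tree <- read_anatomy_table("sheep_airway_tree.tsv")
  smap <- read_anatomy_table("sheep_airway_lobe_map.tsv")
  m <- new_lung_model("sheep", body_mass, ref,
                      aw, lob, tree, smap,
                      frc_ml = PDM_DEFAULTS$frc_ml * r_vol,
                      deadspace_total_ml = PDM_DEFAULTS$deadspace_total_ml * r_vol,
                      D_L_O2_ref = PDM_DEFAULTS$D_L_O2_ref * r_area,
                      D_L_CO2 = PDM_DEFAULTS$D_L_CO2 * r_area,
                      V_capillary = PDM_DEFAULTS$V_capillary * r_vol,
                      shunt_baseline = shunt_baseline)
  m
}

#' Build a goat lung model
#'
#' Goats share the sheep lobar lung structure; the goat model is the sheep
#' anatomy scaled allometrically to the goat reference mass (30 kg by default).
#'
#' @inheritParams build_human_lung
#' @return A `lung_model` object.
#' @export
build_goat_lung <- function(body_mass = 30, ...) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || !is.finite(body_mass) ||
      body_mass <= 0)
    stop_invalid("body_mass must be a positive number")
  m <- build_sheep_lung(body_mass = body_mass, ...)
  m$species <- "goat"
  m$reference_mass <- PDM_REF_MASS[["goat"]]
  m
}

#' Allometric rescaling of a lung model
#'
#' Rescales every volume linearly with body mass and every area-proportional
#' quantity (diffusing capacities) with mass to the 2/3 power, relative to the
#' model's current mass. Dimensionless fractions (segment volume fractions,
#' shunt) are unchanged.
#'
#' @param model A `lung_model`.
#' @param target_mass New body mass in kg (> 0).
#' @return The rescaled `lung_model`.
#' @export
scale_anatomy <- function(model, target_mass) {
  stopifnot(inherits(model, "lung_model"))
  if (!is.numeric(target_mass) || length(target_mass) != 1L ||
      !is.finite(target_mass) || target_mass <= 0)
    stop_invalid("target_mass must be a positive number")
  r <- target_mass / model$body_mass
  if (r == 1) return(model)
  rl <- r^(1 / 3)   # lengths/diameters scale with the cube root of volume
  ra <- r^(2 / 3)
  model$airways$volume_ml <- model$airways$volume_ml * r
  if (!is.null(model$airways$length_mm))
    model$airways$length_mm <- model$airways$length_mm * rl
  if (!is.null(model$airways$diameter_mm))
    model$airways$diameter_mm <- model$airways$diameter_mm * rl
  model$segments$deadspace_ml <- model$segments$deadspace_ml * r
  model$segments$alv_volume_ml <- model$segments$alv_volume_ml * r
  model$frc_ml <- model$frc_ml * r
  model$deadspace_total_ml <- model$deadspace_total_ml * r
  model$V_capillary <- model$V_capillary * r
  model$D_L_O2_ref <- model$D_L_O2_ref * ra
  model$D_L_CO2 <- model$D_L_CO2 * ra
  model$body_mass <- target_mass
  model
}

#' Volume fraction of the right lung
#'
#' @param model A `lung_model`.
#' @return Fraction of total alveolar volume in right-lung segments.
#' @export
right_lung_fraction <- function(model) {
  stopifnot(inherits(model, "lung_model"))
  sum(model$segments$f[model$segments$side == "right"])
}

# Depth of each airway compartment (root = 0); used by tree-sanity tests.
airway_depths <- function(model) {
  ids <- model$airways$id
  d <- integer(length(ids))
  for (i in seq_along(ids)) {
    j <- ids[i]; n <- 0L
    while (!is.na(model$parent[match(j, ids)])) {
      j <- model$parent[match(j, ids)]; n <- n + 1L
    }
    d[i] <- n
  }
  d
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf("Anatomic lung model: %s, %.1f kg (reference %.1f kg)\n",
              x$species, x$body_mass, x$reference_mass))
  cat(sprintf("  %d airway compartments, %d %s\n",
              nrow(x$airways), nrow(x$segments),
              if (x$species == "human") "lung segments" else "lobar compartments"))
  cat(sprintf("  FRC %.0f ml, dead space %.0f ml, capillary volume %.1f ml\n",
              x$frc_ml, x$deadspace_total_ml, x$V_capillary))
  cat(sprintf("  D_L,O2(ref) %.1f, D_L,CO2 %.1f ml/(mmHg*min), baseline shunt %.3f\n",
              x$D_L_O2_ref, x$D_L_CO2, x$shunt_baseline))
  invisible(x)
}

#' @export
summary.lung_model <- function(object, ...) {
  s <- object$segments
  cat("Segments (fraction of alveolar volume, height % from base):\n")
  print(data.frame(id = s$id, f = round(s$f, 4), height = s$height_pct,
                   side = if (!is.null(s$side)) s$side else NA), row.names = FALSE)
  invisible(object)
}
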