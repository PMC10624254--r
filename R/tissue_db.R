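# Tissue property database: adult dielectric/perfusion values, age-dependent
# conversion ratios, derived toddler (3.5 y.o.) values, and unit conversions.
#
# The packaged table carries, per tissue: the 297.2 MHz relative permittivity
# and electrical conductivity of a 3.5-year-old together with the
# adult-to-child conversion ratios (adult value = child value / ratio), the
# basal perfusion (ml min^-1 kg^-1) with its ratio, and documented default
# density / heat capacity / thermal conductivity / metabolic heat columns
# (these four carry no age dependency). Liquid tissues (blood, CSF, vitreous
# and aqueous humor, intestine contents, urine, bile) keep adult dielectric
# properties at every age, so their dielectric ratios are exactly 1.

.tissue_cols <- c("tissue", "is_liquid", "permittivity_ratio", "permittivity",
                  "conductivity_ratio", "conductivity", "perfusion_ratio",
                  "perfusion", "density", "heat_capacity",
                  "thermal_conductivity", "metabolic_rate")

#' Load and validate a tissue property table
#'
#' Reads a CSV with the packaged schema (see Details), validates physical
#' invariants, and derives the adult-value columns
#' `permittivity_adult`, `conductivity_adult`, `perfusion_adult` as
#' child value / ratio (0 where both are 0).
#'
#' @details Required columns: `tissue`, `is_liquid`, `permittivity_ratio`,
#' `permittivity` (child, dimensionless), `conductivity_ratio`,
#' `conductivity` (child, S/m), `perfusion_ratio`, `perfusion`
#' (child, ml min^-1 kg^-1), `density` (kg/m^3), `heat_capacity`
#' (J kg^-1 degC^-1), `thermal_conductivity` (W m^-1 degC^-1),
#' `metabolic_rate` (W/kg).
#'
#' @param path CSV path; default is the packaged 297.2 MHz table.
#' @param freq_hz drive frequency the dielectric columns refer to; stored as
#'   an attribute (the packaged table is tabulated at 297.2 MHz; solvers take
#'   their frequency from configuration, not from here).
#' @return data.frame of class `tissue_table` with attribute `freq_hz`.
#' @export
load_tissue_table <- function(path = default_tissue_table_path(),
                              freq_hz = 297.2e6) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.tissue_cols, names(tab))
  if (length(miss))
    stop("tissue table is missing columns: ", paste(miss, collapse = ", "))
  tab$is_liquid <- as.logical(tab$is_liquid)
  num <- setdiff(.tissue_cols, c("tissue", "is_liquid"))
  for (cn in num) tab[[cn]] <- as.numeric(tab[[cn]])
  check_row <- function(ok, what) {
    if (any(!ok))
      stop("invalid tissue table row(s) [", what, "]: ",
           paste(tab$tissue[!ok], collapse = ", "))
  }
  check_row(tab$conductivity >= 0, "conductivity < 0")
  check_row(tab$permittivity >= 1, "relative permittivity < 1")
  check_row(tab$density > 0, "density <= 0")
  check_row(tab$heat_capacity > 0, "heat capacity <= 0")
  check_row(tab$thermal_conductivity >= 0, "thermal conductivity < 0")
  check_row(tab$perfusion >= 0, "perfusion < 0")
  check_row(tab$metabolic_rate >= 0, "metabolic rate < 0")
  check_row(!tab$is_liquid |
              (tab$permittivity_ratio == 1 & tab$conductivity_ratio == 1),
            "liquid tissue with dielectric ratio != 1")
  if (anyDuplicated(tab$tissue))
    stop("duplicate tissue names in table")
  safe_div <- function(child, ratio)
    ifelse(ratio == 0, ifelse(child == 0, 0, NA_real_), child / ratio)
  tab$permittivity_adult <- safe_div(tab$permittivity, tab$permittivity_ratio)
  tab$conductivity_adult <- safe_div(tab$conductivity, tab$conductivity_ratio)
  tab$perfusion_adult <- safe_div(tab$perfusion, tab$perfusion_ratio)
  check_row(!is.na(tab$permittivity_adult) & !is.na(tab$conductivity_adult) &
              !is.na(tab$perfusion_adult), "zero ratio with nonzero value")
  attr(tab, "freq_hz") <- freq_hz
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Path to the packaged 297.2 MHz tissue property table
#' @export
default_tissue_table_path <- function() {
  system.file("extdata", "tissue_properties_297MHz.csv",
              package = "voxdosim", mustWork = TRUE)
}

#' Look up one tissue's properties
#' @param tab a `tissue_table`; @param tissue tissue name
#' @return single-row data.frame
#' @export
tissue_row <- function(tab, tissue) {
  i <- match(tissue, tab$tissue)
  if (is.na(i)) stop("tissue not in table: ", tissue)
  tab[i, , drop = FALSE]
}

#' Scale adult tissue properties to the modeled age
#'
#' Applies the age-dependent conversion ratios: child permittivity =
#' adult x permittivity ratio, child conductivity = adult x conductivity
#' ratio, child perfusion = adult x perfusion ratio. Density, thermal
#' conductivity and specific heat capacity carry no age dependency and pass
#' through unchanged; liquid tissues have all-unity dielectric ratios so
#' their dielectric properties are unchanged by construction.
#'
#' @param adult single-row data.frame (or list) with fields
#'   `permittivity`, `conductivity`, `perfusion` holding *adult* values, the
#'   three `*_ratio` fields, and the age-independent columns.
#' @return the same structure with child values in `permittivity`,
#'   `conductivity`, `perfusion`.
#' @export
scale_properties_to_age <- function(adult) {
  need <- c("permittivity", "conductivity", "perfusion",
            "permittivity_ratio", "conductivity_ratio", "perfusion_ratio")
  miss <- setdiff(need, names(adult))
  if (length(miss)) stop("missing fields: ", paste(miss, collapse = ", "))
  out <- adult
  out$permittivity <- adult$permittivity * adult$permittivity_ratio
  out$conductivity <- adult$conductivity * adult$conductivity_ratio
  out$perfusion <- adult$perfusion * adult$perfusion_ratio
  out
}

#' Convert mass-specific perfusion to a volumetric rate
#'
#' The tabulated basal perfusion W is in ml of blood per minute per kg of
#' tissue. The Pennes sink term uses a volumetric rate
#' omega (s^-1) = W x 1e-6 (m^3/ml) / 60 (s/min) x rho_tissue (kg/m^3),
#' i.e. m^3 of blood per m^3 of tissue per second.
#'
#' @param W perfusion in ml min^-1 kg^-1 (>= 0)
#' @param rho_tissue tissue mass density in kg m^-3
#' @return omega in s^-1
#' @export
perfusion_to_volumetric <- function(W, rho_tissue) {
  if (any(W < 0)) stop("perfusion must be non-negative")
  if (any(rho_tissue <= 0)) stop("tissue density must be positive")
  W * 1e-6 / 60 * rho_tissue
}

#' Blood constants for the bioheat sink term
#'
#' Defaults are standard reference values (the source publication does not
#' state them numerically): density 1050 kg/m^3, heat capacity
#' 3617 J kg^-1 degC^-1, basal blood temperature 37 degC. All are
#' configuration-exposed.
#'
#' @param rho_b,c_b,T_b overrides
#' @return list with `rho_b`, `c_b`, `T_b`
#' @export
blood_constants <- function(rho_b = 1050, c_b = 3617, T_b = 37.0) {
  stopifnot(rho_b > 0, c_b > 0, T_b > 30, T_b < 40)
  list(rho_b = rho_b, c_b = c_b, T_b = T_b)
}

#' Per-voxel property maps for a labeled phantom
#'
#' Expands the tissue table onto the voxel grid of a phantom: one numeric
#' array per requested property, with exterior air (label 0) given the air
#' value for dielectrics and NA for thermal-only fields as appropriate.
#'
#' @param vol a [label_volume]
#' @param tab a `tissue_table`
#' @param properties character vector of table column names
#' @param outside value to assign to label-0 voxels (default 0)
#' @return named list of 3-D numeric arrays
#' @export
property_maps <- function(vol, tab,
                          properties = c("permittivity", "conductivity",
                                         "density"),
                          outside = 0) {
  tis <- label_tissues(vol)
  idx <- match(tis, tab$tissue)
  if (anyNA(idx))
    stop("tissues absent from the property table: ",
         paste(tis[is.na(idx)], collapse = ", "))
  labs <- as.integer(names(tis))
  lut_n <- max(labs) + 1L
  out <- lapply(properties, function(p) {
    lut <- rep(as.numeric(outside), lut_n)
    lut[labs + 1L] <- tab[[p]][idx]
    array(lut[vol$data + 1L], dim = dim(vol$data))
  })
  names(out) <- properties
  out
}

#' Identify internal-air labels in a phantom
#'
#' Labels whose tissue name starts with "Air" are treated as internal air:
#' they carry no EM or thermal degrees of freedom and act through the
#' internal-air convective boundary.
#' @param vol a [label_volume]
#' @return integer vector of labels
#' @export
internal_air_labels <- function(vol) {
  tis <- label_tissues(vol)
  as.integer(names(tis)[grepl("^Air", tis)])
}
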